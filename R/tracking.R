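#' Generate a stable patient pseudonym
#'
#' Keyed MD5 digest of the patient identifier: deterministic for a
#' given (id, key) pair, different across keys, and not invertible
#' without the key. Used so that every downstream artifact is
#' name-blinded.
#'
#' @param patient_id Patient identifier (non-empty).
#' @param secret Secret key (non-empty); keep it outside the reports.
#' @return Pseudonym string of the form `P-<12 hex digits>`.
#' @export
pseudonymize <- function(patient_id, secret) {
  if (!length(secret) || !nzchar(secret)) stop("empty pseudonymization key")
  if (!length(patient_id) || any(!nzchar(patient_id))) {
    stop("empty patient identifier")
  }
  vapply(patient_id, function(id) {
    paste0("P-", toupper(substr(md5_string(paste(secret, id, secret,
                                                 sep = ":")), 1, 12)))
  }, "", USE.NAMES = FALSE)
}

#' Workflow states and their allowed transitions
#'
#' The per-sample workflow is a small DAG: a registered sample receives
#' its two assays in either order, may branch through an IHC
#' validation request, and ends in delivery; `FAILED_QC` (the
#' cellularity gate) and `DELIVERED` are terminal.
#'
#' @return Named list mapping each state to its allowed successors.
#' @export
workflow_dag <- function() {
  list(
    REGISTERED        = c("CNA_RECEIVED", "VARIANTS_RECEIVED", "FAILED_QC"),
    CNA_RECEIVED      = c("CNA_ANALYZED", "FAILED_QC"),
    CNA_ANALYZED      = c("IHC_REQUESTED", "VARIANTS_RECEIVED",
                          "REPORT_GENERATED", "FAILED_QC"),
    IHC_REQUESTED     = c("VARIANTS_RECEIVED", "REPORT_GENERATED", "FAILED_QC"),
    VARIANTS_RECEIVED = c("VARIANTS_ANALYZED", "FAILED_QC"),
    VARIANTS_ANALYZED = c("CNA_RECEIVED", "REPORT_GENERATED", "FAILED_QC"),
    REPORT_GENERATED  = "DELIVERED",
    DELIVERED         = character(0),
    FAILED_QC         = character(0)
  )
}

#' Start tracking a sample
#'
#' @param sample_id Sample identifier.
#' @param timestamp Registration time (POSIXct or parseable string).
#' @param actor Who registered it.
#' @param note Free-text audit note.
#' @return A `workflow_state` object in state REGISTERED.
#' @export
workflow_start <- function(sample_id, timestamp = Sys.time(),
                           actor = "system", note = "registered") {
  structure(list(
    sample_id = as.character(sample_id),
    state = "REGISTERED",
    history = data.frame(state = "REGISTERED",
                         timestamp = format(as.POSIXct(timestamp), "%Y-%m-%dT%H:%M:%S"),
                         actor = actor, note = note,
                         stringsAsFactors = FALSE)
  ), class = "workflow_state")
}

#' Advance a sample to a new workflow state
#'
#' Appends an immutable audit entry; transitions outside the DAG are
#' rejected with the list of allowed successors, and timestamps must
#' be non-decreasing.
#'
#' @param ws A `workflow_state`.
#' @param to Target state.
#' @param timestamp Event time.
#' @param actor,note Audit fields.
#' @return The updated `workflow_state`.
#' @export
workflow_advance <- function(ws, to, timestamp = Sys.time(),
                             actor = "system", note = "") {
  dag <- workflow_dag()
  if (!to %in% names(dag)) stop("unknown state: ", to)
  allowed <- dag[[ws$state]]
  if (!to %in% allowed) {
    stop("illegal transition ", ws$state, " -> ", to, "; allowed successors: ",
         if (length(allowed)) paste(allowed, collapse = ", ") else
           "(none, terminal state)")
  }
  ts <- format(as.POSIXct(timestamp), "%Y-%m-%dT%H:%M:%S")
  last <- ws$history$timestamp[nrow(ws$history)]
  if (ts < last) stop("timestamp earlier than last audit entry")
  ws$history <- rbind(ws$history,
                      data.frame(state = to, timestamp = ts, actor = actor,
                                 note = note, stringsAsFactors = FALSE))
  ws$state <- to
  ws
}

#' @export
print.workflow_state <- function(x, ...) {
  cat("Sample", x$sample_id, "-", x$state, "\n")
  cat(paste0("  ", x$history$timestamp, " ", x$history$state,
             " (", x$history$actor, ")", collapse = "\n"), "\n")
  invisible(x)
}

# ISO timestamps are stored with a "T" separator, which the default
# as.POSIXct format does not parse
.parse_ts <- function(x) {
  if (inherits(x, "POSIXt")) return(x)
  x <- as.character(x)
  if (grepl("T", x)) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S")
  else as.POSIXct(x)
}

.first_ts <- function(ws, states) {
  h <- ws$history[ws$history$state %in% states, , drop = FALSE]
  if (!nrow(h)) return(NA_character_)
  h$timestamp[1]
}

#' Turnaround times against the trial deadlines
#'
#' The bioinformatics clock runs from the first data arrival (copy
#' number or variants, whichever came first) to report generation (or
#' `now` while pending); the default allowance is 4 days. The total
#' clock runs from biopsy to delivery (or `now`) against a 28-day
#' (four-week) allowance. Elapsed days are calendar days, fractional
#' days rounded up.
#'
#' @param ws A `workflow_state`.
#' @param biopsy_date Biopsy date (anchor of the total clock).
#' @param now Current time, used while the endpoint is pending.
#' @param bioinformatics_days,total_days Deadline allowances in days.
#' @return List: `elapsed_bioinfo_days`, `elapsed_total_days`,
#'   `overdue_bioinfo`, `overdue_total`.
#' @export
turnaround <- function(ws, biopsy_date = NA, now = Sys.time(),
                       bioinformatics_days = 4L, total_days = 28L) {
  stopifnot(bioinformatics_days > 0, total_days > 0,
            bioinformatics_days <= total_days)
  received <- .first_ts(ws, c("CNA_RECEIVED", "VARIANTS_RECEIVED"))
  if (is.na(received)) stop("missing anchor timestamp: no data received yet")
  reported <- .first_ts(ws, "REPORT_GENERATED")
  end_bio <- if (!is.na(reported)) .parse_ts(reported) else .parse_ts(now)
  days <- function(from, to) {
    ceiling(as.numeric(difftime(to, from, units = "days")))
  }
  elapsed_bio <- days(.parse_ts(received), end_bio)
  elapsed_total <- NA_real_
  if (!is.na(biopsy_date)) {
    delivered <- .first_ts(ws, "DELIVERED")
    end_total <- if (!is.na(delivered)) .parse_ts(delivered) else .parse_ts(now)
    elapsed_total <- days(as.POSIXct(as.Date(biopsy_date)), end_total)
  }
  list(elapsed_bioinfo_days = elapsed_bio,
       elapsed_total_days = elapsed_total,
       overdue_bioinfo = elapsed_bio > bioinformatics_days,
       overdue_total = if (is.na(elapsed_total)) NA else
         elapsed_total > total_days)
}

#' Save / load a tracking registry
#'
#' The registry is a flat JSON file mapping sample ids to their full
#' audit histories; saving is an atomic whole-file replacement, and a
#' save/load round trip reproduces the states exactly.
#'
#' @param registry Named list of `workflow_state` objects.
#' @param path Registry file path.
#' @return `registry_save`: invisibly, `path`. `registry_load`: the
#'   registry (empty list if the file does not exist).
#' @export
registry_save <- function(registry, path) {
  payload <- lapply(registry, function(ws) {
    list(sample_id = ws$sample_id, state = ws$state, history = ws$history)
  })
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname registry_save
#' @export
registry_load <- function(path) {
  if (!file.exists(path)) return(list())
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(x) {
    structure(list(sample_id = x$sample_id, state = x$state,
                   history = as.data.frame(x$history,
                                           stringsAsFactors = FALSE)),
              class = "workflow_state")
  })
  names(out) <- vapply(out, `[[`, "", "sample_id")
  out
}
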