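#' Patient block of the molecular board report
#'
#' Clinical context shown at the top of the report. The type carries no
#' name field by construction: the only identifier is the opaque
#' pseudonym, so the report is name-blinded.
#'
#' @param pseudonym Opaque patient identifier ([pseudonymize()]).
#' @param tumor_type Free-text tumor description.
#' @param cellularity Tumor-cell fraction.
#' @param ploidy_class `"diploid"` or `"tetraploid"`.
#' @param hr_estrogen,hr_progesterone,hr_androgen Hormone-receptor
#'   statuses: `"POS"`, `"NEG"` or `"UNKNOWN"`.
#' @param biopsy_date,data_received_date Dates.
#' @return List of class `patient_block`.
#' @export
patient_block <- function(pseudonym, tumor_type = "", cellularity = NA,
                          ploidy_class = c("diploid", "tetraploid"),
                          hr_estrogen = "UNKNOWN", hr_progesterone = "UNKNOWN",
                          hr_androgen = "UNKNOWN",
                          biopsy_date = NA, data_received_date = NA) {
  ploidy_class <- match.arg(ploidy_class)
  hr <- c(hr_estrogen, hr_progesterone, hr_androgen)
  if (!all(hr %in% c("POS", "NEG", "UNKNOWN"))) {
    stop("hormone receptor status must be POS, NEG or UNKNOWN")
  }
  structure(list(
    pseudonym = as.character(pseudonym),
    tumor_type = as.character(tumor_type),
    cellularity = as.numeric(cellularity),
    ploidy_class = ploidy_class,
    hormone_receptors = list(estrogen = hr_estrogen,
                             progesterone = hr_progesterone,
                             androgen = hr_androgen),
    biopsy_date = as.character(biopsy_date),
    data_received_date = as.character(data_received_date)
  ), class = "patient_block")
}

#' Assemble the molecular board report
#'
#' Integrates per-gene copy-number calls and triaged variants into the
#' name-blinded technical report reviewed by the board: a per-gene
#' summary table (status code, LOH flag, mutation count), detail
#' sections for altered genes and reportable variants, the IHC request
#' section, and provenance. FILTERED variants never enter the report
#' body; they are kept in a machine-readable appendix for audit.
#'
#' @param patient A [patient_block()].
#' @param calls Gene calls ([call_genes()]).
#' @param triaged Triaged variants ([triage_variants()]); may have zero
#'   rows.
#' @param panel The gene panel the calls cover.
#' @param thresholds_cna,thresholds_triage Threshold sets (hashed into
#'   provenance).
#' @param timestamp Generation time (pin for byte-identical
#'   regeneration).
#' @param input_checksums Optional named character vector of input-file
#'   MD5s.
#' @return List of class `mbb_report`.
#' @export
build_report <- function(patient, calls, triaged, panel,
                         thresholds_cna = status_thresholds(),
                         thresholds_triage = triage_thresholds(),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                         input_checksums = NULL) {
  stopifnot(inherits(patient, "patient_block"))
  cna_sample <- attr(calls, "sample_id", exact = TRUE)
  var_samples <- unique(triaged$sample_id)
  if (!is.null(cna_sample) && length(var_samples) &&
      !all(var_samples == cna_sample)) {
    stop("sample mismatch between assays: CNA calls are for '", cna_sample,
         "' but variants are for '", paste(var_samples, collapse = ","), "'")
  }
  if (!all(panel$symbol %in% calls$symbol)) {
    stop("calls do not cover the full panel")
  }
  reportable <- triaged[nrow(triaged) > 0 &
                          triaged$category %in% c("POSITIVE", "TO_DISCUSS"), ,
                        drop = FALSE]
  mut_count <- vapply(panel$symbol, function(sym) {
    sum(!is.na(reportable$gene) & reportable$gene == sym)
  }, integer(1))
  idx <- match(panel$symbol, calls$symbol)
  summary_rows <- data.frame(
    symbol = panel$symbol,
    status_code = calls$code[idx],
    loh = calls$loh[idx],
    mutation_count = unname(mut_count),
    stringsAsFactors = FALSE)
  cna_details <- calls[calls$status != "NORMAL" | calls$loh, , drop = FALSE]
  details_cols <- c("chrom", "pos", "ref", "alt", "variant_class", "gene",
                    "consequence", "allele_frequency", "depth",
                    "strand_ratio_value", "hotspot_id", "context",
                    "category", "reasons_str")
  body_variants <- triaged[nrow(triaged) > 0 &
                             triaged$category %in%
                             c("POSITIVE", "TO_DISCUSS", "CONTROL"), ,
                           drop = FALSE]
  filtered <- triaged[nrow(triaged) > 0 & triaged$category == "FILTERED", ,
                      drop = FALSE]
  pick <- function(df) df[, intersect(details_cols, names(df)), drop = FALSE]
  structure(list(
    patient = patient,
    summary_rows = summary_rows,
    cna_details = as.data.frame(cna_details),
    variant_details = pick(as.data.frame(body_variants)),
    ihc_section = list(requests = ihc_requests(calls, thresholds_cna),
                       results = NULL),
    filtered_appendix = pick(as.data.frame(filtered)),
    provenance = list(
      tool = "mtbpipe",
      version = as.character(utils::packageVersion("mtbpipe")),
      threshold_hash = threshold_hash(thresholds_cna, thresholds_triage),
      input_checksums = as.list(input_checksums),
      generated = timestamp)
  ), class = "mbb_report")
}

#' @export
print.mbb_report <- function(x, ...) {
  cat("Molecular board report for patient", x$patient$pseudonym, "\n")
  altered <- sum(x$summary_rows$status_code != "N")
  cat(sprintf("  %d panel genes: %d with altered copy number, %d mutated\n",
              nrow(x$summary_rows), altered,
              sum(x$summary_rows$mutation_count > 0)))
  cat(sprintf("  %d reportable variants, %d IHC request(s)\n",
              nrow(x$variant_details), nrow(x$ihc_section$requests)))
  invisible(x)
}

# recursively sort list names and redact denylisted tokens in strings
.canonicalize <- function(x, denylist) {
  redact <- function(s) {
    for (tok in denylist) {
      s <- gsub(tok, "[REDACTED]", s, ignore.case = TRUE, fixed = FALSE)
    }
    s
  }
  if (is.data.frame(x)) {
    x <- x[, order(names(x)), drop = FALSE]
    for (j in seq_along(x)) {
      if (is.character(x[[j]]) && length(denylist)) x[[j]] <- redact(x[[j]])
      if (is.list(x[[j]])) x[[j]] <- vapply(x[[j]], paste, "", collapse = ";")
    }
    x
  } else if (is.list(x)) {
    if (!is.null(names(x)) && length(x)) x <- x[order(names(x))]
    lapply(x, .canonicalize, denylist = denylist)
  } else if (is.character(x) && length(denylist)) {
    redact(x)
  } else x
}

#' Render a board report
#'
#' JSON is the canonical artifact (recursively sorted keys, so
#' regeneration with a pinned timestamp is byte-identical); markdown
#' and HTML are human-readable views derived from the same content,
#' with copy-number status codes color-coded in HTML. Any token on the
#' identifier denylist is redacted from free-text content before
#' rendering, preserving name-blindness.
#'
#' @param report An `mbb_report` ([build_report()]).
#' @param format `"json"`, `"markdown"` or `"html"`.
#' @param path Optional output file.
#' @param denylist Character vector of forbidden identifier tokens.
#' @return The rendered document as a character scalar (invisibly if
#'   `path` given).
#' @export
render_report <- function(report, format = c("json", "markdown", "html"),
                          path = NULL, denylist = character()) {
  format <- match.arg(format)
  clean <- .canonicalize(unclass(report), denylist)
  doc <- switch(format,
    json = as.character(jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA,
                                         na = "null", null = "null",
                                         pretty = TRUE)),
    markdown = .render_markdown(clean),
    html = .render_html(clean))
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

.render_markdown <- function(r) {
  sr <- r$summary_rows
  lines <- c(
    paste("# Molecular board report -", r$patient$pseudonym),
    "",
    paste0("- Tumor type: ", r$patient$tumor_type),
    sprintf("- Cellularity: %.0f%% | Ploidy class: %s",
            100 * r$patient$cellularity, r$patient$ploidy_class),
    paste0("- Hormone receptors (E/P/A): ",
           paste(unlist(r$patient$hormone_receptors[c("estrogen",
                                                      "progesterone",
                                                      "androgen")]),
                 collapse = "/")),
    "",
    "## Gene summary",
    "",
    "| gene | CN status | LOH | mutations |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %d |", sr$symbol, sr$status_code,
            ifelse(sr$loh, "yes", ""), sr$mutation_count),
    "",
    "## Variants",
    "")
  if (nrow(r$variant_details)) {
    vd <- r$variant_details
    lines <- c(lines,
      "| locus | change | gene | AF | depth | category | reasons |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s:%d | %s>%s | %s | %.3f | %d | %s | %s |",
              vd$chrom, vd$pos + 1L, vd$ref, vd$alt,
              ifelse(is.na(vd$gene), "", vd$gene), vd$allele_frequency,
              vd$depth, vd$category, vd$reasons_str))
  } else {
    lines <- c(lines, "No reportable variants.")
  }
  lines <- c(lines, "", "## IHC validation requests", "")
  if (nrow(r$ihc_section$requests)) {
    rq <- r$ihc_section$requests
    lines <- c(lines, sprintf("- %s: %s (CN=%d, %.1f Mb)",
                              rq$symbol, rq$reason, rq$total_cn,
                              rq$event_size_mb))
  } else {
    lines <- c(lines, "None.")
  }
  c(lines, "",
    sprintf("Generated by %s %s on %s (thresholds %s)",
            r$provenance$tool, r$provenance$version, r$provenance$generated,
            r$provenance$threshold_hash))
}

.status_colors <- c(D = "#2166ac", L = "#92c5de", N = "#f7f7f7",
                    G = "#f4a582", A = "#b2182b")

.render_html <- function(r) {
  sr <- r$summary_rows
  cell <- sprintf("<td style=\"background:%s\">%s</td>",
                  .status_colors[sr$status_code], sr$status_code)
  rows <- sprintf("<tr><td>%s</td>%s<td>%s</td><td>%d</td></tr>",
                  sr$symbol, cell, ifelse(sr$loh, "yes", ""),
                  sr$mutation_count)
  vrows <- if (nrow(r$variant_details)) {
    vd <- r$variant_details
    sprintf("<tr><td>%s:%d %s&gt;%s</td><td>%s</td><td>%.3f</td><td>%d</td><td>%s</td><td>%s</td></tr>",
            vd$chrom, vd$pos + 1L, vd$ref, vd$alt,
            ifelse(is.na(vd$gene), "", vd$gene), vd$allele_frequency,
            vd$depth, vd$category, vd$reasons_str)
  } else character(0)
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>Report %s</title></head><body>", r$patient$pseudonym),
    sprintf("<h1>Molecular board report &mdash; %s</h1>", r$patient$pseudonym),
    sprintf("<p>Tumor type: %s | cellularity %.0f%% | %s</p>",
            r$patient$tumor_type, 100 * r$patient$cellularity,
            r$patient$ploidy_class),
    "<h2>Gene summary</h2>",
    "<table><tr><th>gene</th><th>CN</th><th>LOH</th><th>mutations</th></tr>",
    rows, "</table>",
    "<h2>Variants</h2>",
    "<table><tr><th>locus</th><th>gene</th><th>AF</th><th>depth</th><th>category</th><th>reasons</th></tr>",
    vrows, "</table>",
    sprintf("<p><small>%s %s | %s | thresholds %s</small></p>",
            r$provenance$tool, r$provenance$version, r$provenance$generated,
            r$provenance$threshold_hash),
    "</body></html>")
}

#' Build the pathologist IHC request document
#'
#' Lists exactly the genes whose calls require protein-level
#' validation, with locus, event size and copy number; valid (an empty
#' list) when no focal event qualifies.
#'
#' @param calls Gene calls ([call_genes()]).
#' @param thresholds A [status_thresholds()].
#' @param path Optional JSON output path.
#' @return List with `requests` (data.frame) and `n`.
#' @export
build_ihc_request_report <- function(calls, thresholds = status_thresholds(),
                                     path = NULL) {
  req <- ihc_requests(calls, thresholds)
  doc <- list(document = "ihc_validation_request", n = nrow(req),
              requests = req)
  if (!is.null(path)) {
    jsonlite::write_json(.canonicalize(doc, character()), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  doc
}
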