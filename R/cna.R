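#' Copy-number status levels and their one-letter report codes
#'
#' Statuses are ordered from deepest loss to strongest gain; the codes
#' (D, L, N, G, A) are the letters used in the board report's summary
#' table.
#'
#' @return Named character vector mapping status to code.
#' @export
status_codes <- function() {
  c(DELETION = "D", LOSS = "L", NORMAL = "N", GAIN = "G", AMPLIFICATION = "A")
}

# Rank distance from NORMAL used for "most extreme status wins".
.status_rank <- c(DELETION = -2L, LOSS = -1L, NORMAL = 0L, GAIN = 1L,
                  AMPLIFICATION = 2L)

#' Default thresholds for copy-number status assignment
#'
#' Encodes the clinical calling tables: for a diploid tumor, deletion =
#' 0 copies, loss = 1, normal = 2, gain = 3-5, amplification >= 6; for
#' a tetraploid tumor, deletion = 0, loss = 1-2, normal = 3-4, gain =
#' 5-6, amplification >= 7. Focal events are alterations under
#' `focal_max_size_mb` (10 Mb) elevated above their surroundings; focal
#' gains/amplifications of size in `[ihc_min_size_mb, ihc_max_size_mb)`
#' = \[1, 10) Mb over an IHC-validatable gene trigger a protein-level
#' validation request. Samples are processed only when strictly more
#' than `min_cellularity` (30%) of cells are tumor.
#'
#' @param diploid_amp_min,tetraploid_amp_min Smallest copy number
#'   called AMPLIFICATION per ploidy class.
#' @param focal_max_size_mb Focal-event size bound (Mb, exclusive).
#' @param ihc_min_size_mb,ihc_max_size_mb IHC trigger window (Mb,
#'   inclusive lower / exclusive upper).
#' @param min_cellularity QC gate (fraction; strict "more than").
#' @param ploidy_split Real ploidies below this use the diploid table,
#'   at or above it the tetraploid table.
#' @param strict_ploidy If TRUE, only ploidy 2 or 4 is accepted.
#' @return List of class `status_thresholds`.
#' @export
status_thresholds <- function(diploid_amp_min = 6L, tetraploid_amp_min = 7L,
                              focal_max_size_mb = 10, ihc_min_size_mb = 1,
                              ihc_max_size_mb = 10, min_cellularity = 0.30,
                              ploidy_split = 3, strict_ploidy = FALSE) {
  stopifnot(focal_max_size_mb > 0, ihc_min_size_mb >= 0,
            ihc_min_size_mb < ihc_max_size_mb,
            min_cellularity >= 0, min_cellularity <= 1)
  structure(list(diploid_amp_min = as.integer(diploid_amp_min),
                 tetraploid_amp_min = as.integer(tetraploid_amp_min),
                 focal_max_size_mb = focal_max_size_mb,
                 ihc_min_size_mb = ihc_min_size_mb,
                 ihc_max_size_mb = ihc_max_size_mb,
                 min_cellularity = min_cellularity,
                 ploidy_split = ploidy_split,
                 strict_ploidy = strict_ploidy),
            class = "status_thresholds")
}

#' Classify a real-valued tumor ploidy as diploid or tetraploid
#'
#' The calling tables are published for diploid and tetraploid tumors
#' only; real-valued ploidy estimates are binned at
#' `thresholds$ploidy_split` (default 3). In strict mode only exact
#' ploidies 2 and 4 are accepted.
#'
#' @param ploidy Positive real.
#' @param thresholds A [status_thresholds()].
#' @return "diploid" or "tetraploid".
#' @export
ploidy_class <- function(ploidy, thresholds = status_thresholds()) {
  if (is.na(ploidy) || ploidy <= 0) stop("ploidy must be > 0")
  if (thresholds$strict_ploidy && !ploidy %in% c(2, 4)) {
    stop("strict ploidy mode: ploidy must be exactly 2 or 4, got ", ploidy)
  }
  if (ploidy < thresholds$ploidy_split) "diploid" else "tetraploid"
}

#' Sample quality-control gate on cellularity
#'
#' Samples are analysed only when the biopsy contains strictly more
#' tumor cells than the gate fraction (default: more than 30%); below
#' or at the gate the tumor signal is too diluted for reliable
#' absolute copy-number calls.
#'
#' @param meta A [sample_meta()].
#' @param thresholds A [status_thresholds()].
#' @return List with `pass` (logical) and `reason` (`NA` or
#'   `"LOW_CELLULARITY"`).
#' @export
check_sample_qc <- function(meta, thresholds = status_thresholds()) {
  if (is.na(meta$cellularity)) stop("cellularity missing for sample ", meta$sample_id)
  if (meta$cellularity > thresholds$min_cellularity) {
    list(pass = TRUE, reason = NA_character_)
  } else {
    list(pass = FALSE, reason = "LOW_CELLULARITY")
  }
}

# round half away from zero (deterministic, unlike banker's rounding)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate absolute total copy number from a segment log ratio
#'
#' Inverts the two-population mixture model of the observed log R
#' ratio. With tumor-cell fraction c, tumor ploidy psi and tumor copy
#' number n, the expected log ratio is
#' \deqn{LRR = \log_2\frac{c\,n + 2(1-c)}{c\,\psi + 2(1-c)}}
#' so the estimate is
#' \eqn{n = (2^{LRR}(c\psi + 2(1-c)) - 2(1-c))/c}, rounded half away
#' from zero and clipped at 0.
#'
#' @param log_ratio Segment mean log2 R ratio (scalar or vector).
#' @param meta A [sample_meta()] providing cellularity and ploidy.
#' @return Integer copy number(s), >= 0.
#' @examples
#' m <- sample_meta("P1", "S1", cellularity = 0.5, ploidy = 2)
#' estimate_total_cn(1, m)   # 6 copies
#' @export
estimate_total_cn <- function(log_ratio, meta) {
  cc <- meta$cellularity
  if (is.na(cc) || cc <= 0) {
    stop("UNIDENTIFIABLE: copy number cannot be estimated with cellularity ", cc)
  }
  psi <- meta$ploidy
  n_raw <- (2^log_ratio * (cc * psi + 2 * (1 - cc)) - 2 * (1 - cc)) / cc
  n <- .round_half_away(n_raw)
  as.integer(pmax(0, n))
}

# Expected mirrored BAF (major-allele fraction folded to [0.5, 1]) for
# tumor genotype (total, minor) diluted by normal cells at cellularity c.
expected_mirrored_baf <- function(total_cn, minor_cn, cellularity) {
  denom <- cellularity * total_cn + 2 * (1 - cellularity)
  out <- (cellularity * (total_cn - minor_cn) + (1 - cellularity)) / denom
  out[rep_len(denom <= 0, length(out))] <- NA_real_
  out
}

#' Estimate the minor-allele copy number from a mirrored BAF
#'
#' Enumerates candidate minor copy numbers m in 0..floor(total/2) and
#' returns the one whose expected mirrored B-allele fraction under the
#' mixture model is closest to the observed value. The expected value
#' is strictly decreasing in m, so the argmin is unique; a missing
#' mirrored BAF (no heterozygous probes) yields NA.
#'
#' @param mirrored_baf Observed mean mirrored BAF in \[0.5, 1\], or NA.
#' @param meta A [sample_meta()].
#' @param total_cn Total copy number of the segment.
#' @return Integer minor copy number, or NA.
#' @export
estimate_minor_cn <- function(mirrored_baf, meta, total_cn) {
  if (is.na(mirrored_baf)) return(NA_integer_)
  if (total_cn < 0) stop("total_cn must be >= 0")
  m_cand <- 0:(total_cn %/% 2)
  expected <- expected_mirrored_baf(total_cn, m_cand, meta$cellularity)
  if (all(is.na(expected))) return(NA_integer_)
  as.integer(m_cand[which.min(abs(mirrored_baf - expected))])
}

#' Assign a copy-number status from an absolute copy number
#'
#' Applies the per-ploidy-class calling table: diploid — deletion = 0,
#' loss = 1, normal = 2, gain = 3-5, amplification >= 6; tetraploid —
#' deletion = 0, loss = 1-2, normal = 3-4, gain = 5-6, amplification
#' >= 7. Total over all non-negative integers and monotone in copy
#' number.
#'
#' @param total_cn Non-negative integer copy number (vectorised).
#' @param ploidy_class `"diploid"` or `"tetraploid"`.
#' @param thresholds A [status_thresholds()].
#' @return Character vector of statuses.
#' @export
assign_status <- function(total_cn, ploidy_class = c("diploid", "tetraploid"),
                          thresholds = status_thresholds()) {
  ploidy_class <- match.arg(ploidy_class)
  if (any(is.na(total_cn)) || any(total_cn < 0) || any(total_cn != floor(total_cn))) {
    stop("total_cn must be non-negative integers")
  }
  if (ploidy_class == "diploid") {
    amp_min <- thresholds$diploid_amp_min
    ifelse(total_cn == 0, "DELETION",
    ifelse(total_cn == 1, "LOSS",
    ifelse(total_cn == 2, "NORMAL",
    ifelse(total_cn < amp_min, "GAIN", "AMPLIFICATION"))))
  } else {
    amp_min <- thresholds$tetraploid_amp_min
    ifelse(total_cn == 0, "DELETION",
    ifelse(total_cn <= 2, "LOSS",
    ifelse(total_cn <= 4, "NORMAL",
    ifelse(total_cn < amp_min, "GAIN", "AMPLIFICATION"))))
  }
}

#' Annotate a profile's segments with absolute copy numbers and statuses
#'
#' Convenience wrapper running [estimate_total_cn()],
#' [estimate_minor_cn()], [assign_status()] and [detect_focal()] over
#' every segment of a profile.
#'
#' @param profile A [segmented_profile()].
#' @param thresholds A [status_thresholds()].
#' @return The segments data.frame augmented with `total_cn`,
#'   `minor_cn`, `status`, `loh`, `focal`, `size_mb`.
#' @export
call_segments <- function(profile, thresholds = status_thresholds()) {
  segs <- profile$segments
  meta <- profile$meta
  pc <- ploidy_class(meta$ploidy, thresholds)
  segs$total_cn <- estimate_total_cn(segs$log_ratio, meta)
  segs$minor_cn <- vapply(seq_len(nrow(segs)), function(i) {
    estimate_minor_cn(segs$mirrored_baf[i], meta, segs$total_cn[i])
  }, integer(1))
  segs$status <- assign_status(segs$total_cn, pc, thresholds)
  segs$loh <- !is.na(segs$minor_cn) & segs$minor_cn == 0 & segs$total_cn >= 1
  segs$size_mb <- (segs$end - segs$start) / 1e6
  segs$focal <- detect_focal(segs, thresholds)
  attr(segs, "sample_id") <- meta$sample_id
  segs
}

#' Flag focal gains and amplifications
#'
#' A segment is focal when it is a gain or amplification, spans
#' strictly less than `focal_max_size_mb` (10 Mb), and its copy number
#' strictly exceeds that of every immediately adjacent segment on the
#' same chromosome (a single neighbor at chromosome ends). Focal
#' events point at single driver genes rather than arm-level changes.
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `total_cn`,
#'   `status`, sorted by (chrom, start).
#' @param thresholds A [status_thresholds()].
#' @return Logical vector, one flag per segment.
#' @export
detect_focal <- function(segments, thresholds = status_thresholds()) {
  n <- nrow(segments)
  if (!n) return(logical(0))
  size_mb <- (segments$end - segments$start) / 1e6
  focal <- logical(n)
  for (i in seq_len(n)) {
    if (!segments$status[i] %in% c("GAIN", "AMPLIFICATION")) next
    if (size_mb[i] >= thresholds$focal_max_size_mb) next
    same <- which(segments$chrom == segments$chrom[i])
    pos <- match(i, same)
    nb <- c(if (pos > 1) same[pos - 1], if (pos < length(same)) same[pos + 1])
    if (length(nb) && all(segments$total_cn[i] > segments$total_cn[nb])) {
      focal[i] <- TRUE
    }
  }
  focal
}

#' Call per-gene copy-number status over a panel
#'
#' Every panel gene receives exactly one call. A gene overlapping
#' several segments takes the status of the most extreme one (largest
#' rank distance from NORMAL, so an actionable amplification or
#' deletion is never hidden by a breakpoint); ties are broken by the
#' larger overlap. Genes with no overlapping segment are reported
#' NORMAL with a `no_coverage` flag. The LOH flag, focality and event
#' size are inherited from the chosen segment.
#'
#' @param called_segments Output of [call_segments()].
#' @param panel A `gene_panel` data.frame ([read_panel()]).
#' @param thresholds A [status_thresholds()] (for the IHC window).
#' @return data.frame of gene calls: `symbol`, `chrom`, `start`, `end`,
#'   `pathway`, `ihc_validatable`, `total_cn`, `minor_cn`, `status`,
#'   `code`, `loh`, `focal`, `event_size_mb`, `no_coverage`,
#'   `ihc_required`.
#' @export
call_genes <- function(called_segments, panel, thresholds = status_thresholds()) {
  if (!nrow(panel)) stop("panel must be non-empty")
  codes <- status_codes()
  out <- lapply(seq_len(nrow(panel)), function(g) {
    ov <- interval_overlap(panel$chrom[g], panel$start[g], panel$end[g],
                           called_segments$chrom, called_segments$start,
                           called_segments$end)
    hit <- which(ov > 0)
    base <- data.frame(symbol = panel$symbol[g], chrom = panel$chrom[g],
                       start = panel$start[g], end = panel$end[g],
                       pathway = panel$pathway[g],
                       ihc_validatable = panel$ihc_validatable[g],
                       stringsAsFactors = FALSE)
    if (!length(hit)) {
      cbind(base, data.frame(total_cn = NA_integer_, minor_cn = NA_integer_,
                             status = "NORMAL", code = "N", loh = FALSE,
                             focal = FALSE, event_size_mb = NA_real_,
                             no_coverage = TRUE, stringsAsFactors = FALSE))
    } else {
      extremity <- abs(.status_rank[called_segments$status[hit]])
      best <- hit[order(-extremity, -ov[hit])][1]
      cbind(base, data.frame(
        total_cn = called_segments$total_cn[best],
        minor_cn = called_segments$minor_cn[best],
        status = called_segments$status[best],
        code = unname(codes[called_segments$status[best]]),
        loh = called_segments$loh[best],
        focal = called_segments$focal[best],
        event_size_mb = called_segments$size_mb[best],
        no_coverage = FALSE, stringsAsFactors = FALSE))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$ihc_required <- res$focal &
    res$status %in% c("GAIN", "AMPLIFICATION") &
    !is.na(res$event_size_mb) &
    res$event_size_mb >= thresholds$ihc_min_size_mb &
    res$event_size_mb < thresholds$ihc_max_size_mb &
    res$ihc_validatable
  attr(res, "sample_id") <- attr(called_segments, "sample_id", exact = TRUE)
  class(res) <- c("gene_cna_calls", "data.frame")
  res
}

#' Generate immunohistochemistry validation requests
#'
#' A gene is requested for IHC validation when its call is a focal
#' gain or amplification whose event size falls in the configured
#' window (default \[1, 10) Mb) and the gene is IHC-validatable. The
#' result is the automatically generated pathologist request list.
#'
#' @param calls Output of [call_genes()].
#' @param thresholds A [status_thresholds()].
#' @return data.frame with `symbol`, `chrom`, `start`, `end`, `status`,
#'   `total_cn`, `event_size_mb`, `reason`; sorted by symbol.
#' @export
ihc_requests <- function(calls, thresholds = status_thresholds()) {
  sel <- calls$focal &
    calls$status %in% c("GAIN", "AMPLIFICATION") &
    !is.na(calls$event_size_mb) &
    calls$event_size_mb >= thresholds$ihc_min_size_mb &
    calls$event_size_mb < thresholds$ihc_max_size_mb &
    calls$ihc_validatable
  req <- calls[sel, c("symbol", "chrom", "start", "end", "status",
                      "total_cn", "event_size_mb"), drop = FALSE]
  req <- req[order(req$symbol), , drop = FALSE]
  req$reason <- sprintf("focal %s of %.1f Mb", tolower(req$status),
                        req$event_size_mb)
  rownames(req) <- NULL
  req
}
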