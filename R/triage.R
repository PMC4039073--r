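#' Default thresholds for the somatic-variant triage cascade
#'
#' The filter set tuned for high specificity on an amplicon panel:
#' variants at annotated hotspots must reach 4% allele frequency (SNVs)
#' or 5% (indels); non-targeted coding variants face the stricter 10% /
#' 15%; coverage must reach 30X (SNVs) / 100X (indels); the
#' minority-strand fraction of alt reads must be at least 0.2.
#' Population polymorphisms above 1% in either reference cohort are
#' routed to the internal-control category, as are recurrent neutral
#' hotspot variants. Indel-prone sequence context (homopolymer runs of
#' 4+, tandem repeats of period 2-3 within +/-20 bp) triggers the
#' run-recurrence artifact check.
#'
#' @param snv_af_hotspot,indel_af_hotspot Minimum allele frequency at
#'   hotspots (inclusive).
#' @param snv_af_nontargeted,indel_af_nontargeted Minimum allele
#'   frequency for non-hotspot variants (inclusive).
#' @param min_strand_ratio Minimum minority-strand fraction (inclusive).
#' @param snv_min_depth,indel_min_depth Minimum total depth (inclusive).
#' @param polymorphism_max_pop_freq Population-frequency bound (strict
#'   "more than" routes to CONTROL).
#' @param homopolymer_min_run Minimum single-base run length.
#' @param repeat_window_bp Half-width of the reference window scanned.
#' @param recurrence_min_other_samples Other samples of the same run
#'   sharing the variant needed to discard a context-flagged variant.
#' @return List of class `triage_thresholds`.
#' @export
triage_thresholds <- function(snv_af_hotspot = 0.04, indel_af_hotspot = 0.05,
                              snv_af_nontargeted = 0.10,
                              indel_af_nontargeted = 0.15,
                              min_strand_ratio = 0.2,
                              snv_min_depth = 30L, indel_min_depth = 100L,
                              polymorphism_max_pop_freq = 0.01,
                              homopolymer_min_run = 4L,
                              repeat_window_bp = 20L,
                              recurrence_min_other_samples = 1L) {
  th <- list(snv_af_hotspot = snv_af_hotspot,
             indel_af_hotspot = indel_af_hotspot,
             snv_af_nontargeted = snv_af_nontargeted,
             indel_af_nontargeted = indel_af_nontargeted,
             min_strand_ratio = min_strand_ratio,
             snv_min_depth = as.integer(snv_min_depth),
             indel_min_depth = as.integer(indel_min_depth),
             polymorphism_max_pop_freq = polymorphism_max_pop_freq,
             homopolymer_min_run = as.integer(homopolymer_min_run),
             repeat_window_bp = as.integer(repeat_window_bp),
             recurrence_min_other_samples = as.integer(recurrence_min_other_samples))
  fracs <- c("snv_af_hotspot", "indel_af_hotspot", "snv_af_nontargeted",
             "indel_af_nontargeted", "min_strand_ratio",
             "polymorphism_max_pop_freq")
  stopifnot(all(unlist(th[fracs]) >= 0), all(unlist(th[fracs]) <= 1),
            th$snv_min_depth > 0, th$indel_min_depth > 0,
            th$snv_af_hotspot <= th$snv_af_nontargeted,
            th$indel_af_hotspot <= th$indel_af_nontargeted)
  structure(th, class = "triage_thresholds")
}

#' Classify a variant by its ref/alt allele lengths
#'
#' SNV for single-base substitutions, INS/DEL for length changes, MNV
#' for equal-length multi-base substitutions; routing between the SNV
#' and indel threshold sets depends on this class.
#'
#' @param ref,alt Allele strings (A/C/G/T only).
#' @return One of "SNV", "INS", "DEL", "MNV".
#' @export
classify_variant_class <- function(ref, alt) {
  if (!nchar(ref) || !nchar(alt) ||
      grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop("alleles must be non-empty ACGT strings, got ref='", ref,
         "' alt='", alt, "'")
  }
  if (nchar(ref) == 1 && nchar(alt) == 1) "SNV"
  else if (nchar(ref) < nchar(alt)) "INS"
  else if (nchar(ref) > nchar(alt)) "DEL"
  else "MNV"
}

#' Minority-strand fraction of alt-supporting reads
#'
#' `min(fwd, rev) / (fwd + rev)`, in \[0, 0.5\]; values near 0 indicate
#' the strand bias typical of sequencing artifacts.
#'
#' @param alt_fwd,alt_rev Alt read counts per strand.
#' @return Fraction in \[0, 0.5\].
#' @export
strand_ratio <- function(alt_fwd, alt_rev) {
  if (any(alt_fwd + alt_rev <= 0)) stop("no alt-supporting reads: strand ratio undefined")
  pmin(alt_fwd, alt_rev) / (alt_fwd + alt_rev)
}

#' Detect homopolymer or tandem-repeat context around a variant
#'
#' Scans the reference window around the variant: if a single-base run
#' of length >= `homopolymer_min_run` touches the variant's reference
#' span (including the immediately adjacent base, so an insertion at a
#' run boundary is caught), the context is HOMOPOLYMER; otherwise if a
#' tandem repeat of period 2 or 3 with at least 2 full copies (and a
#' non-degenerate unit) touches it, REPEAT; else NONE. These contexts
#' are the recurrent false-positive modes of ion semiconductor
#' sequencing.
#'
#' @param window Reference sequence string containing the variant.
#' @param at 1-based offset of the variant's first reference base
#'   within `window`.
#' @param ref Reference allele (its length defines the affected span).
#' @param thresholds A [triage_thresholds()].
#' @return "HOMOPOLYMER", "REPEAT" or "NONE".
#' @export
detect_context <- function(window, at, ref = "A",
                           thresholds = triage_thresholds()) {
  window <- toupper(window)
  n <- nchar(window)
  if (n < thresholds$homopolymer_min_run) {
    stop("reference window too short (", n, " bp) for homopolymer check")
  }
  if (at < 1 || at > n) stop("variant offset outside window")
  span <- c(max(1, at - 1), min(n, at + nchar(ref)))  # span +/- 1 bp
  chars <- strsplit(window, "")[[1]]

  # homopolymer runs
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hp <- which(r$lengths >= thresholds$homopolymer_min_run)
  for (k in hp) {
    if (starts[k] <= span[2] && ends[k] >= span[1]) return("HOMOPOLYMER")
  }

  # tandem repeats, period 2-3, >= 2 full copies, unit not a single base
  for (p in 2:3) {
    i <- 1
    while (i + 2 * p - 1 <= n) {
      unit <- substr(window, i, i + p - 1)
      if (length(unique(strsplit(unit, "")[[1]])) > 1) {
        k <- 1
        while (i + (k + 1) * p - 1 <= n &&
               substr(window, i + k * p, i + (k + 1) * p - 1) == unit) {
          k <- k + 1
        }
        if (k >= 2) {
          rep_end <- i + k * p - 1
          if (i <= span[2] && rep_end >= span[1]) return("REPEAT")
          i <- i + 1
        } else i <- i + 1
      } else i <- i + 1
    }
  }
  "NONE"
}

#' Annotate variant records against hotspot, polymorphism and
#' neutral-variant tables
#'
#' Exact-key joins on (chrom, pos, ref, alt). The hotspot table
#' supplies catalog identifiers for recurrently mutated cancer
#' positions; the population tables supply cohort allele frequencies
#' used by the polymorphism filter; the neutral table flags recurrent
#' hotspot variants with no therapeutic interest that serve as internal
#' sequencing controls. Unmatched records keep missing fields.
#'
#' @param records Variant-record data.frame ([read_vcf()]).
#' @param hotspots data.frame `chrom,pos,ref,alt,hotspot_id`
#'   (1-based pos).
#' @param popfreq_esp,popfreq_1kg data.frames `chrom,pos,ref,alt,freq`.
#' @param neutral data.frame `chrom,pos,ref,alt`.
#' @return `records` with `hotspot_id`, `pop_freq_esp`, `pop_freq_1kg`,
#'   `neutral_recurrent` populated.
#' @export
annotate_variants <- function(records, hotspots = NULL, popfreq_esp = NULL,
                              popfreq_1kg = NULL, neutral = NULL) {
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  rk <- key(records$chrom, records$pos + 1L, records$ref, records$alt)
  join <- function(tab, value_col) {
    if (length(setdiff(c("chrom", "pos", "ref", "alt", value_col), names(tab)))) {
      stop("annotation table missing required columns")
    }
    tk <- key(tab$chrom, tab$pos, tab$ref, tab$alt)
    if (anyNA(suppressWarnings(as.integer(tab$pos)))) {
      stop("malformed annotation table: non-integer position")
    }
    tab[[value_col]][match(rk, tk)]
  }
  if (!is.null(hotspots) && nrow(hotspots)) {
    records$hotspot_id <- as.character(join(hotspots, "hotspot_id"))
  }
  if (!is.null(popfreq_esp) && nrow(popfreq_esp)) {
    records$pop_freq_esp <- as.numeric(join(popfreq_esp, "freq"))
  }
  if (!is.null(popfreq_1kg) && nrow(popfreq_1kg)) {
    records$pop_freq_1kg <- as.numeric(join(popfreq_1kg, "freq"))
  }
  if (!is.null(neutral) && nrow(neutral)) {
    nk <- key(neutral$chrom, neutral$pos, neutral$ref, neutral$alt)
    records$neutral_recurrent <- rk %in% nk
  }
  records
}

#' Read an annotation table (hotspots, population frequencies, neutral
#' variants)
#'
#' Tab-separated with a header; `chrom`, `ref` and `alt` are forced to
#' character so allele values like "T" survive parsing intact.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in intersect(c("pos", "freq"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (nrow(df) && anyNA(v)) stop("malformed annotation table ", basename(path),
                                   ": non-numeric '", col, "'")
    df[[col]] <- v
  }
  df
}

#' Count run-level recurrence of each variant
#'
#' For every record, the number of *other* samples in the same
#' sequencing run carrying the identical (chrom, pos, ref, alt).
#' Variants recurring across samples of one run in artifact-prone
#' context are discarded as platform artifacts.
#'
#' @param records Variant-record data.frame for one or more runs.
#' @return Integer vector aligned with `records` rows.
#' @export
run_recurrence <- function(records) {
  if (!nrow(records)) return(integer(0))
  vkey <- paste(records$run_id, records$chrom, records$pos, records$ref,
                records$alt, sep = ":")
  # samples per (run, variant), minus self
  samples_per_variant <- tapply(records$sample_id, vkey,
                                function(s) length(unique(s)))
  out <- as.integer(samples_per_variant[vkey] - 1L)
  out
}

.triage_reason_order <- c("POLYMORPHISM", "NEUTRAL_RECURRENT", "LOW_FREQUENCY",
                          "LOW_DEPTH", "STRAND_BIAS", "HOMOPOLYMER_CONTEXT",
                          "REPEAT_CONTEXT", "RECURRENT_RUN_ARTIFACT",
                          "NON_TARGETED_STRICT", "NO_COSMIC_ID")

#' Triage one annotated variant through the filter cascade
#'
#' Applies the specificity-first rule cascade in fixed order:
#' \enumerate{
#'   \item population frequency above 1% in either cohort → CONTROL
#'     (POLYMORPHISM);
#'   \item recurrent neutral hotspot variant → CONTROL
#'     (NEUTRAL_RECURRENT) — good internal sequencing controls;
#'   \item allele frequency below the class- and targeting-appropriate
#'     bound (hotspot 4%/5%, non-targeted 10%/15%) → FILTERED
#'     (LOW_FREQUENCY);
#'   \item depth below 30X (SNV) / 100X (indel) → FILTERED (LOW_DEPTH);
#'   \item strand ratio below 0.2 → FILTERED (STRAND_BIAS);
#'   \item homopolymer/repeat context recurring in other samples of the
#'     run → FILTERED (RECURRENT_RUN_ARTIFACT);
#'   \item context-flagged but sample-specific → TO_DISCUSS (context
#'     reason);
#'   \item otherwise-passing non-hotspot variant → TO_DISCUSS
#'     (NO_COSMIC_ID);
#'   \item else POSITIVE.
#' }
#' The category is decided by the first rule that fires; the reasons
#' list accumulates every rule whose predicate holds, in cascade order,
#' so each decision is auditable.
#'
#' @param variant One-row variant record (annotated, context set).
#' @param recurrence_count Other same-run samples sharing the variant
#'   ([run_recurrence()]).
#' @param thresholds A [triage_thresholds()].
#' @return List with `category` and `reasons` (character vector).
#' @export
triage_variant <- function(variant, recurrence_count = 0L,
                           thresholds = triage_thresholds()) {
  v <- as.list(variant)
  needed <- c("variant_class", "allele_frequency", "depth", "alt_fwd",
              "alt_rev", "context")
  miss <- needed[!vapply(needed, function(f) !is.null(v[[f]]) && !is.na(v[[f]]),
                         logical(1))]
  if (length(miss)) {
    stop("cannot triage: missing required fields: ", paste(miss, collapse = ", "))
  }
  is_indel <- v$variant_class %in% c("INS", "DEL")
  is_hotspot <- !is.null(v$hotspot_id) && !is.na(v$hotspot_id)
  af_min <- if (is_hotspot) {
    if (is_indel) thresholds$indel_af_hotspot else thresholds$snv_af_hotspot
  } else {
    if (is_indel) thresholds$indel_af_nontargeted else thresholds$snv_af_nontargeted
  }
  depth_min <- if (is_indel) thresholds$indel_min_depth else thresholds$snv_min_depth
  ratio <- if (v$alt_fwd + v$alt_rev > 0) strand_ratio(v$alt_fwd, v$alt_rev) else 0
  ctx <- if (is.null(v$context) || is.na(v$context)) "NONE" else v$context
  ctx_reason <- switch(ctx, HOMOPOLYMER = "HOMOPOLYMER_CONTEXT",
                       REPEAT = "REPEAT_CONTEXT", NULL)

  pop <- c(v$pop_freq_esp, v$pop_freq_1kg)
  pop <- pop[!is.na(pop)]

  fired <- character(0)
  category <- NULL
  add <- function(reason, cat) {
    fired <<- c(fired, reason)
    if (is.null(category)) category <<- cat
  }
  if (length(pop) && any(pop > thresholds$polymorphism_max_pop_freq)) {
    add("POLYMORPHISM", "CONTROL")
  }
  if (isTRUE(v$neutral_recurrent)) add("NEUTRAL_RECURRENT", "CONTROL")
  if (v$allele_frequency < af_min) add("LOW_FREQUENCY", "FILTERED")
  if (v$depth < depth_min) add("LOW_DEPTH", "FILTERED")
  if (ratio < thresholds$min_strand_ratio) add("STRAND_BIAS", "FILTERED")
  if (!is.null(ctx_reason) &&
      recurrence_count >= thresholds$recurrence_min_other_samples) {
    add(ctx_reason, "FILTERED")
    add("RECURRENT_RUN_ARTIFACT", "FILTERED")
  } else if (!is.null(ctx_reason)) {
    add(ctx_reason, "TO_DISCUSS")
  }
  if (is.null(category) && !is_hotspot) add("NO_COSMIC_ID", "TO_DISCUSS")
  if (is.null(category)) category <- "POSITIVE"
  list(category = category, reasons = fired)
}

#' Triage a table of variant records
#'
#' Computes run-level recurrence set-wise (so the result is invariant
#' under input row order) and applies [triage_variant()] to each
#' record.
#'
#' @param records Annotated variant-record data.frame with `context`
#'   set.
#' @param thresholds A [triage_thresholds()].
#' @return `records` augmented with `strand_ratio_value`,
#'   `recurrence_count`, `category` and `reasons` (list column;
#'   also flattened to a `;`-separated `reasons_str`).
#' @export
triage_variants <- function(records, thresholds = triage_thresholds()) {
  if (!nrow(records)) {
    records$recurrence_count <- integer(0)
    records$category <- character(0)
    records$reasons <- list()
    records$reasons_str <- character(0)
    return(records)
  }
  rec <- run_recurrence(records)
  res <- lapply(seq_len(nrow(records)), function(i) {
    triage_variant(records[i, ], rec[i], thresholds)
  })
  records$strand_ratio_value <- ifelse(
    records$alt_fwd + records$alt_rev > 0,
    pmin(records$alt_fwd, records$alt_rev) /
      (records$alt_fwd + records$alt_rev), NA_real_)
  records$recurrence_count <- rec
  records$category <- vapply(res, `[[`, "", "category")
  records$reasons <- lapply(res, `[[`, "reasons")
  records$reasons_str <- vapply(records$reasons, paste, "", collapse = ";")
  records
}

#' Write triage results as TSV
#'
#' @param triaged Output of [triage_variants()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_triage_tsv <- function(triaged, path) {
  cols <- c("chrom", "pos", "ref", "alt", "variant_class", "sample_id",
            "run_id", "allele_frequency", "depth", "alt_fwd", "alt_rev",
            "strand_ratio_value", "gene", "consequence", "hotspot_id",
            "pop_freq_esp", "pop_freq_1kg", "context", "recurrence_count",
            "category", "reasons_str")
  out <- triaged[, intersect(cols, names(triaged)), drop = FALSE]
  out$pos <- out$pos + 1L  # 1-based at the boundary
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
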