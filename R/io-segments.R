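#' Construct a segmented copy-number profile
#'
#' A profile is the per-sample output of upstream log-R-ratio
#' segmentation: non-overlapping genomic segments, each summarised by a
#' mean log2 R ratio and (where heterozygous probes were available) a
#' mean mirrored B-allele fraction in \[0.5, 1\].
#'
#' @param meta A [sample_meta()] object.
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `n_probes`, `log_ratio`, `mirrored_baf`
#'   (NA allowed).
#' @return A `segmented_profile` object; segments sorted by
#'   (chromosome, start) and validated non-overlapping.
#' @export
segmented_profile <- function(meta, segments) {
  stopifnot(inherits(meta, "sample_meta"))
  required <- c("chrom", "start", "end", "n_probes", "log_ratio", "mirrored_baf")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols)) {
    stop("segments missing columns: ", paste(missing_cols, collapse = ", "))
  }
  segments <- as.data.frame(segments)[required]
  segments$chrom <- as.character(segments$chrom)
  if (nrow(segments)) {
    bad_chrom <- setdiff(unique(segments$chrom), assembly_chromosomes())
    if (length(bad_chrom)) stop("unknown chromosome(s): ", paste(bad_chrom, collapse = ", "))
    if (any(segments$start < 0 | segments$start >= segments$end)) {
      stop("invalid segment coordinates: require 0 <= start < end")
    }
    if (any(is.na(segments$n_probes)) || any(segments$n_probes < 1)) {
      stop("n_probes must be >= 1 for every segment")
    }
    mb <- segments$mirrored_baf
    if (any(!is.na(mb) & (mb < 0.5 | mb > 1))) {
      stop("mirrored_baf must lie in [0.5, 1] (or be NA)")
    }
    ord <- order(match(segments$chrom, assembly_chromosomes()), segments$start)
    segments <- segments[ord, , drop = FALSE]
    rownames(segments) <- NULL
    for (chr in unique(segments$chrom)) {
      s <- segments[segments$chrom == chr, , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
        stop("overlapping segments on chromosome ", chr)
      }
    }
  }
  structure(list(meta = meta, segments = segments), class = "segmented_profile")
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat("Segmented profile:", x$meta$sample_id, "-", nrow(x$segments), "segments\n")
  invisible(x)
}

.seg_columns <- c("chrom", "start", "end", "n_probes", "log_ratio", "mirrored_baf")

#' Read a segmented profile from a tab-separated file
#'
#' Two dialects are supported. `internal_tsv` stores 0-based half-open
#' coordinates; `seg_1based` stores 1-based inclusive coordinates (the
#' common SEG convention) and is converted at read time
#' (`start - 1`, `end` unchanged). Both share the header
#' `chrom start end n_probes log_ratio mirrored_baf`.
#'
#' @param path File path.
#' @param meta A [sample_meta()] attached to the profile.
#' @param dialect `"internal_tsv"` or `"seg_1based"`.
#' @return A [segmented_profile()].
#' @export
read_segments <- function(path, meta, dialect = c("internal_tsv", "seg_1based")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file (header required): ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .seg_columns)) {
    stop("header does not match the '", dialect, "' dialect; expected: ",
         paste(.seg_columns, collapse = "\t"))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 6) {
      stop("malformed row at line ", i + 1L, ": expected 6 fields, got ",
           length(fields))
    }
    num <- suppressWarnings(as.numeric(fields[2:5]))
    if (anyNA(num)) stop("malformed row at line ", i + 1L, ": non-numeric field")
    mb <- if (fields[6] %in% c("NA", ".", "")) NA_real_ else {
      v <- suppressWarnings(as.numeric(fields[6]))
      if (is.na(v)) stop("malformed row at line ", i + 1L, ": bad mirrored_baf")
      v
    }
    data.frame(chrom = fields[1], start = num[1], end = num[2],
               n_probes = num[3], log_ratio = num[4], mirrored_baf = mb)
  })
  segs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_probes = numeric(), log_ratio = numeric(),
               mirrored_baf = numeric())
  if (dialect == "seg_1based" && nrow(segs)) segs$start <- segs$start - 1
  segmented_profile(meta, segs)
}

#' Write a segmented profile
#'
#' @param profile A [segmented_profile()].
#' @param path Output path.
#' @param dialect Coordinate dialect, as in [read_segments()].
#' @return Invisibly, `path`.
#' @export
write_segments <- function(profile, path,
                           dialect = c("internal_tsv", "seg_1based")) {
  dialect <- match.arg(dialect)
  segs <- profile$segments
  out <- segs
  if (dialect == "seg_1based" && nrow(out)) out$start <- out$start + 1
  lines <- c(paste(.seg_columns, collapse = "\t"),
             if (nrow(out)) apply(out, 1, function(r) {
               paste(c(r[["chrom"]],
                       format(as.numeric(r[2:5]), scientific = FALSE, trim = TRUE),
                       if (is.na(r[["mirrored_baf"]])) "NA" else r[["mirrored_baf"]]),
                     collapse = "\t")
             }))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata from TSV or JSON
#'
#' TSV requires a header with the `sample_meta` field names; JSON is an
#' object keyed by the same names. Dates are ISO-8601.
#'
#' @param path File path ending in `.json` or a tab-separated file.
#' @return A [sample_meta()].
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) != 1) stop("sample metadata TSV must contain exactly one row")
    x <- as.list(df[1, ])
  }
  need <- c("patient_pseudonym", "sample_id", "cellularity", "ploidy")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sample metadata missing fields: ", paste(miss, collapse = ", "))
  sample_meta(
    patient_pseudonym = x$patient_pseudonym,
    sample_id = x$sample_id,
    run_id = if (is.null(x$run_id)) x$sample_id else x$run_id,
    cellularity = x$cellularity,
    ploidy = x$ploidy,
    biopsy_date = if (is.null(x$biopsy_date)) NA else x$biopsy_date,
    data_received_date = if (is.null(x$data_received_date)) NA else x$data_received_date
  )
}
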