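#' Chromosome names of the default assembly
#'
#' The pipeline treats the genome build as a configuration string; the
#' default chromosome set is the human autosomes plus X and Y.
#'
#' @param build Genome build label (kept as provenance only).
#' @return Character vector of chromosome names ("1".."22", "X", "Y").
#' @export
assembly_chromosomes <- function(build = "hg19") {
  c(as.character(1:22), "X", "Y")
}

# Approximate chromosome lengths (bp) used by the simulator; order matches
# assembly_chromosomes().
.chrom_lengths <- c(
  249e6, 243e6, 198e6, 191e6, 181e6, 171e6, 159e6, 146e6, 141e6, 136e6,
  135e6, 134e6, 115e6, 107e6, 103e6, 90e6, 81e6, 78e6, 59e6, 63e6,
  48e6, 51e6, 155e6, 59e6
)

chromosome_length <- function(chrom) {
  idx <- match(as.character(chrom), assembly_chromosomes())
  if (anyNA(idx)) {
    stop("unknown chromosome: ", paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  .chrom_lengths[idx]
}

#' Construct a genomic interval
#'
#' Internal coordinates are 0-based half-open: `start` is the 0-based
#' position of the first base, `end` is one past the last base, so
#' `interval_length()` is simply `end - start`. External formats (SEG,
#' BED, VCF) are converted at the I/O boundary.
#'
#' @param chrom Chromosome name, one of [assembly_chromosomes()].
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @return A `genomic_interval` object (a named list).
#' @examples
#' gi <- genomic_interval("17", 37844000, 37886000)
#' interval_length(gi)
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  if (!chrom %in% assembly_chromosomes()) {
    stop("chrom must be one of the assembly chromosomes, got: ", chrom)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d (%s bp)\n", x$chrom, x$start, x$end,
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

# Width of the overlap between two half-open intervals on the same
# chromosome; 0 when disjoint or on different chromosomes.
interval_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ifelse(chrom1 == chrom2,
         pmax(0, pmin(end1, end2) - pmax(start1, start2)),
         0)
}

#' Sample metadata
#'
#' Per-sample clinical and technical metadata carried through the
#' pipeline. Cellularity is the tumor-cell fraction of the biopsy;
#' ploidy is the tumor's average copies per locus (both typically
#' estimated upstream from the allele-specific copy-number fit).
#'
#' @param patient_pseudonym Opaque, name-blinded patient identifier.
#' @param sample_id Sample identifier.
#' @param run_id Sequencing/array run identifier.
#' @param cellularity Tumor-cell fraction in \[0, 1\].
#' @param ploidy Positive real, tumor average copies per locus.
#' @param biopsy_date,data_received_date Dates (coerced with `as.Date`).
#' @return A `sample_meta` object.
#' @export
sample_meta <- function(patient_pseudonym, sample_id, run_id = sample_id,
                        cellularity, ploidy = 2,
                        biopsy_date = NA, data_received_date = NA) {
  cellularity <- as.numeric(cellularity)
  ploidy <- as.numeric(ploidy)
  if (!is.na(cellularity) && (cellularity < 0 || cellularity > 1)) {
    stop("cellularity must be in [0, 1], got ", cellularity)
  }
  if (is.na(ploidy) || ploidy <= 0) stop("ploidy must be > 0")
  structure(list(
    patient_pseudonym = as.character(patient_pseudonym),
    sample_id = as.character(sample_id),
    run_id = as.character(run_id),
    cellularity = cellularity,
    ploidy = ploidy,
    biopsy_date = if (is.na(biopsy_date[1])) as.Date(NA) else as.Date(biopsy_date),
    data_received_date = if (is.na(data_received_date[1])) as.Date(NA) else as.Date(data_received_date)
  ), class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat("Sample", x$sample_id, "(patient", x$patient_pseudonym, ")\n")
  cat(sprintf("  run %s | cellularity %.2f | ploidy %.2f\n",
              x$run_id, x$cellularity, x$ploidy))
  invisible(x)
}
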