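#' Annotate variant records with sequence context from a reference FASTA
#'
#' Extracts the +/- `repeat_window_bp` reference window around each
#' variant (via \pkg{Biostrings}) and runs [detect_context()] on it.
#' FASTA sequence names must match the records' chromosome names.
#'
#' @param records Variant-record data.frame (0-based `pos`).
#' @param fasta_path Reference FASTA path.
#' @param thresholds A [triage_thresholds()].
#' @return `records` with the `context` column set.
#' @export
context_from_fasta <- function(records, fasta_path,
                               thresholds = triage_thresholds()) {
  if (!nrow(records)) return(records)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  w <- thresholds$repeat_window_bp
  records$context <- vapply(seq_len(nrow(records)), function(i) {
    chrom <- records$chrom[i]
    if (!chrom %in% names(seqs)) {
      stop("chromosome '", chrom, "' not in reference: ", fasta_path)
    }
    len <- Biostrings::nchar(seqs[[chrom]])
    pos1 <- records$pos[i] + 1L  # 1-based within contig
    if (pos1 < 1 || pos1 > len) stop("variant locus outside reference sequence")
    lo <- max(1L, pos1 - w)
    hi <- min(len, pos1 + nchar(records$ref[i]) - 1L + w)
    window <- as.character(Biostrings::subseq(seqs[[chrom]], lo, hi))
    detect_context(window, at = pos1 - lo + 1L, ref = records$ref[i],
                   thresholds = thresholds)
  }, "")
  records
}
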