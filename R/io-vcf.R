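#' FORMAT-key dialect for variant files
#'
#' Amplicon callers differ in how they encode depth and per-strand alt
#' counts; the dialect maps the pipeline's required quantities onto
#' FORMAT keys. The defaults match Ion Torrent-style output: total
#' depth `DP`, alt observations `AO`, forward/reverse alt counts
#' `SAF`/`SAR`. Setting `alt_obs = "AD"` switches to the
#' ref,alt-ordered allelic-depth convention.
#'
#' @param depth,alt_obs,alt_fwd,alt_rev FORMAT key names.
#' @return A named list of class `vcf_dialect`.
#' @export
vcf_dialect <- function(depth = "DP", alt_obs = "AO",
                        alt_fwd = "SAF", alt_rev = "SAR") {
  structure(list(depth = depth, alt_obs = alt_obs,
                 alt_fwd = alt_fwd, alt_rev = alt_rev),
            class = "vcf_dialect")
}

# Empty variant-record table with the full column contract.
empty_variant_records <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), variant_class = character(),
             sample_id = character(), run_id = character(),
             depth = integer(), alt_fwd = integer(), alt_rev = integer(),
             allele_frequency = numeric(), gene = character(),
             consequence = character(), hotspot_id = character(),
             pop_freq_esp = numeric(), pop_freq_1kg = numeric(),
             neutral_recurrent = logical(), context = character(),
             stringsAsFactors = FALSE)
}

.parse_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read variant records from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into the flat variant-record
#' table the triage cascade consumes: one row per sample and per alt
#' allele (multi-allelic sites are decomposed). Positions are converted
#' to the internal 0-based convention. The per-allele allele frequency
#' is alt observations / total depth.
#'
#' @param path VCF file path.
#' @param run_id Run identifier attached to every record.
#' @param dialect A [vcf_dialect()].
#' @return data.frame of variant records (annotation columns NA until
#'   [annotate_variants()] is applied; `context` is "NONE" until
#'   [detect_context()] is applied).
#' @export
read_vcf <- function(path, run_id = "run1", dialect = vcf_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) return(empty_variant_records())
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  for (k in unlist(dialect)) {
    if (!k %in% fmt_keys) {
      if (k %in% c(dialect$alt_fwd, dialect$alt_rev)) {
        stop("strand counts unavailable: FORMAT key '", k,
             "' not present (dialect: ",
             paste(names(dialect), unlist(dialect), sep = "=", collapse = ", "), ")")
      }
      stop("missing required FORMAT key '", k, "' (dialect: ",
           paste(names(dialect), unlist(dialect), sep = "=", collapse = ", "), ")")
    }
  }
  samples <- colnames(v@gt)[-1]
  get_fmt <- function(key) vcfR::extract.gt(v, element = key)
  dp <- get_fmt(dialect$depth)
  ao <- get_fmt(dialect$alt_obs)
  saf <- get_fmt(dialect$alt_fwd)
  sar <- get_fmt(dialect$alt_rev)

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- if (is.null(fix$INFO)) NA_character_ else fix$INFO[i]
    gene <- .parse_info_field(info, "GENE")
    conseq <- .parse_info_field(info, "CONSEQ")
    for (s in samples) {
      nth <- function(x, a, offset = 0L) {
        parts <- strsplit(as.character(x), ",", fixed = TRUE)[[1]]
        as.integer(parts[min(length(parts), a + offset)])
      }
      for (a in seq_along(alts)) {
        depth_i <- as.integer(strsplit(as.character(dp[i, s]), ",")[[1]][1])
        # AD convention lists the ref allele first
        ao_i <- nth(ao[i, s], a, offset = if (dialect$alt_obs == "AD") 1L else 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = sub("^chr", "", fix$CHROM[i]),
          pos = as.integer(fix$POS[i]) - 1L,
          ref = fix$REF[i], alt = alts[a],
          variant_class = classify_variant_class(fix$REF[i], alts[a]),
          sample_id = s, run_id = run_id,
          depth = depth_i,
          alt_fwd = nth(saf[i, s], a), alt_rev = nth(sar[i, s], a),
          allele_frequency = ao_i / depth_i,
          gene = gene, consequence = conseq,
          hotspot_id = NA_character_, pop_freq_esp = NA_real_,
          pop_freq_1kg = NA_real_, neutral_recurrent = FALSE,
          context = "NONE", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- which(out$alt_fwd + out$alt_rev > out$depth)
  if (length(bad)) {
    stop("alt strand counts exceed depth at ", out$chrom[bad[1]], ":",
         out$pos[bad[1]] + 1L)
  }
  out
}

#' Write variant records to a single-sample VCF file
#'
#' Emits a minimal VCF 4.2 whose FORMAT fields follow `dialect`;
#' reading the result back with [read_vcf()] reproduces the record
#' fields the pipeline uses.
#'
#' @param records Variant-record data.frame for one sample.
#' @param path Output path.
#' @param dialect A [vcf_dialect()] (only the default AO-style keys are
#'   written).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(records, path, dialect = vcf_dialect()) {
  sample_ids <- unique(records$sample_id)
  if (length(sample_ids) > 1) {
    stop("write_vcf writes one sample per file; got ",
         length(sample_ids), " samples")
  }
  sid <- if (length(sample_ids)) sample_ids else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mtbpipe",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Total read depth\">", dialect$depth),
    sprintf("##FORMAT=<ID=%s,Number=A,Type=Integer,Description=\"Alt allele observations\">", dialect$alt_obs),
    sprintf("##FORMAT=<ID=%s,Number=A,Type=Integer,Description=\"Alt observations on the forward strand\">", dialect$alt_fwd),
    sprintf("##FORMAT=<ID=%s,Number=A,Type=Integer,Description=\"Alt observations on the reverse strand\">", dialect$alt_rev),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Coding consequence\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sid), collapse = "\t")
  )
  body <- character(0)
  if (nrow(records)) {
    info <- ifelse(is.na(records$gene), ".",
                   paste0("GENE=", records$gene,
                          ifelse(is.na(records$consequence), "",
                                 paste0(";CONSEQ=", records$consequence))))
    ao <- records$alt_fwd + records$alt_rev
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\t%s\t%s",
                    records$chrom, records$pos + 1L, records$ref, records$alt,
                    info,
                    paste(dialect$depth, dialect$alt_obs, dialect$alt_fwd,
                          dialect$alt_rev, sep = ":"),
                    paste(records$depth, ao, records$alt_fwd, records$alt_rev,
                          sep = ":"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
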