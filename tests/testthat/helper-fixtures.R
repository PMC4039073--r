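# shared fixture builders; everything is generated in code at test time

mk_meta <- function(cellularity = 0.6, ploidy = 2, sample_id = "S01",
                    run_id = "RUN1", patient = "P-TEST") {
  sample_meta(patient, sample_id, run_id, cellularity, ploidy,
              biopsy_date = "2026-01-01", data_received_date = "2026-01-05")
}

# three-gene toy panel written as BED-plus and read back through the parser
toy_panel_path <- function(dir = tempfile("panel")) {
  dir.create(dir, showWarnings = FALSE)
  p <- file.path(dir, "toy_panel.bed")
  writeLines(c(
    "17\t37840000\t37890000\tERBB2\tMAPK\t1",
    "12\t25360000\t25400000\tKRAS\tMAPK\t0",
    "3\t178860000\t178960000\tPIK3CA\tPI3K_AKT_MTOR\t0"
  ), p)
  p
}
toy_panel <- function() read_panel(toy_panel_path())

# a minimal triage-ready variant record (list form accepted by triage_variant)
mk_variant <- function(variant_class = "SNV", allele_frequency = 0.10,
                       depth = 1000L, alt_fwd = NULL, alt_rev = NULL,
                       strand_ratio = 0.5, hotspot = TRUE,
                       pop_freq_esp = NA_real_, pop_freq_1kg = NA_real_,
                       neutral_recurrent = FALSE, context = "NONE") {
  if (is.null(alt_fwd)) {
    # build strand counts realising the requested minority fraction
    total <- 100L
    alt_fwd <- as.integer(round(total * (1 - strand_ratio)))
    alt_rev <- total - alt_fwd
  }
  list(variant_class = variant_class, allele_frequency = allele_frequency,
       depth = depth, alt_fwd = alt_fwd, alt_rev = alt_rev,
       hotspot_id = if (hotspot) "COSM00001" else NA_character_,
       pop_freq_esp = pop_freq_esp, pop_freq_1kg = pop_freq_1kg,
       neutral_recurrent = neutral_recurrent, context = context)
}

# Independent brute-force evaluator of the triage rules, written as a
# plain transcription of the filter definitions (kept deliberately
# separate from the package's cascade).
oracle_triage <- function(v, recurrence, th = triage_thresholds()) {
  indel <- v$variant_class %in% c("INS", "DEL")
  hot <- !is.na(v$hotspot_id)
  reasons <- character(0)
  category <- NA_character_
  note <- function(r, cat) {
    reasons <<- c(reasons, r)
    if (is.na(category)) category <<- cat
  }
  pop_hit <- (!is.na(v$pop_freq_esp) && v$pop_freq_esp > th$polymorphism_max_pop_freq) ||
    (!is.na(v$pop_freq_1kg) && v$pop_freq_1kg > th$polymorphism_max_pop_freq)
  if (pop_hit) note("POLYMORPHISM", "CONTROL")
  if (isTRUE(v$neutral_recurrent)) note("NEUTRAL_RECURRENT", "CONTROL")
  af_th <- if (hot && !indel) th$snv_af_hotspot else
    if (hot && indel) th$indel_af_hotspot else
      if (!hot && !indel) th$snv_af_nontargeted else th$indel_af_nontargeted
  if (v$allele_frequency < af_th) note("LOW_FREQUENCY", "FILTERED")
  if (v$depth < (if (indel) th$indel_min_depth else th$snv_min_depth)) {
    note("LOW_DEPTH", "FILTERED")
  }
  sr <- min(v$alt_fwd, v$alt_rev) / (v$alt_fwd + v$alt_rev)
  if (sr < th$min_strand_ratio) note("STRAND_BIAS", "FILTERED")
  if (v$context != "NONE") {
    ctx_r <- if (v$context == "HOMOPOLYMER") "HOMOPOLYMER_CONTEXT" else "REPEAT_CONTEXT"
    if (recurrence >= th$recurrence_min_other_samples) {
      note(ctx_r, "FILTERED"); note("RECURRENT_RUN_ARTIFACT", "FILTERED")
    } else note(ctx_r, "TO_DISCUSS")
  }
  if (is.na(category) && !hot) note("NO_COSMIC_ID", "TO_DISCUSS")
  if (is.na(category)) category <- "POSITIVE"
  list(category = category, reasons = reasons)
}

# write a segments TSV (internal dialect) from a data.frame
write_seg_file <- function(df, path = tempfile(fileext = ".tsv")) {
  lines <- c("chrom\tstart\tend\tn_probes\tlog_ratio\tmirrored_baf",
             sprintf("%s\t%s\t%s\t%s\t%s\t%s", df$chrom,
                     format(df$start, scientific = FALSE, trim = TRUE),
                     format(df$end, scientific = FALSE, trim = TRUE),
                     df$n_probes, df$log_ratio,
                     ifelse(is.na(df$mirrored_baf), "NA", df$mirrored_baf)))
  writeLines(lines, path)
  path
}

# segment table ready for detect_focal / call_genes
mk_called_segments <- function(chrom, start, end, total_cn,
                               ploidy_class = "diploid", minor_cn = NA,
                               sample_id = "S01") {
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   total_cn = as.integer(total_cn),
                   minor_cn = as.integer(minor_cn),
                   stringsAsFactors = FALSE)
  df$status <- assign_status(df$total_cn, ploidy_class)
  df$loh <- !is.na(df$minor_cn) & df$minor_cn == 0 & df$total_cn >= 1
  df$size_mb <- (df$end - df$start) / 1e6
  df$focal <- detect_focal(df)
  attr(df, "sample_id") <- sample_id
  df
}

# a small standard variant-spec table for run simulations: planted
# categories with allele fractions far from every threshold so binomial
# sampling cannot flip a class
mk_run_variant_spec <- function(n = 10, n_samples = 8) {
  kinds <- rep(c("positive", "low_freq", "polymorphism", "neutral",
                 "homopolymer_shared", "repeat_private", "nontargeted",
                 "strand_bias", "low_depth", "positive_indel"),
               length.out = n)
  pos <- 100 + seq_len(n) * 60  # spaced beyond the context window
  data.frame(
    chrom = rep(c("7", "12", "3", "17"), length.out = n),
    pos = pos,
    ref = ifelse(kinds == "positive_indel", "A", "C"),
    alt = ifelse(kinds == "positive_indel", "AGG",
                 ifelse(kinds == "homopolymer_shared", "T", "G")),
    true_af = c(positive = 0.20, low_freq = 0.005, polymorphism = 0.30,
                neutral = 0.30, homopolymer_shared = 0.30,
                repeat_private = 0.30, nontargeted = 0.40,
                strand_bias = 0.20, low_depth = 0.20,
                positive_indel = 0.30)[kinds],
    depth = ifelse(kinds == "low_depth", 20L, 600L),
    strand_fwd_frac = ifelse(kinds == "strand_bias", 0.97, 0.5),
    context_kind = ifelse(kinds == "homopolymer_shared", "HOMOPOLYMER",
                          ifelse(kinds == "repeat_private", "REPEAT", "NONE")),
    n_samples_sharing = ifelse(kinds == "homopolymer_shared", 3L, 1L),
    hotspot = !kinds %in% c("nontargeted", "polymorphism"),
    pop_freq_esp = ifelse(kinds == "polymorphism", 0.05, NA_real_),
    pop_freq_1kg = NA_real_,
    neutral = kinds == "neutral",
    gene = rep(c("BRAF", "KRAS", "PIK3CA", "ERBB2"), length.out = n),
    consequence = "MISSENSE",
    kind = kinds,
    stringsAsFactors = FALSE)
}
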