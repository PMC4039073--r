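test_that("variant classes follow allele lengths", {
  expect_equal(classify_variant_class("A", "T"), "SNV")
  expect_equal(classify_variant_class("A", "AGG"), "INS")
  expect_equal(classify_variant_class("AGG", "A"), "DEL")
  expect_equal(classify_variant_class("ACGT", "AGGT"), "MNV")
  expect_error(classify_variant_class("A", "N"), "ACGT")
  expect_error(classify_variant_class("", "A"))
})

test_that("strand ratio is the minority fraction of alt reads", {
  expect_equal(strand_ratio(10, 10), 0.5)
  expect_equal(strand_ratio(20, 5), 0.2)
  expect_equal(strand_ratio(24, 1), 0.04)
  expect_error(strand_ratio(0, 0), "undefined")
})

test_that("sequence context detection finds homopolymers and short repeats", {
  expect_equal(detect_context("TTAAAAAC", 4, "A"), "HOMOPOLYMER")
  expect_equal(detect_context("ACACACGT", 3, "A"), "REPEAT")
  expect_equal(detect_context("ACGTACGA", 2, "C"), "NONE")  # period 4 only
  # run adjacent to an insertion point still counts
  expect_equal(detect_context("CGTAAAAG", 3, "T"), "HOMOPOLYMER")
  # distant motifs do not contaminate the call
  expect_equal(detect_context("AAAAACGTCGTACGTACGATCGATCGGC", 20, "T"), "NONE")
  expect_error(detect_context("ACG", 1, "A"), "too short")
})

test_that("annotation joins are exact-key and leave misses missing", {
  recs <- data.frame(chrom = c("7", "7", "3"), pos = c(100L, 200L, 300L),
                     ref = "A", alt = "T", hotspot_id = NA_character_,
                     pop_freq_esp = NA_real_, pop_freq_1kg = NA_real_,
                     neutral_recurrent = FALSE, stringsAsFactors = FALSE)
  hot <- data.frame(chrom = "7", pos = 101, ref = "A", alt = "T",
                    hotspot_id = "COSM7")
  kg <- data.frame(chrom = "7", pos = 201, ref = "A", alt = "T", freq = 0.025)
  out <- annotate_variants(recs, hotspots = hot, popfreq_1kg = kg)
  expect_equal(out$hotspot_id, c("COSM7", NA, NA))
  expect_equal(out$pop_freq_1kg, c(NA, 0.025, NA))
  expect_true(all(is.na(out$pop_freq_esp)))
})

test_that("run recurrence counts other samples in the same run only", {
  recs <- data.frame(
    chrom = "7", pos = 100L, ref = "A", alt = "T",
    sample_id = c("S1", "S2", "S3", "S4", "S1"),
    run_id = c("RUN1", "RUN1", "RUN1", "RUN2", "RUN1"),
    stringsAsFactors = FALSE)
  recs$pos[5] <- 999L  # S1's second variant is private
  counts <- run_recurrence(recs)
  expect_equal(counts, c(2L, 2L, 2L, 0L, 0L))
})

test_that("triage reproduces the published decision boundaries", {
  # all filters satisfied
  expect_equal(triage_variant(mk_variant(allele_frequency = 0.05))$category,
               "POSITIVE")
  expect_length(triage_variant(mk_variant(allele_frequency = 0.05))$reasons, 0)
  # hotspot SNV below 4%
  r <- triage_variant(mk_variant(allele_frequency = 0.03))
  expect_equal(r$category, "FILTERED")
  expect_equal(r$reasons, "LOW_FREQUENCY")
  # non-hotspot missense below 10%
  r <- triage_variant(mk_variant(allele_frequency = 0.08, depth = 400,
                                 strand_ratio = 0.4, hotspot = FALSE))
  expect_equal(r$category, "FILTERED")
  expect_true("LOW_FREQUENCY" %in% r$reasons)
  # common polymorphism
  r <- triage_variant(mk_variant(pop_freq_esp = 0.02))
  expect_equal(r$category, "CONTROL")
  expect_equal(r$reasons[1], "POLYMORPHISM")
  # neutral recurrent hotspot variant is an internal control
  r <- triage_variant(mk_variant(neutral_recurrent = TRUE))
  expect_equal(r$category, "CONTROL")
  # homopolymer indel recurring in the run accumulates both reasons
  r <- triage_variant(mk_variant("INS", allele_frequency = 0.06, depth = 300,
                                 strand_ratio = 0.3,
                                 context = "HOMOPOLYMER"),
                      recurrence_count = 2)
  expect_equal(r$category, "FILTERED")
  expect_equal(r$reasons, c("HOMOPOLYMER_CONTEXT", "RECURRENT_RUN_ARTIFACT"))
  # sample-specific repeat-context variant is reported for discussion
  r <- triage_variant(mk_variant(context = "REPEAT"), recurrence_count = 0)
  expect_equal(r$category, "TO_DISCUSS")
  expect_equal(r$reasons, "REPEAT_CONTEXT")
  # passing non-hotspot variant surfaces for discussion
  r <- triage_variant(mk_variant(allele_frequency = 0.2, hotspot = FALSE))
  expect_equal(r$category, "TO_DISCUSS")
  expect_equal(r$reasons, "NO_COSMIC_ID")
  # indel thresholds: 5% AF and 100X
  expect_equal(triage_variant(mk_variant("INS", 0.05, depth = 100L))$category,
               "POSITIVE")
  expect_equal(triage_variant(mk_variant("INS", 0.049, depth = 100L))$reasons,
               "LOW_FREQUENCY")
  expect_equal(triage_variant(mk_variant("INS", 0.05, depth = 99L))$reasons,
               "LOW_DEPTH")
  expect_error(triage_variant(list(variant_class = "SNV")), "missing")
})

test_that("the cascade agrees with a brute-force rule evaluator on a dense grid", {
  th <- triage_thresholds()
  grid <- expand.grid(af = seq(0.01, 0.20, by = 0.01),
                      depth = c(10L, 30L, 50L, 100L, 200L),
                      ratio = seq(0, 0.5, by = 0.05),
                      class = c("SNV", "INS"),
                      hotspot = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  mismatch <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    v <- mk_variant(g$class, g$af, g$depth, strand_ratio = g$ratio,
                    hotspot = g$hotspot)
    a <- triage_variant(v, 0L, th)
    b <- oracle_triage(v, 0L, th)
    if (!identical(a$category, b$category) ||
        !identical(a$reasons, b$reasons)) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("triage results are invariant under input row order", {
  spec <- simulation_spec(seed = 21, variants = mk_run_variant_spec(8),
                          n_samples = 4)
  run <- simulate_run_vcfs(spec, tempfile())
  recs <- do.call(rbind, lapply(run$vcf_paths, read_vcf, run_id = "RUN1"))
  recs <- annotate_variants(
    recs, hotspots = read_annotation_table(run$annotations$hotspots),
    popfreq_esp = read_annotation_table(run$annotations$popfreq_esp),
    neutral = read_annotation_table(run$annotations$neutral))
  recs <- context_from_fasta(recs, run$fasta_path)
  set.seed(1)
  perm <- sample.int(nrow(recs))
  a <- triage_variants(recs)
  b <- triage_variants(recs[perm, ])
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$alt)
  expect_identical(a$category[match(key(b), key(a))], b$category)
  expect_identical(a$recurrence_count[match(key(b), key(a))],
                   b$recurrence_count)
})

test_that("tightening a threshold never rescues a variant, loosening never kills one", {
  rank <- c(FILTERED = 0, TO_DISCUSS = 1, CONTROL = 1, POSITIVE = 2)
  set.seed(99)
  for (i in 1:60) {
    v <- mk_variant(sample(c("SNV", "INS"), 1), runif(1, 0.01, 0.2),
                    sample(c(20L, 80L, 400L), 1),
                    strand_ratio = runif(1, 0, 0.5),
                    hotspot = sample(c(TRUE, FALSE), 1))
    base <- triage_variant(v)$category
    stricter <- triage_variant(v, thresholds = triage_thresholds(
      snv_af_hotspot = 0.08, indel_af_hotspot = 0.10,
      snv_af_nontargeted = 0.15, indel_af_nontargeted = 0.20,
      snv_min_depth = 60L, indel_min_depth = 200L,
      min_strand_ratio = 0.3))$category
    looser <- triage_variant(v, thresholds = triage_thresholds(
      snv_af_hotspot = 0.01, indel_af_hotspot = 0.01,
      snv_af_nontargeted = 0.02, indel_af_nontargeted = 0.02,
      snv_min_depth = 5L, indel_min_depth = 10L,
      min_strand_ratio = 0))$category
    expect_lte(rank[stricter], rank[base])
    expect_gte(rank[looser], rank[base])
  }
})

test_that("every non-positive call carries true, auditable reasons", {
  th <- triage_thresholds()
  set.seed(7)
  for (i in 1:80) {
    v <- mk_variant(sample(c("SNV", "DEL"), 1), runif(1, 0.005, 0.25),
                    sample(c(15L, 50L, 150L, 600L), 1),
                    strand_ratio = runif(1, 0, 0.5),
                    hotspot = sample(c(TRUE, FALSE), 1),
                    pop_freq_esp = sample(c(NA, 0.002, 0.05), 1),
                    context = sample(c("NONE", "HOMOPOLYMER"), 1))
    rec <- sample(0:2, 1)
    r <- triage_variant(v, rec, th)
    if (r$category == "POSITIVE") {
      expect_length(r$reasons, 0)
    } else {
      expect_gt(length(r$reasons), 0)
    }
    for (reason in r$reasons) {
      truth <- switch(reason,
        POLYMORPHISM = !is.na(v$pop_freq_esp) &&
          v$pop_freq_esp > th$polymorphism_max_pop_freq,
        NEUTRAL_RECURRENT = isTRUE(v$neutral_recurrent),
        LOW_FREQUENCY = v$allele_frequency < (
          if (!is.na(v$hotspot_id)) {
            if (v$variant_class %in% c("INS", "DEL")) th$indel_af_hotspot
            else th$snv_af_hotspot
          } else {
            if (v$variant_class %in% c("INS", "DEL")) th$indel_af_nontargeted
            else th$snv_af_nontargeted
          }),
        LOW_DEPTH = v$depth < (if (v$variant_class %in% c("INS", "DEL"))
          th$indel_min_depth else th$snv_min_depth),
        STRAND_BIAS = strand_ratio(v$alt_fwd, v$alt_rev) < th$min_strand_ratio,
        HOMOPOLYMER_CONTEXT = v$context == "HOMOPOLYMER",
        REPEAT_CONTEXT = v$context == "REPEAT",
        RECURRENT_RUN_ARTIFACT = v$context != "NONE" &&
          rec >= th$recurrence_min_other_samples,
        NO_COSMIC_ID = is.na(v$hotspot_id),
        FALSE)
      expect_true(truth, info = reason)
    }
  }
})
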