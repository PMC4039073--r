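# build a small coherent sample: 3-gene panel, one amplification, a few
# triaged variants
mk_report_inputs <- function(sample_id = "S01") {
  panel <- toy_panel()
  segs <- rbind(
    mk_called_segments("17", c(30e6, 37e6, 40e6), c(37e6, 40e6, 70e6),
                       c(2, 8, 2), sample_id = sample_id),
    mk_called_segments("12", 0, 100e6, 2, sample_id = sample_id),
    mk_called_segments("3", 0, 190e6, 2, sample_id = sample_id))
  attr(segs, "sample_id") <- sample_id
  calls <- call_genes(segs, panel)
  records <- data.frame(
    chrom = c("17", "12", "3"), pos = c(37850000L, 25370000L, 178900000L),
    ref = "C", alt = "T", variant_class = "SNV", sample_id = sample_id,
    run_id = "RUN1", depth = 900L, alt_fwd = c(45L, 54L, 4L),
    alt_rev = c(45L, 54L, 5L), allele_frequency = c(0.10, 0.12, 0.01),
    gene = c("ERBB2", "KRAS", "PIK3CA"), consequence = "MISSENSE",
    hotspot_id = c("COSM1", NA, "COSM3"),
    pop_freq_esp = NA_real_, pop_freq_1kg = NA_real_,
    neutral_recurrent = FALSE, context = "NONE", stringsAsFactors = FALSE)
  triaged <- triage_variants(records)
  pb <- patient_block("P-ABC123", tumor_type = "breast adenocarcinoma",
                      cellularity = 0.6, ploidy_class = "diploid",
                      hr_estrogen = "POS")
  list(panel = panel, calls = calls, triaged = triaged, patient = pb)
}

test_that("the report summarises every panel gene with codes and counts", {
  x <- mk_report_inputs()
  rep <- build_report(x$patient, x$calls, x$triaged, x$panel,
                      timestamp = "2026-02-01T00:00:00+0000")
  expect_equal(nrow(rep$summary_rows), 3)
  expect_setequal(rep$summary_rows$symbol, x$panel$symbol)
  sr <- rep$summary_rows
  expect_equal(sr$status_code[sr$symbol == "ERBB2"], "A")
  expect_equal(sr$status_code[sr$symbol == "KRAS"], "N")
  # ERBB2 has one POSITIVE variant; KRAS one TO_DISCUSS; the PIK3CA
  # variant is FILTERED and must not be counted
  expect_equal(sr$mutation_count[sr$symbol == "ERBB2"], 1)
  expect_equal(sr$mutation_count[sr$symbol == "KRAS"], 1)
  expect_equal(sr$mutation_count[sr$symbol == "PIK3CA"], 0)
  expect_false(any(rep$variant_details$category == "FILTERED"))
  expect_equal(nrow(rep$filtered_appendix), 1)
})

test_that("reports with no variants carry zero mutation counts", {
  x <- mk_report_inputs()
  none <- x$triaged[0, ]
  rep <- build_report(x$patient, x$calls, none, x$panel,
                      timestamp = "2026-02-01T00:00:00+0000")
  expect_true(all(rep$summary_rows$mutation_count == 0))
  expect_equal(nrow(rep$variant_details), 0)
})

test_that("cross-assay sample mismatch is rejected", {
  x <- mk_report_inputs()
  wrong <- x$triaged
  wrong$sample_id <- "S99"
  expect_error(build_report(x$patient, x$calls, wrong, x$panel),
               "sample mismatch")
})

test_that("every reportable variant appears in exactly one detail row", {
  x <- mk_report_inputs()
  rep <- build_report(x$patient, x$calls, x$triaged, x$panel,
                      timestamp = "2026-02-01T00:00:00+0000")
  reportable <- x$triaged[x$triaged$category %in%
                            c("POSITIVE", "TO_DISCUSS"), ]
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  for (k in key(reportable)) {
    expect_equal(sum(key(rep$variant_details) == k), 1)
  }
})

test_that("JSON rendering is canonical, parseable and idempotent", {
  x <- mk_report_inputs()
  rep <- build_report(x$patient, x$calls, x$triaged, x$panel,
                      timestamp = "2026-02-01T00:00:00+0000")
  j1 <- render_report(rep, "json")
  j2 <- render_report(rep, "json")
  expect_identical(j1, j2)  # byte-identical with a pinned timestamp
  parsed <- jsonlite::fromJSON(j1)
  expect_equal(parsed$patient$pseudonym, "P-ABC123")
  expect_equal(nrow(parsed$summary_rows), 3)
  expect_equal(sort(parsed$summary_rows$symbol),
               sort(rep$summary_rows$symbol))
  expect_equal(parsed$provenance$generated, "2026-02-01T00:00:00+0000")
  # keys are sorted at every level
  expect_identical(names(parsed), sort(names(parsed)))
})

test_that("rendered documents never leak denylisted identifiers", {
  x <- mk_report_inputs()
  x$patient$tumor_type <- "adenocarcinoma (patient Jane Doe)"
  rep <- build_report(x$patient, x$calls, x$triaged, x$panel,
                      timestamp = "2026-02-01T00:00:00+0000")
  for (fmt in c("json", "markdown", "html")) {
    doc <- render_report(rep, fmt, denylist = c("Jane", "Doe"))
    expect_false(any(grepl("Jane|Doe", doc)))
    expect_true(any(grepl("REDACTED", doc)))
  }
})

test_that("HTML view carries one color-coded row per panel gene", {
  x <- mk_report_inputs()
  rep <- build_report(x$patient, x$calls, x$triaged, x$panel,
                      timestamp = "2026-02-01T00:00:00+0000")
  html <- render_report(rep, "html")
  gene_rows <- grep("<tr><td>(ERBB2|KRAS|PIK3CA)</td>", html)
  expect_length(gene_rows, nrow(x$panel))
  expect_true(any(grepl("background:#b2182b", html)))  # amplification color
  md <- render_report(rep, "markdown")
  expect_true(any(grepl("\\| ERBB2 \\| A \\|", md)))
  expect_error(render_report(rep, "docx"))
})

test_that("the IHC request document lists qualifying genes sorted by symbol", {
  x <- mk_report_inputs()
  doc <- build_ihc_request_report(x$calls)
  expect_equal(doc$n, 1)
  expect_equal(doc$requests$symbol, "ERBB2")

  # no focal events -> still a valid, empty document
  flat <- mk_called_segments("17", 0, 70e6, 2)
  calls_flat <- call_genes(flat, toy_panel())
  p <- tempfile(fileext = ".json")
  doc0 <- build_ihc_request_report(calls_flat, path = p)
  expect_equal(doc0$n, 0)
  expect_equal(jsonlite::read_json(p)$n, 0)
})

test_that("TO_DISCUSS reasons are carried verbatim into the rendered report", {
  x <- mk_report_inputs()
  rep <- build_report(x$patient, x$calls, x$triaged, x$panel,
                      timestamp = "2026-02-01T00:00:00+0000")
  md <- render_report(rep, "markdown")
  expect_true(any(grepl("NO_COSMIC_ID", md)))
  j <- jsonlite::fromJSON(render_report(rep, "json"))
  expect_true("NO_COSMIC_ID" %in% j$variant_details$reasons_str)
})
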