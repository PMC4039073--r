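test_that("cellularity gate uses strict more-than semantics", {
  expect_true(check_sample_qc(mk_meta(0.50))$pass)
  expect_true(check_sample_qc(mk_meta(1.0))$pass)
  gate <- check_sample_qc(mk_meta(0.30))
  expect_false(gate$pass)  # exactly 30% is rejected
  expect_equal(gate$reason, "LOW_CELLULARITY")
  expect_true(check_sample_qc(mk_meta(0.31))$pass)
  m <- mk_meta(0.5); m$cellularity <- NA_real_
  expect_error(check_sample_qc(m), "missing")
})

test_that("total copy number inverts the log-ratio mixture model", {
  expect_equal(estimate_total_cn(0, mk_meta(1, 2)), 2L)
  # forward model: c=0.5, psi=2, n=6 -> LRR = log2(4/2) = 1
  expect_equal(estimate_total_cn(1, mk_meta(0.5, 2)), 6L)
  # c=0.4, psi=4, n=0 -> LRR = log2(1.2/2.8)
  expect_equal(estimate_total_cn(log2(1.2 / 2.8), mk_meta(0.4, 4)), 0L)
  # strongly negative ratios clip at zero copies
  expect_equal(estimate_total_cn(-10, mk_meta(0.9, 2)), 0L)
  expect_error(estimate_total_cn(0, sample_meta("P", "S", cellularity = 0,
                                                ploidy = 2)),
               "UNIDENTIFIABLE")
})

test_that("minor copy number is the argmin over the allelic mixture model", {
  expect_equal(estimate_minor_cn(0.5, mk_meta(1), 2), 1L)   # balanced het
  expect_equal(estimate_minor_cn(1.0, mk_meta(1), 2), 0L)   # LOH
  # c=0.5: expected mirrored BAF for (2, 0) is (1 + 0.5)/2 = 0.75
  expect_equal(estimate_minor_cn(0.75, mk_meta(0.5), 2), 0L)
  expect_true(is.na(estimate_minor_cn(NA, mk_meta(0.5), 2)))
})

test_that("noise-free forward simulation inverts exactly over the full grid", {
  for (psi in c(2, 4)) {
    for (cc in seq(0.35, 1.0, by = 0.05)) {
      meta <- mk_meta(cc, psi)
      for (n in 0:12) {
        lrr <- log2((cc * n + 2 * (1 - cc)) / (cc * psi + 2 * (1 - cc)))
        expect_identical(estimate_total_cn(lrr, meta), as.integer(n))
        for (m in 0:(n %/% 2)) {
          denom <- cc * n + 2 * (1 - cc)
          if (denom <= 0) next  # c = 1 with zero copies: BAF undefined
          baf <- (cc * (n - m) + (1 - cc)) / denom
          expect_identical(estimate_minor_cn(baf, meta, n), as.integer(m))
        }
      }
    }
  }
})

test_that("status tables match the diploid and tetraploid calling rules", {
  dip <- assign_status(0:8, "diploid")
  expect_equal(dip, c("DELETION", "LOSS", "NORMAL", "GAIN", "GAIN", "GAIN",
                      "AMPLIFICATION", "AMPLIFICATION", "AMPLIFICATION"))
  tet <- assign_status(0:8, "tetraploid")
  expect_equal(tet, c("DELETION", "LOSS", "LOSS", "NORMAL", "NORMAL",
                      "GAIN", "GAIN", "AMPLIFICATION", "AMPLIFICATION"))
})

test_that("status assignment is total and monotone over 0..20", {
  ranks <- c(DELETION = 1, LOSS = 2, NORMAL = 3, GAIN = 4, AMPLIFICATION = 5)
  for (pc in c("diploid", "tetraploid")) {
    st <- assign_status(0:20, pc)
    expect_false(anyNA(st))
    expect_true(all(diff(ranks[st]) >= 0))
  }
  expect_error(assign_status(-1, "diploid"))
})

test_that("ploidy is binned at 3, with a strict mode", {
  th <- status_thresholds()
  expect_equal(ploidy_class(2.1, th), "diploid")
  expect_equal(ploidy_class(3.7, th), "tetraploid")
  strict <- status_thresholds(strict_ploidy = TRUE)
  expect_equal(ploidy_class(2, strict), "diploid")
  expect_error(ploidy_class(2.5, strict), "strict")
})

test_that("focality requires size under 10 Mb and elevation above both neighbors", {
  segs <- mk_called_segments("1", c(0e6, 40e6, 45e6), c(40e6, 45e6, 90e6),
                             c(2, 8, 2))
  expect_identical(detect_focal(segs), c(FALSE, TRUE, FALSE))

  wide <- mk_called_segments("1", c(0e6, 40e6, 52e6), c(40e6, 52e6, 90e6),
                             c(2, 8, 2))
  expect_false(any(detect_focal(wide)))  # 12 Mb is not focal

  flat <- mk_called_segments("1", c(0e6, 40e6, 45e6), c(40e6, 45e6, 90e6),
                             c(4, 3, 3))
  expect_false(any(detect_focal(flat)))  # CN 3 not above the CN 4 neighbor

  # a gained segment at a chromosome end compares to its single neighbor
  endseg <- mk_called_segments("1", c(0e6, 5e6), c(5e6, 90e6), c(8, 2))
  expect_identical(detect_focal(endseg), c(TRUE, FALSE))
})

test_that("focal flags are unaffected by unrelated chromosomes", {
  segs <- rbind(
    mk_called_segments("1", c(0e6, 40e6, 45e6), c(40e6, 45e6, 90e6), c(2, 8, 2)),
    mk_called_segments("2", c(0e6, 30e6), c(30e6, 60e6), c(3, 3)))
  base <- detect_focal(segs)
  perm <- rbind(segs[4:5, ], segs[1:3, ])  # chromosome blocks swapped
  expect_identical(detect_focal(perm)[3:5], base[1:3])
})

test_that("gene calls partition the panel and take the most extreme status", {
  panel <- toy_panel()
  # ERBB2 inside a CN=6 segment; KRAS uncovered; PIK3CA spans CN=2 + CN=0
  segs <- rbind(
    mk_called_segments("17", 30e6, 45e6, 6),
    mk_called_segments("3", c(178e6, 178.9e6), c(178.9e6, 179.2e6), c(2, 0)))
  attr(segs, "sample_id") <- "S01"
  calls <- call_genes(segs, panel)
  expect_equal(nrow(calls), 3)
  expect_setequal(calls$symbol, panel$symbol)
  expect_equal(calls$status[calls$symbol == "ERBB2"], "AMPLIFICATION")
  expect_equal(calls$code[calls$symbol == "ERBB2"], "A")
  expect_equal(calls$status[calls$symbol == "KRAS"], "NORMAL")
  expect_true(calls$no_coverage[calls$symbol == "KRAS"])
  # deletion outranks normal for the breakpoint-spanning gene
  expect_equal(calls$status[calls$symbol == "PIK3CA"], "DELETION")
})

test_that("every panel gene appears exactly once however segments fall", {
  panel <- default_panel()
  set.seed(42)
  for (rep in 1:3) {
    chroms <- sample(assembly_chromosomes(), 5)
    segs <- do.call(rbind, lapply(chroms, function(ch) {
      b <- sort(sample.int(9e7, 3))
      mk_called_segments(ch, c(0, b), c(b, 9.5e7), sample(0:8, 4, TRUE))
    }))
    attr(segs, "sample_id") <- "S01"
    calls <- call_genes(segs, panel)
    expect_identical(sort(calls$symbol), sort(panel$symbol))
  }
})

test_that("IHC requests require focality, the size window and a validatable gene", {
  panel <- default_panel()
  mk_focal_calls <- function(symbol, size_mb, cn = 8) {
    row <- panel[panel$symbol == symbol, ]
    centre <- (row$start + row$end) / 2
    half <- size_mb * 1e6 / 2
    segs <- mk_called_segments(row$chrom,
                               c(0, centre - half, centre + half),
                               c(centre - half, centre + half, centre + half + 30e6),
                               c(2, cn, 2))
    call_genes(segs, panel)
  }
  erbb2_3mb <- mk_focal_calls("ERBB2", 3)
  req <- ihc_requests(erbb2_3mb)
  expect_equal(req$symbol, "ERBB2")
  expect_true(erbb2_3mb$ihc_required[erbb2_3mb$symbol == "ERBB2"])

  kras_3mb <- mk_focal_calls("KRAS", 3)
  expect_equal(nrow(ihc_requests(kras_3mb)), 0)  # not IHC-validatable

  erbb2_small <- mk_focal_calls("ERBB2", 0.5)
  expect_equal(nrow(ihc_requests(erbb2_small)), 0)  # below the 1 Mb window
})

test_that("profile-level calling recovers planted events at zero noise", {
  ev <- data.frame(chrom = c("17", "12"), start = c(37e6, 20e6),
                   end = c(40e6, 70e6), total_cn = c(8, 1),
                   minor_cn = c(1, 0))
  spec <- simulation_spec(seed = 5, ploidy = 2, cellularity = 0.5,
                          events = ev, noise_sd_lrr = 0)
  sim <- simulate_profile(spec)
  calls <- call_genes(call_segments(sim$profile), default_panel())
  merged <- merge(calls, sim$truth, by = "symbol",
                  suffixes = c("", ".truth"))
  expect_identical(merged$status, merged$status.truth)
  expect_identical(merged$loh, merged$loh.truth)
  expect_identical(merged$focal, merged$focal.truth)
  expect_equal(calls$total_cn[calls$symbol == "ERBB2"], 8L)
  expect_true(calls$loh[calls$symbol == "KRAS"])
})
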