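#' Specification of a synthetic study sample set
#'
#' Describes everything the generator needs to forward-simulate a
#' segmented copy-number profile and a multi-sample sequencing run
#' with known ground truth: copy-number events over a genome of the
#' given ploidy observed at the given cellularity, and planted
#' variants with true allele fractions, depths, strand splits,
#' sequence contexts and cross-sample sharing.
#'
#' @param seed Integer seed; the whole simulation is reproducible from
#'   it.
#' @param ploidy,cellularity Tumor ploidy and tumor-cell fraction.
#' @param events data.frame `chrom,start,end,total_cn,minor_cn`
#'   (0-based half-open, non-overlapping); `minor_cn` may be NA.
#' @param noise_sd_lrr Gaussian noise SD added to segment log ratios.
#' @param variants data.frame with columns `chrom,pos,ref,alt,true_af,
#'   depth,strand_fwd_frac,context_kind,n_samples_sharing` and
#'   optional `hotspot` (logical), `pop_freq_esp`, `pop_freq_1kg`,
#'   `neutral` (logical), `gene`, `consequence`. `pos` is 0-based;
#'   `context_kind` one of NONE/HOMOPOLYMER/REPEAT.
#' @param panel A `gene_panel` ([default_panel()]).
#' @param n_samples Samples in the simulated sequencing run.
#' @param run_id Run identifier.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, ploidy = 2, cellularity = 0.6,
                            events = NULL, noise_sd_lrr = 0,
                            variants = NULL, panel = default_panel(),
                            n_samples = 8L, run_id = "RUN1") {
  if (!is.null(events) && nrow(events)) {
    stopifnot(all(c("chrom", "start", "end", "total_cn") %in% names(events)))
    if (is.null(events$minor_cn)) events$minor_cn <- NA_integer_
    ord <- order(events$chrom, events$start)
    ev <- events[ord, ]
    for (chr in unique(ev$chrom)) {
      e <- ev[ev$chrom == chr, , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
        stop("overlapping simulated events on chromosome ", chr)
      }
    }
  }
  if (!is.null(variants) && nrow(variants)) {
    need <- c("chrom", "pos", "ref", "alt", "true_af", "depth",
              "strand_fwd_frac", "context_kind", "n_samples_sharing")
    miss <- setdiff(need, names(variants))
    if (length(miss)) stop("variants spec missing: ", paste(miss, collapse = ", "))
    stopifnot(all(variants$true_af > 0), all(variants$true_af <= 1),
              all(variants$depth > 0),
              all(variants$n_samples_sharing >= 1),
              all(variants$n_samples_sharing <= n_samples),
              all(variants$context_kind %in% c("NONE", "HOMOPOLYMER", "REPEAT")))
    for (opt in c("hotspot", "neutral")) {
      if (is.null(variants[[opt]])) variants[[opt]] <- FALSE
    }
    for (opt in c("pop_freq_esp", "pop_freq_1kg")) {
      if (is.null(variants[[opt]])) variants[[opt]] <- NA_real_
    }
    if (is.null(variants$gene)) variants$gene <- NA_character_
    if (is.null(variants$consequence)) variants$consequence <- "MISSENSE"
  }
  structure(list(seed = as.integer(seed), ploidy = ploidy,
                 cellularity = cellularity, events = events,
                 noise_sd_lrr = noise_sd_lrr, variants = variants,
                 panel = panel, n_samples = as.integer(n_samples),
                 run_id = run_id),
            class = "simulation_spec")
}

# Forward mixture model: expected log R ratio of tumor copy number n at
# cellularity c over a tumor of ploidy psi.
forward_log_ratio <- function(total_cn, cellularity, ploidy) {
  log2((cellularity * total_cn + 2 * (1 - cellularity)) /
         (cellularity * ploidy + 2 * (1 - cellularity)))
}

#' Simulate a segmented copy-number profile with known truth
#'
#' Builds whole-chromosome baseline segments at the tumor's rounded
#' ploidy, carves out the specified events, and emits each segment's
#' log R ratio from the forward mixture model (plus optional Gaussian
#' noise) and its mirrored BAF from the allelic mixture model. The
#' truth table records the intended per-gene status, LOH flag and
#' focality obtained from the noise-free event definitions.
#'
#' @param spec A [simulation_spec()].
#' @param sample_id,patient Sample and patient identifiers.
#' @return List: `profile` (a [segmented_profile()]) and `truth`
#'   (data.frame `symbol,status,loh,focal`).
#' @export
simulate_profile <- function(spec, sample_id = "S01", patient = "P-SYN") {
  set.seed(spec$seed)
  base_cn <- as.integer(round(spec$ploidy))
  base_minor <- base_cn %/% 2L
  chroms <- unique(spec$panel$chrom)
  ev <- spec$events
  segs <- list()
  for (chr in chroms) {
    len <- chromosome_length(chr)
    e <- if (!is.null(ev)) ev[ev$chrom == chr, , drop = FALSE] else
      data.frame()
    bounds <- c(0, if (nrow(e)) as.vector(rbind(e$start, e$end)), len)
    cns <- rep(base_cn, length(bounds) - 1)
    minors <- rep(base_minor, length(bounds) - 1)
    if (nrow(e)) {
      ei <- seq(2, by = 2, length.out = nrow(e))
      cns[ei] <- e$total_cn
      minors[ei] <- ifelse(is.na(e$minor_cn), pmin(base_minor, e$total_cn %/% 2L),
                           e$minor_cn)
    }
    keep <- bounds[-length(bounds)] < bounds[-1]
    st <- bounds[-length(bounds)][keep]; en <- bounds[-1][keep]
    cns <- cns[keep]; minors <- minors[keep]
    segs[[chr]] <- data.frame(
      chrom = chr, start = st, end = en,
      n_probes = pmax(2, round((en - st) / 1e5)),
      log_ratio = forward_log_ratio(cns, spec$cellularity, spec$ploidy) +
        stats::rnorm(length(st), 0, spec$noise_sd_lrr),
      mirrored_baf = expected_mirrored_baf(cns, minors, spec$cellularity),
      true_cn = cns, true_minor = minors, stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  meta <- sample_meta(patient, sample_id, run_id = spec$run_id,
                      cellularity = spec$cellularity, ploidy = spec$ploidy)
  profile <- segmented_profile(meta, segs[, .seg_columns])

  # intended truth, from the noise-free event definitions
  pc <- if (round(spec$ploidy) < 3) "diploid" else "tetraploid"
  truth_segs <- segs
  truth_segs$total_cn <- truth_segs$true_cn
  truth_segs$minor_cn <- truth_segs$true_minor
  truth_segs$status <- assign_status(truth_segs$true_cn, pc)
  truth_segs$loh <- !is.na(truth_segs$true_minor) &
    truth_segs$true_minor == 0 & truth_segs$true_cn >= 1
  truth_segs$size_mb <- (truth_segs$end - truth_segs$start) / 1e6
  truth_segs$focal <- detect_focal(truth_segs)
  truth_calls <- call_genes(truth_segs, spec$panel)
  truth <- data.frame(symbol = truth_calls$symbol,
                      status = truth_calls$status, loh = truth_calls$loh,
                      focal = truth_calls$focal, stringsAsFactors = FALSE)
  list(profile = profile, truth = truth)
}

# Plant a context motif around a variant in a character vector of bases.
.plant_context <- function(bases, pos1, ref, kind, hp_run = 5L) {
  ref_chars <- strsplit(ref, "")[[1]]
  if (kind == "HOMOPOLYMER") {
    run_len <- max(hp_run, length(ref_chars) + 2L)
    idx <- pos1:(pos1 + run_len - 1L)
    bases[idx] <- ref_chars[1]
  } else if (kind == "REPEAT") {
    other <- setdiff(c("A", "C", "G", "T"), ref_chars[1])[1]
    unit <- c(ref_chars[1], other)
    idx <- pos1:(pos1 + 5L)
    bases[idx] <- rep(unit, 3L)
  }
  # the reference must carry the ref allele at the locus
  bases[pos1:(pos1 + length(ref_chars) - 1L)] <- ref_chars
  bases
}

#' Simulate a sequencing run: VCFs, reference FASTA, annotation tables
#'
#' Emits one single-sample VCF per simulated sample, a reference FASTA
#' with planted homopolymer/repeat motifs, the four annotation tables
#' (hotspots, two population-frequency cohorts, recurrent-neutral
#' controls), and a per-variant truth table with the intended triage
#' category. Alt read counts are drawn binomially around the true
#' allele fraction with the requested strand split; variants shared by
#' k samples appear in the first k samples of the run. The reference
#' background is a pattern with no homopolymer run or short tandem
#' repeat, so only planted motifs produce non-NONE contexts.
#'
#' @param spec A [simulation_spec()] with a non-empty `variants` table.
#' @param dir Output directory (created if needed).
#' @return List: `vcf_paths` (named by sample id), `fasta_path`,
#'   `annotations` (named list of TSV paths), `truth` (data.frame with
#'   the planted parameters and `expected_category`), `sample_ids`.
#' @export
simulate_run_vcfs <- function(spec, dir = tempfile("simrun")) {
  if (is.null(spec$variants) || !nrow(spec$variants)) {
    stop("simulation spec has no variants")
  }
  set.seed(spec$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- spec$variants
  sample_ids <- sprintf("S%02d", seq_len(spec$n_samples))

  # reference contigs: per chromosome, cover all loci + window
  contigs <- list()
  for (chr in unique(v$chrom)) {
    vv <- v[v$chrom == chr, , drop = FALSE]
    len <- max(vv$pos + nchar(vv$ref)) + 60L
    bases <- rep(c("A", "C", "G", "T"), length.out = len)
    for (i in seq_len(nrow(vv))) {
      if (vv$pos[i] < 25) stop("variant locus too close to contig start")
      bases <- .plant_context(bases, vv$pos[i] + 1L, vv$ref[i],
                              vv$context_kind[i])
    }
    contigs[[chr]] <- paste(bases, collapse = "")
  }
  fasta_path <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(contigs)), fasta_path)

  # annotation tables
  ann <- list()
  key_cols <- function(idx) data.frame(chrom = v$chrom[idx],
                                       pos = v$pos[idx] + 1L,
                                       ref = v$ref[idx], alt = v$alt[idx],
                                       stringsAsFactors = FALSE)
  hot_idx <- which(v$hotspot | v$neutral)  # neutral controls sit on hotspots
  hotspots <- cbind(key_cols(hot_idx),
                    hotspot_id = sprintf("COSM%05d", 10000L + hot_idx))
  esp_idx <- which(!is.na(v$pop_freq_esp))
  esp <- cbind(key_cols(esp_idx), freq = v$pop_freq_esp[esp_idx])
  kg_idx <- which(!is.na(v$pop_freq_1kg))
  kg <- cbind(key_cols(kg_idx), freq = v$pop_freq_1kg[kg_idx])
  neutral <- key_cols(which(v$neutral))
  write_tab <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  ann$hotspots <- write_tab(hotspots, "hotspots.tsv")
  ann$popfreq_esp <- write_tab(esp, "popfreq_esp.tsv")
  ann$popfreq_1kg <- write_tab(kg, "popfreq_1kg.tsv")
  ann$neutral <- write_tab(neutral, "neutral.tsv")

  # observed records per sample
  vcf_paths <- character(0)
  for (s in seq_along(sample_ids)) {
    idx <- which(v$n_samples_sharing >= s)
    recs <- empty_variant_records()
    if (length(idx)) {
      alt_total <- stats::rbinom(length(idx), v$depth[idx], v$true_af[idx])
      alt_total <- pmax(alt_total, 1L)  # a called variant has >= 1 alt read
      alt_fwd <- round(alt_total * v$strand_fwd_frac[idx])
      recs <- data.frame(
        chrom = v$chrom[idx], pos = as.integer(v$pos[idx]),
        ref = v$ref[idx], alt = v$alt[idx],
        variant_class = vapply(idx, function(i)
          classify_variant_class(v$ref[i], v$alt[i]), ""),
        sample_id = sample_ids[s], run_id = spec$run_id,
        depth = as.integer(v$depth[idx]),
        alt_fwd = as.integer(alt_fwd),
        alt_rev = as.integer(alt_total - alt_fwd),
        allele_frequency = alt_total / v$depth[idx],
        gene = v$gene[idx], consequence = v$consequence[idx],
        hotspot_id = NA_character_, pop_freq_esp = NA_real_,
        pop_freq_1kg = NA_real_, neutral_recurrent = FALSE,
        context = "NONE", stringsAsFactors = FALSE)
    }
    p <- file.path(dir, paste0(sample_ids[s], ".vcf"))
    write_vcf(recs, p)
    vcf_paths[sample_ids[s]] <- p
  }

  # intended truage category from the planted (noise-free) parameters
  th <- triage_thresholds()
  planted_ctx <- vapply(seq_len(nrow(v)), function(i) {
    chr <- v$chrom[i]
    seq_str <- contigs[[chr]]
    w <- th$repeat_window_bp
    pos1 <- v$pos[i] + 1L
    lo <- max(1L, pos1 - w)
    hi <- min(nchar(seq_str), pos1 + nchar(v$ref[i]) - 1L + w)
    detect_context(substr(seq_str, lo, hi), pos1 - lo + 1L, v$ref[i], th)
  }, "")
  expected <- vapply(seq_len(nrow(v)), function(i) {
    rec <- list(variant_class = classify_variant_class(v$ref[i], v$alt[i]),
                allele_frequency = v$true_af[i], depth = v$depth[i],
                alt_fwd = round(100 * v$strand_fwd_frac[i]),
                alt_rev = 100 - round(100 * v$strand_fwd_frac[i]),
                hotspot_id = if (v$hotspot[i] || v$neutral[i]) "X" else NA,
                pop_freq_esp = v$pop_freq_esp[i],
                pop_freq_1kg = v$pop_freq_1kg[i],
                neutral_recurrent = v$neutral[i],
                context = planted_ctx[i])
    triage_variant(rec, recurrence_count = v$n_samples_sharing[i] - 1L, th)$category
  }, "")
  truth <- cbind(v, planted_context = planted_ctx,
                 expected_category = expected)

  list(vcf_paths = vcf_paths, fasta_path = fasta_path, annotations = ann,
       truth = truth, sample_ids = sample_ids)
}
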