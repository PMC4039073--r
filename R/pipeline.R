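#' Pipeline configuration
#'
#' Bundles resource paths, the two threshold sets, deadlines, output
#' options and the identifier denylist. Every decision threshold
#' defaults to the clinical pipeline's published value and can be
#' overridden per field.
#'
#' @param panel_path Panel BED-plus path (default: the bundled panel).
#' @param hotspots_path,popfreq_esp_path,popfreq_1kg_path,neutral_path
#'   Annotation TSV paths (optional).
#' @param reference_path Reference FASTA path (optional; required for
#'   sequence-context detection).
#' @param out_dir Output directory.
#' @param genome_build Build label, provenance only.
#' @param report_formats Subset of `c("json", "markdown", "html")`.
#' @param cna_thresholds A [status_thresholds()].
#' @param triage_thresholds_ A [triage_thresholds()].
#' @param bioinformatics_days,total_days Deadlines (days).
#' @param denylist Identifier tokens that must never appear in reports.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(panel_path = NULL, hotspots_path = NULL,
                            popfreq_esp_path = NULL, popfreq_1kg_path = NULL,
                            neutral_path = NULL, reference_path = NULL,
                            out_dir = "mtbpipe-out", genome_build = "hg19",
                            report_formats = c("json", "html"),
                            cna_thresholds = status_thresholds(),
                            triage_thresholds_ = triage_thresholds(),
                            bioinformatics_days = 4L, total_days = 28L,
                            denylist = character()) {
  stopifnot(inherits(cna_thresholds, "status_thresholds"),
            inherits(triage_thresholds_, "triage_thresholds"),
            all(report_formats %in% c("json", "markdown", "html")),
            bioinformatics_days > 0, total_days >= bioinformatics_days)
  structure(list(panel_path = panel_path, hotspots_path = hotspots_path,
                 popfreq_esp_path = popfreq_esp_path,
                 popfreq_1kg_path = popfreq_1kg_path,
                 neutral_path = neutral_path,
                 reference_path = reference_path, out_dir = out_dir,
                 genome_build = genome_build,
                 report_formats = report_formats,
                 cna_thresholds = cna_thresholds,
                 triage_thresholds = triage_thresholds_,
                 bioinformatics_days = as.integer(bioinformatics_days),
                 total_days = as.integer(total_days),
                 denylist = denylist),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; threshold overrides are passed through
#' the threshold constructors so invariants are re-validated on load.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("panel_path", "hotspots_path", "popfreq_esp_path",
             "popfreq_1kg_path", "neutral_path", "reference_path",
             "out_dir", "genome_build", "report_formats",
             "cna_thresholds", "triage_thresholds",
             "bioinformatics_days", "total_days", "denylist")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cna <- do.call(status_thresholds, as.list(y$cna_thresholds))
  tri <- do.call(triage_thresholds, as.list(y$triage_thresholds))
  args <- y[setdiff(names(y), c("cna_thresholds", "triage_thresholds"))]
  args$cna_thresholds <- cna
  args$triage_thresholds_ <- tri
  args$denylist <- as.character(args$denylist)
  args$report_formats <- if (is.null(args$report_formats)) c("json", "html")
    else unlist(args$report_formats)
  do.call(pipeline_config, args)
}

#' Run the full decision pipeline for one sample
#'
#' Chains the stages: cellularity QC gate, per-segment and per-gene
#' copy-number calling, IHC request generation, variant annotation and
#' triage, board-report assembly, and workflow-tracking updates. Either
#' assay may be absent; the report marks the missing section
#' unavailable. A QC failure moves the sample to FAILED_QC and emits no
#' report.
#'
#' @param config A [pipeline_config()].
#' @param meta A [sample_meta()] for the sample.
#' @param segments_path Segments TSV (internal dialect), or NULL.
#' @param vcf_path Variant VCF for this sample, or NULL.
#' @param run_vcf_paths Optional additional VCFs of the same run (used
#'   for run-recurrence).
#' @param patient Optional [patient_block()]; a minimal one is built
#'   from `meta` when absent.
#' @param registry_path Tracking registry JSON (updated in place).
#' @param timestamp Pinned generation timestamp (for reproducible
#'   reports).
#' @return List: `status` ("ok" or "failed_qc"), `exit_code` (0 ok, 2
#'   QC failure), `calls`, `triaged`, `report`, `paths` (named output
#'   files), `registry`.
#' @export
run_pipeline <- function(config, meta, segments_path = NULL, vcf_path = NULL,
                         run_vcf_paths = NULL, patient = NULL,
                         registry_path = file.path(config$out_dir, "registry.json"),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(inherits(config, "pipeline_config"), inherits(meta, "sample_meta"))
  if (is.null(segments_path) && is.null(vcf_path)) {
    stop("inputs for at least one assay are required")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, msg) {
    message(sprintf("[%s] sample=%s stage=%s %s", timestamp, meta$sample_id,
                    stage, msg))
  }
  registry <- registry_load(registry_path)
  ws <- registry[[meta$sample_id]]
  # a sample already beyond REGISTERED starts a fresh analysis cycle
  if (is.null(ws) || ws$state != "REGISTERED") {
    ws <- workflow_start(meta$sample_id, timestamp,
                         note = if (is.null(ws)) "registered" else "reanalysis")
  }

  qc <- check_sample_qc(meta, config$cna_thresholds)
  if (!qc$pass) {
    ws <- workflow_advance(ws, "FAILED_QC", timestamp,
                           note = qc$reason)
    registry[[meta$sample_id]] <- ws
    registry_save(registry, registry_path)
    log_line("qc", paste("FAIL", qc$reason))
    return(list(status = "failed_qc", exit_code = 2L, calls = NULL,
                triaged = NULL, report = NULL,
                paths = c(registry = registry_path), registry = registry))
  }
  log_line("qc", sprintf("PASS cellularity=%.2f", meta$cellularity))

  panel <- if (is.null(config$panel_path)) default_panel() else
    read_panel(config$panel_path)
  paths <- c(registry = registry_path)
  checksums <- c()

  calls <- NULL
  if (!is.null(segments_path)) {
    ws <- workflow_advance(ws, "CNA_RECEIVED", timestamp)
    profile <- read_segments(segments_path, meta)
    called <- call_segments(profile, config$cna_thresholds)
    calls <- call_genes(called, panel, config$cna_thresholds)
    ws <- workflow_advance(ws, "CNA_ANALYZED", timestamp)
    checksums["segments"] <- md5_file(segments_path)
    gc_path <- file.path(config$out_dir,
                         paste0(meta$sample_id, "_gene_calls.tsv"))
    utils::write.table(
      calls[, c("symbol", "total_cn", "minor_cn", "code", "loh", "focal",
                "event_size_mb", "ihc_required")],
      gc_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["gene_calls"] <- gc_path
    req <- ihc_requests(calls, config$cna_thresholds)
    ihc_path <- file.path(config$out_dir,
                          paste0(meta$sample_id, "_ihc_request.json"))
    build_ihc_request_report(calls, config$cna_thresholds, path = ihc_path)
    paths["ihc_request"] <- ihc_path
    if (nrow(req)) ws <- workflow_advance(ws, "IHC_REQUESTED", timestamp)
    log_line("cna-call", sprintf("%d genes, %d altered, %d IHC request(s)",
                                 nrow(calls), sum(calls$status != "NORMAL"),
                                 nrow(req)))
  }

  triaged <- NULL
  if (!is.null(vcf_path)) {
    ws <- workflow_advance(ws, "VARIANTS_RECEIVED", timestamp)
    records <- read_vcf(vcf_path, run_id = meta$run_id)
    records$sample_id <- meta$sample_id
    others <- lapply(setdiff(run_vcf_paths, vcf_path), read_vcf,
                     run_id = meta$run_id)
    all_records <- do.call(rbind, c(list(records), others))
    read_tab <- function(p) if (is.null(p)) NULL else read_annotation_table(p)
    all_records <- annotate_variants(
      all_records,
      hotspots = read_tab(config$hotspots_path),
      popfreq_esp = read_tab(config$popfreq_esp_path),
      popfreq_1kg = read_tab(config$popfreq_1kg_path),
      neutral = read_tab(config$neutral_path))
    if (!is.null(config$reference_path)) {
      all_records <- context_from_fasta(all_records, config$reference_path,
                                        config$triage_thresholds)
    }
    all_triaged <- triage_variants(all_records, config$triage_thresholds)
    triaged <- all_triaged[all_triaged$sample_id == meta$sample_id, ,
                           drop = FALSE]
    ws <- workflow_advance(ws, "VARIANTS_ANALYZED", timestamp)
    checksums["vcf"] <- md5_file(vcf_path)
    tri_path <- file.path(config$out_dir,
                          paste0(meta$sample_id, "_triage.tsv"))
    write_triage_tsv(triaged, tri_path)
    paths["triage"] <- tri_path
    counts <- table(factor(triaged$category,
                           c("POSITIVE", "TO_DISCUSS", "CONTROL", "FILTERED")))
    log_line("variant-triage",
             paste(names(counts), counts, sep = "=", collapse = " "))
  }

  if (is.null(calls)) {
    # CNA assay unavailable: placeholder no-coverage calls keep the
    # summary table total over the panel
    empty_segs <- data.frame(chrom = character(), start = numeric(),
                             end = numeric(), total_cn = integer(),
                             minor_cn = integer(), status = character(),
                             loh = logical(), focal = logical(),
                             size_mb = numeric())
    attr(empty_segs, "sample_id") <- meta$sample_id
    calls_for_report <- call_genes(empty_segs, panel, config$cna_thresholds)
  } else calls_for_report <- calls
  if (is.null(triaged)) triaged_for_report <- triage_variants(
    empty_variant_records(), config$triage_thresholds)
  else triaged_for_report <- triaged

  if (is.null(patient)) {
    patient <- patient_block(
      pseudonym = meta$patient_pseudonym,
      cellularity = meta$cellularity,
      ploidy_class = ploidy_class(meta$ploidy, config$cna_thresholds),
      biopsy_date = meta$biopsy_date,
      data_received_date = meta$data_received_date)
  }
  report <- build_report(patient, calls_for_report, triaged_for_report,
                         panel, config$cna_thresholds,
                         config$triage_thresholds, timestamp = timestamp,
                         input_checksums = checksums)
  report$assays <- list(cna = !is.null(calls), variants = !is.null(triaged))
  for (fmt in config$report_formats) {
    ext <- c(json = "json", markdown = "md", html = "html")[fmt]
    p <- file.path(config$out_dir,
                   paste0(meta$sample_id, "_report.", ext))
    render_report(report, fmt, path = p, denylist = config$denylist)
    paths[paste0("report_", fmt)] <- p
  }
  if (!is.null(triaged) && any(triaged$category == "FILTERED")) {
    fpath <- file.path(config$out_dir,
                       paste0(meta$sample_id, "_filtered_variants.tsv"))
    write_triage_tsv(triaged[triaged$category == "FILTERED", , drop = FALSE],
                     fpath)
    paths["filtered_appendix"] <- fpath
  }
  ws <- workflow_advance(ws, "REPORT_GENERATED", timestamp)
  registry[[meta$sample_id]] <- ws
  registry_save(registry, registry_path)
  log_line("report", paste("written:",
                           paste(basename(unname(paths)), collapse = " ")))
  list(status = "ok", exit_code = 0L, calls = calls, triaged = triaged,
       report = report, paths = paths, registry = registry)
}
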