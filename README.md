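# mtbpipe

A desk-scale reimplementation of the bioinformatics decision layer used
in precision-oncology trials that match refractory-cancer patients to
molecularly targeted agents from a tumor biopsy. Between the upstream
platforms (SNP-array segmentation, amplicon variant calling) and the
molecular tumor board sits a set of deterministic clinical decision
rules; `mtbpipe` implements those rules as tested, auditable R
functions:

- **gene-level copy-number status calling** from segmented tumor
  profiles, aware of tumor cellularity and ploidy, with loss of
  heterozygosity (LOH), focal-event detection, and automatic
  immunohistochemistry (IHC) validation requests;
- **somatic variant triage** for an amplicon panel — a specificity-first
  filter cascade with hotspot/polymorphism annotation,
  homopolymer/repeat context detection, and run-level recurrence
  checks, emitting auditable reason codes;
- **molecular-board report generation** — a name-blinded, canonical-JSON
  technical report with per-gene summary codes and provenance;
- **sample workflow tracking** — a per-sample state machine with an
  append-only audit log, pseudonymization, and turnaround-time
  monitoring against the trial deadlines (4 days of bioinformatics,
  four weeks biopsy-to-decision);
- **a seeded synthetic-data generator** so every stage is testable
  end-to-end with known ground truth and no external downloads.

It is aimed at clinical bioinformaticians who need the decision rules
of such a pipeline as a reusable, testable library rather than as prose
in an SOP.

## The models and rules at the core

**Absolute copy number.** A segment's log R ratio under a two-population
mixture of tumor (fraction *c*, copy number *n*, tumor ploidy ψ) and
normal cells is

    LRR = log2( (c·n + 2(1−c)) / (c·ψ + 2(1−c)) )

`estimate_total_cn()` inverts this exactly,
*n* = (2^LRR·(c·ψ + 2(1−c)) − 2(1−c))/c, rounded half away from zero and
clipped at 0. The minor-allele copy number *m* is recovered from the
mirrored B-allele fraction by enumerating *m* ∈ {0..⌊n/2⌋} against the
allelic mixture model; *m* = 0 with *n* ≥ 1 flags LOH.

**Status tables.** Diploid tumors: deletion = 0 copies, loss = 1,
normal = 2, gain = 3–5, amplification ≥ 6. Tetraploid tumors:
deletion = 0, loss = 1–2, normal = 3–4, gain = 5–6, amplification ≥ 7.
Codes D/L/N/G/A in the report. Focal events are gains/amplifications
< 10 Mb with copy number strictly above both flanking segments; focal
events of 1–10 Mb over an IHC-validatable gene (ALK, BRAF, EGFR, ERBB2,
KIT, MET, PDGFRA, PDGFRB, PTEN) trigger a pathologist request. Samples
are processed only when cellularity is strictly above 30%.

**Variant triage.** In fixed order: population frequency > 1% (ESP or
1000-Genomes-like cohort) → CONTROL; recurrent neutral hotspot variant →
CONTROL; allele frequency below 4% (hotspot SNV) / 5% (hotspot indel) /
10% (non-targeted SNV) / 15% (non-targeted indel) → FILTERED; depth
below 30X (SNV) / 100X (indel) → FILTERED; minority-strand fraction
min(fwd,rev)/(fwd+rev) below 0.2 → FILTERED; homopolymer/repeat context
shared with other samples of the same sequencing run → FILTERED as a
platform artifact; context-flagged but sample-specific → TO_DISCUSS;
otherwise-passing variant without a hotspot catalog ID → TO_DISCUSS;
else POSITIVE. Every decision carries its reason codes.

## Worked example

```r
library(mtbpipe)
dir <- tempfile(); dir.create(dir)

# simulate a diploid tumor at 60% cellularity with a 3 Mb ERBB2
# amplification (8 copies) and a 3-sample sequencing run carrying one
# clean hotspot SNV and one homopolymer indel shared across samples
events   <- data.frame(chrom = "17", start = 37e6, end = 40e6,
                       total_cn = 8, minor_cn = 1)
variants <- data.frame(chrom = "7", pos = c(100, 220), ref = "C",
                       alt = c("G", "T"), true_af = c(0.18, 0.06),
                       depth = 900, strand_fwd_frac = 0.5,
                       context_kind = c("NONE", "HOMOPOLYMER"),
                       n_samples_sharing = c(1, 3), hotspot = TRUE,
                       gene = c("BRAF", "EGFR"))
spec <- simulation_spec(seed = 42, ploidy = 2, cellularity = 0.6,
                        events = events, variants = variants, n_samples = 3)
sim <- simulate_profile(spec, sample_id = "S01")
write_segments(sim$profile, file.path(dir, "segments.tsv"))
run <- simulate_run_vcfs(spec, file.path(dir, "run"))

config <- pipeline_config(hotspots_path = run$annotations$hotspots,
                          popfreq_esp_path = run$annotations$popfreq_esp,
                          popfreq_1kg_path = run$annotations$popfreq_1kg,
                          neutral_path = run$annotations$neutral,
                          reference_path = run$fasta_path,
                          out_dir = file.path(dir, "out"))
meta <- sample_meta(pseudonymize("hospital-patient-17", "trial-key"),
                    "S01", "RUN1", cellularity = 0.6, ploidy = 2,
                    biopsy_date = "2026-01-05")
res <- run_pipeline(config, meta,
                    segments_path = file.path(dir, "segments.tsv"),
                    vcf_path = run$vcf_paths[["S01"]],
                    run_vcf_paths = run$vcf_paths,
                    timestamp = "2026-01-08T09:00:00+0000")
res$report
```

The run logs each stage and prints:

```
[2026-01-08T09:00:00+0000] sample=S01 stage=qc PASS cellularity=0.60
[2026-01-08T09:00:00+0000] sample=S01 stage=cna-call 76 genes, 1 altered, 1 IHC request(s)
[2026-01-08T09:00:00+0000] sample=S01 stage=variant-triage POSITIVE=1 TO_DISCUSS=0 CONTROL=0 FILTERED=1
Molecular board report for patient P-8D8F95CCDDA1
  76 panel genes: 1 with altered copy number, 1 mutated
  1 reportable variants, 1 IHC request(s)
```

The ERBB2 event is called an amplification (8 copies, focal, 3 Mb) and,
being in the IHC-validatable window, generates a pathologist request;
the BRAF hotspot SNV (observed allele frequency 0.178) passes every
filter and is POSITIVE; the EGFR indel sits in a planted homopolymer
run and recurs in the other two samples of the run, so it is FILTERED
with reasons `HOMOPOLYMER_CONTEXT;RECURRENT_RUN_ARTIFACT`:

```
   symbol total_cn minor_cn        status focal event_size_mb ihc_required
30  ERBB2        8        1 AMPLIFICATION  TRUE             3         TRUE

  chrom pos ref alt allele_frequency     context category reasons_str
1     7 100   C   G           0.1778        NONE POSITIVE
2     7 220   C   T           0.0522 HOMOPOLYMER FILTERED HOMOPOLYMER_CONTEXT;RECURRENT_RUN_ARTIFACT
```

Outputs land in `out/`: `S01_report.json` (canonical), `S01_report.html`
(color-coded view), `S01_ihc_request.json`, `S01_gene_calls.tsv`,
`S01_triage.tsv`, `S01_filtered_variants.tsv` (audit appendix) and the
tracking `registry.json`.

A thin command-line front end ships at `inst/cli/mtbpipe`
(`qc`, `cna-call`, `variant-triage`, `run`, `simulate`, `track`,
`version`).

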