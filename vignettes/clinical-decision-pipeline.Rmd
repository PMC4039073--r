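---
title: "Methods: copy-number calling, variant triage and board reporting"
author: "mtbpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number calling, variant triage and board reporting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbpipe)
```

`mtbpipe` implements the deterministic decision layer of a
precision-oncology molecular-profiling workflow: everything between the
upstream measurement platforms (segmented SNP-array profiles, amplicon
variant calls) and the molecular tumor board. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## The copy-number model

A bulk biopsy is a mixture of tumor cells (fraction $c$, the
*cellularity*) and normal diploid cells. For a genomic segment where
the tumor carries $n$ copies, against a tumor-wide average of $\psi$
copies per locus (the *ploidy*), the expected log R ratio is

$$\mathrm{LRR} = \log_2 \frac{c\,n + 2(1-c)}{c\,\psi + 2(1-c)}.$$

`estimate_total_cn()` inverts this closed form,

$$\hat n = \frac{2^{\mathrm{LRR}} \left(c\psi + 2(1-c)\right) - 2(1-c)}{c},$$

rounds *half away from zero* and clips at 0. Rounding half away from
zero (rather than R's default round-half-even) makes the inversion an
exact inverse of the forward model on integer copy numbers and keeps
boundary behaviour deterministic; clipping covers measurement noise
that would otherwise produce negative copies. At $c = 0$ the model is
unidentifiable and the function errors rather than guessing.

Allelic imbalance is summarised per segment as the *mirrored* B-allele
fraction of heterozygous probes, $\max(b, 1-b) \in [0.5, 1]$, so no
phase information is needed. For minor-allele copy number $m$ the
expected mirrored BAF is

$$\mathbb{E}[\mathrm{mBAF}] = \frac{c\,(n-m) + (1-c)}{c\,n + 2(1-c)},$$

and `estimate_minor_cn()` returns the $m \in \{0, \dots, \lfloor n/2
\rfloor\}$ minimising the absolute deviation. The expected value is
strictly decreasing in $m$ for $c > 0$, so the argmin is unique on
noise-free input; the implementation still breaks hypothetical ties
deterministically by taking the smallest $m$. With $n = 0$ (or the
degenerate $c = 1, n = 0$) the expectation is undefined and the minor
copy number is returned missing, as it is when a segment has no
heterozygous probes. LOH is reported as $m = 0$ with $n \ge 1$ — an
orthogonal flag next to the status letter, not a sixth status, matching
how board reports display a separate LOH column.

### Status tables, focality, IHC

`assign_status()` encodes the two published calling tables — diploid:
deletion 0, loss 1, normal 2, gain 3–5, amplification $\ge 6$;
tetraploid: deletion 0, loss 1–2, normal 3–4, gain 5–6, amplification
$\ge 7$ — total over all non-negative integers and monotone in copy
number. Upstream ploidy estimators emit real values, so a binning rule
is needed: $\psi < 3$ uses the diploid table, $\psi \ge 3$ the
tetraploid one (`ploidy_split`, configurable); a strict mode accepts
only exact ploidy 2 or 4 for pipelines that want the ambiguity
surfaced as an error.

A *focal* event — the signature of a targeted driver rather than an
arm-level change — is a gain or amplification spanning strictly less
than `focal_max_size_mb` (10 Mb) whose copy number strictly exceeds
that of every immediately adjacent segment on the same chromosome.
"Surrounding regions" is interpreted as the immediate flanking
segments, with a single-neighbor comparison at chromosome ends; strict
inequalities keep the boundary cases (equal neighbors, exactly 10 Mb)
non-focal. Focal gains/amplifications of size in $[1, 10)$ Mb over one
of the nine IHC-validatable genes (ALK, BRAF, EGFR, ERBB2, KIT, MET,
PDGFRA, PDGFRB, PTEN) generate the automatic pathologist request list.
Whether sub-1-Mb events should also trigger validation is not settled;
the window is configurable and defaults to the stated 1–10 Mb range.

Genes spanning a breakpoint take the status of the overlapping segment
with the largest rank distance from NORMAL (ties broken by larger
overlap): an extreme-wins rule, chosen so an actionable amplification
or deletion is never hidden by averaging across a breakpoint. Panel
genes with no overlapping segment are reported NORMAL with an explicit
`no_coverage` flag rather than omitted, keeping the summary table total
over the panel.

The cellularity gate is strict: samples with tumor-cell fraction at or
below `min_cellularity` (0.30) fail QC, reading "more than 30%"
literally. The sweep tests pin this boundary (30% fails, 31% passes).

## The variant triage cascade

Variants are filtered for specificity — in a therapy-assignment setting
a false positive mutation is costlier than a missed borderline call.
The cascade applies rules in a fixed order; the **category** is decided
by the first rule that fires, and the **reason codes** accumulate for
every rule whose predicate is true, so each decision is fully
auditable:

1. population allele frequency strictly above 1% in either reference
   cohort → CONTROL (`POLYMORPHISM`);
2. recurrent neutral hotspot variant → CONTROL (`NEUTRAL_RECURRENT`);
   both control classes have no therapeutic interest but confirm assay
   quality;
3. allele frequency below the class-appropriate bound, *inclusive*
   comparisons exactly as printed ("≥4%"): hotspot SNV 4%, hotspot
   indel 5%, non-targeted SNV 10%, non-targeted indel 15% → FILTERED
   (`LOW_FREQUENCY`);
4. total depth below 30X (SNV) / 100X (indel) → FILTERED (`LOW_DEPTH`);
5. strand ratio — defined here as the minority-strand fraction of
   alt-supporting reads, $\min(f, r)/(f + r) \in [0, 0.5]$ — below 0.2
   → FILTERED (`STRAND_BIAS`);
6. homopolymer/repeat context *and* the identical variant observed in
   at least one other sample of the same sequencing run → FILTERED
   (`RECURRENT_RUN_ARTIFACT`), the recurrent false-positive mode of ion
   semiconductor chemistry;
7. context-flagged but sample-specific → TO_DISCUSS with the context
   reason (real sample-specific variation in a repeat is reportable);
8. an otherwise-passing variant with no hotspot catalog identifier →
   TO_DISCUSS (`NO_COSMIC_ID`);
9. else POSITIVE (and only POSITIVE results have empty reasons).

Design choices where the rules needed sharpening: the depth and strand
filters apply to non-targeted variants too (the stricter frequency
bound is *additional* stringency, not a replacement); coverage
thresholds compare *total* depth, not alt-supporting depth
(configurable); "detected in other patients" means at least one other
sample of the same run (`recurrence_min_other_samples`, configurable),
and the recurrence discard applies only to context-flagged variants —
a clean variant shared by two patients in a run is not discarded by
this rule. Population-frequency comparison is strict (">1%") while the
allele-frequency bounds are inclusive ("≥4%"), mirroring the wording of
each rule.

Sequence context is detected in a ±20 bp reference window:
HOMOPOLYMER if a single-base run of length ≥ 4 touches the variant's
reference span (±1 bp, so insertions at a run boundary are caught);
otherwise REPEAT for a period-2 or period-3 tandem repeat with ≥ 2 full
copies and a non-degenerate unit. No published numeric definition
exists for these; 4 bp runs and short-period repeats within ±20 bp are
the operating regime of amplicon indel artifacts, and both knobs are
thresholds in `triage_thresholds()`.

Multi-allelic VCF records are decomposed per alt allele before triage,
since every filter quantity (AF, strand counts) is per-allele.
Run-level recurrence is computed set-wise before any per-variant rule,
which makes triage invariant under input row order (a tested property).

## Reporting and tracking

`build_report()` assembles the name-blinded board report: a patient
block (pseudonym only — the type has no name field), one summary row
per panel gene (status code D/L/N/G/A, LOH flag, count of
POSITIVE + TO_DISCUSS variants), detail sections, the IHC request list,
and provenance (package version, a hash of both threshold sets, input
checksums, timestamp). FILTERED variants never appear in the report
body; they are preserved in a machine-readable appendix for audit.
JSON with recursively sorted keys is the canonical artifact — rendering
the same report twice with a pinned timestamp is byte-identical, the
reproducibility contract under which a re-analysis can be diffed
against a gold-standard run. HTML and markdown are derived views; a
configurable identifier denylist is redacted from free text at render
time, and the blindness test plants a name in a free-text field and
asserts it never reaches any output format.

Sample tracking is a small DAG (`workflow_dag()`) allowing the two
assays in either order, an optional IHC branch, and terminal
FAILED_QC/DELIVERED states, persisted as a flat JSON registry with
atomic whole-file replacement — a deliberate desk-scale stand-in for a
database-backed tracking board that preserves the contract that
matters: append-only audit history and real-time per-sample status.
Turnaround is measured in calendar days (fractional days rounded up)
against the trial allowances of 4 days for bioinformatics and 28 days
from biopsy to delivery.

## The synthetic-data generator

`simulate_profile()` and `simulate_run_vcfs()` forward-simulate exactly
the quantities the pipeline consumes. Segment log ratios come from the
mixture formula plus Gaussian noise (`noise_sd_lrr`; 0 by default so
recovery tests are exact); mirrored BAFs from the allelic formula; alt
read counts are binomial around the true allele fraction with a
deterministic strand split; context motifs (homopolymer runs, period-2
repeats) are planted into an emitted reference FASTA whose background
is a fixed period-4 pattern containing no homopolymer and no
period-2/3 repeat, so only planted motifs can produce a non-NONE
context. Binomial read noise and Gaussian log-ratio noise are the
standard minimal choices; nothing platform-specific is emulated beyond
homopolymer planting. Every simulation is reproducible from its seed,
and each generator returns a truth table (intended gene statuses,
intended triage category per variant) computed from the planted,
noise-free parameters.

What the passing tests therefore show: the decision rules are
implemented exactly (boundary sweeps), the copy-number inversion is an
exact inverse of its forward model, and the full pipeline recovers
planted truth through real file formats. What they do not show:
robustness to segmentation errors, probe-level noise, alignment
artifacts, or cellularity/ploidy misestimation — those live upstream of
this layer and are not modelled. A borderline variant (true AF 5%
against the 4% cutoff) is recovered at the rate given by the binomial
sampling tail, and the corresponding test asserts exactly that
computed tail probability rather than a round number.

## Problem sizes and numerical conventions

The test suite uses: the full recovery grid $n \le 12$,
$c \in \{0.35, 0.40, \dots, 1.0\}$, $\psi \in \{2, 4\}$ (~1,300 cells);
a ~4,400-combination brute-force equivalence grid for the cascade; a
seeded 8-sample × 50-variant run for end-to-end recovery; and 200
seeded replicates for the borderline-variant rate — sizes chosen so
each suite completes in seconds while exercising every rule branch.
Boundary sweeps construct their grids as integer ratios (e.g.
`(1:40)/200` rather than accumulating `seq()` steps) so that sweep
points sit exactly on the decision thresholds being measured.

Other conventions: internal coordinates are 0-based half-open with SEG
(1-based inclusive) and VCF (1-based) converted at the I/O boundary,
isolating off-by-one risk in the readers/writers; the genome build is
carried as a configuration string, not hard-coded; pseudonyms are keyed
MD5 digests (deterministic per key, distinct across keys and patients);
threshold sets are hashed into report provenance so any configuration
drift between runs is visible.

## Known limitations

- No segmentation, probe normalization, or ploidy/cellularity
  estimation: these are inputs, assumed correct.
- Copy-number states are integer; subclonal (fractional) states are out
  of scope.
- Consequence annotation is an input column, not computed from
  transcripts.
- The board's drug-assignment rules are not implemented — published
  sources state such rules exist but do not publish them, so the report
  deliberately stops at prioritized molecular abnormalities.
- The tracking registry offers atomic replacement but no multi-writer
  concurrency control.
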