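Package: mtbpipe
Title: Gene-Level Copy-Number Calling, Somatic Variant Triage and
    Molecular Tumor Board Reporting for Clinical Panels
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale clinical bioinformatics decision layer for
    precision-oncology panels. Calls absolute, cellularity- and
    ploidy-aware gene copy-number statuses (deletion, loss, normal,
    gain, amplification, plus loss of heterozygosity) from segmented
    tumor profiles, detects focal events and triggers
    immunohistochemistry validation requests; triages somatic variant
    calls from an amplicon panel through an auditable filter cascade
    (allele frequency, depth, strand balance, polymorphism and hotspot
    annotation, homopolymer and repeat context, run-level recurrence);
    assembles name-blinded molecular tumor board reports; and tracks
    each sample through the workflow with deadlines and an append-only
    audit log. Ships a seeded synthetic-data generator so every stage
    is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
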