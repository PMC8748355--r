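Package: duplexsim
Title: Duplex Consensus Error Correction with Single-Strand Artifact
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for UMI-free duplex consensus sequencing error correction
    and for studying the single-strand (SS) artifact mechanism that limits
    its accuracy. Aligned paired-end read pairs sharing fragment coordinates
    are grouped into same-position groups, split by orientation, and reduced
    to double-strand consensus sequences; strand-resolved (12-type) and
    pooled (6-type) base-substitution spectra are computed with read-end
    clipping, known-variant masking, and group comparison by Student's t or
    Dunnett's many-to-one test. A mechanistic simulator generates sheared
    dsDNA fragments carrying 5'/3' overhangs, nicks and gaps, places guanine
    damage (8-oxoG, imidazolone, deaminated cytosine) in SS regions only,
    models single-strand-specific nuclease digestion (S1, mung bean
    nuclease, RecJf) and end-repair fill-in, and emits FASTQ, truth-aligned
    SAM and truth tables, so that end-repair error fixation, read clipping,
    and nuclease-based error removal can be reproduced without real
    sequencing data. Coverage, per-cycle base composition and same-position
    group misassignment diagnostics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    mvtnorm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse
Config/testthat/edition: 3
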