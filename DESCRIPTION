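Package: umisim
Title: Simulation and Analysis of Single-Molecule Barcoded PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the full unique-molecular-identifier (UMI) workflow used
    in barcoded amplicon sequencing: generation of barcode pools (uniform,
    normal, lognormal or empirical mixtures), labelling of template molecules
    with clash accounting, PCR amplification under six branching-process
    models (constant efficiency, target degradation, resource competition,
    resource decay, per-cycle variable efficiency, and inherited per-lineage
    efficiency), per-base replication and sequencing error, and random
    subsampling of the amplified pool.  Provides the statistical toolkit used
    to analyse barcode family sizes: zero-truncated Poisson and mixed-Poisson
    maximum-likelihood fits, chi-squared goodness of fit, coefficient of
    variation, barcode-clash analytics, rank comparison of runs and GC
    content, plus reproducible end-to-end experiment drivers with FASTQ, TSV
    and JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
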