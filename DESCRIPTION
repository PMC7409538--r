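Package: driploop
Title: Genome-Wide R-Loop (DRIP-Seq) Landscape and Differential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for genome-wide R-loop mapping by DRIP-seq:
    per-sample broad enrichment peak calling against input with an RNase-H
    sensitivity control, consensus peak construction across conditions,
    negative-binomial Wald tests for R-loop gain and loss, peak-to-gene
    landscape annotation (feature categories, nearest and second-nearest gene
    distances, TSS/TTS proximity, GC and CpG profiles, metagene coverage), and
    detection of intergenic antisense transcription upstream of R-loop gain
    peaks from stranded RNA-seq. Includes a seeded synthetic-data generator
    that plants peaks, differential effects and antisense loci with
    machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
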