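Package: methlift
Title: Harmonize Infinium DNA Methylation BeadChip Data Across Array Platforms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Translates Infinium DNA methylation BeadChip measurements between
    array platforms (HM27/HM450/EPIC/EPICv2/MSA-style). Parses the suffixed
    probe naming convention introduced with EPICv2, maps probes across
    platforms by cg-number prefix, converts beta-value matrices with replicate
    aggregation (mean or best detection p-value) and replicate broadcast,
    builds empirical high-confidence mappings from paired same-sample
    experiments to filter platform-specific biases, imputes completely missing
    probes from tissue-indexed reference panels of per-probe medians with
    SD-based confidence filtering, and lifts over raw signal intensities for
    copy-number workflows. A synthetic-fixture generator produces manifests,
    cohorts, reference panels and paired experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, MethylationArray, Preprocessing
RoxygenNote: 7.3.3
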