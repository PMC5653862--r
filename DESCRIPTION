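Package: aeclass
Title: Ontology-Aware Detection of Drug Class Effects on Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects adverse-event (AE) class effects of drug classes from
    curated drug-AE association tables and is-a ontology hierarchies.
    Implements the proportional class level ratio (PCR), the class-level
    proportional reporting ratio (C-PRR) with its 2x2 contingency table, a
    class-level Pearson chi-squared statistic, and the combined
    significance filter (PCR = 1, C-PRR >= 2, chi-squared > 4, minimum
    class size); builds clustered PCR heatmap matrices over drug-class and
    AE-class axes; and generates synthetic association tables with planted
    class effects for power and false-positive studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pheatmap,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
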