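Package: sarcotrack
Title: Sarcomere Morphometry, Protein Turnover and Muscle-Function Screen Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for adult Drosophila flight-muscle
    maintenance studies. Measures sarcomere length, thin-filament length and
    H-zone width from fluorescence intensity profiles (phalloidin or M-line
    channels) with sub-pixel peak detection; quantifies pulse-chase
    protein-turnover time courses (onset, peak, half-life, Z-disc to
    sarcomere-body enrichment); computes comparative-Ct relative expression and
    percent knockdown from qPCR cycle-threshold tables; scores
    negative-geotaxis climbing assays, detects sustained loss of climbing
    ability and classifies phenotype severity; and summarizes screens with
    GO-term enrichment ratios and severity-annotated interaction networks.
    Includes synthetic-data generators with known ground truth for every input
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
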