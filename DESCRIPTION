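Package: progmeth
Title: Differential DNA Methylation Analysis of Progeroid Fibroblasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-wide Infinium DNA methylation analysis of
    progeroid (Cockayne syndrome) versus non-progeroid (wild-type and UV-sensitive
    syndrome) fibroblasts: dual-platform (450k/EPIC) probe intersection,
    empirical-Bayes batch adjustment, sex-probe removal and replicate averaging;
    per-probe ANOVA calling of differentially methylated positions with
    Benjamini-Hochberg correction and a 10% delta filter; sliding-window MANOVA
    (Pillai trace) calling of differentially methylated regions with a stringent
    group-separation filter; CpG island/shore/shelf/open-sea enrichment;
    epigenetic-clock age prediction and age-acceleration residuals; cross-dataset
    concordance; methylation-expression correlation; and probe-count-adjusted
    gene-set testing. Ships a synthetic dual-platform cohort generator with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sva
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
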