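Package: virotrace
Title: Strain-Level Virome Transmission and Phage-Host Co-Transmission Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal mother-infant gut virome studies: rule-based
    curation of viral scaffolds from annotation feature tables, breadth-filtered
    RPKM abundance profiles, longitudinal virome dynamics (diversity, retention
    from baseline, persistent/transient partition, temperate phage fraction),
    Kimura 2-parameter strain distances from consensus-sequence alignments,
    strain-sharing cutpoint inference (kernel-smoothed Youden index with an
    empirical-FDR fallback), permutation Wilcoxon tests for mother-infant strain
    transmission, and partial Mantel tests of phage-host co-transmission with a
    non-random linkage statistic. Includes a synthetic cohort generator with a
    continuous-time K80 substitution model and planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
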