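Package: cashr
Title: Comparative Analysis of Shapley Values for Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential expression analysis of two-group log2 expression
    matrices by Comparative Analysis of Shapley values (CASh). Expression
    profiles are discretized against control-group thresholds into boolean
    over- and under-expression matrices, each of which defines a microarray
    coalitional game whose Shapley value scores the relevance of every gene;
    case-versus-control Shapley contrasts are tested against a bootstrap
    resampling null and gated by fold change and false discovery rate.
    Includes the classical comparators (gene-wise Welch t-test and
    empirical-Bayes moderated t with Benjamini-Hochberg correction),
    Fisher's-exact over-representation analysis against GMT gene sets,
    a synthetic two-group microarray generator with known ground truth,
    and an end-to-end pipeline producing plot-ready tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
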