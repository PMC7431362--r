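Package: igscore
Title: Information-Gain Statistical Potentials for Protein Model Quality
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds distance-dependent knowledge-based scoring functions for
    ranking predicted protein structures by quality. Trains per-atom-pair-type
    distance distributions from a corpus of native chains (kernel density
    estimation with Scott bandwidths, weighted-mean reference state) and scores
    models with four formalisms: the classical potential of mean force (PMF),
    the total information gain (TIG) score based on relative frequency
    differences, and two mock control scores (MCK1, MCK2). Includes a
    category-stratified pairwise-ranking benchmark (accuracy, average predicted
    rank, per-target Pearson correlation, Wilcoxon signed-rank comparison) and
    a synthetic generator of protein-like Calpha traces with graded-noise
    decoys of known quality, so the full train/score/benchmark pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
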