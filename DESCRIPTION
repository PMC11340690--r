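Package: mbtopics
Title: Microbiome Community Typing by Latent Dirichlet Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers microbial "community types" in genus-level 16S count
    tables by topic modeling. Fits latent Dirichlet allocation by variational
    expectation-maximization, selects the number of topics by grid search over
    density (mean pairwise topic cosine) and spectral-divergence criteria,
    converts per-sample topic probabilities into read-level topic abundances,
    tests topics and genera for differential abundance between patient groups
    (bias-corrected compositional linear models and Wilcoxon rank-sum tests
    with Benjamini-Hochberg adjustment), and validates community types across
    independent cohorts by cosine similarity of topic-term distributions.
    Includes a generative simulator with group-dependent topic prevalence and
    cross-cohort shared topics, and a deterministic two-cohort pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
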