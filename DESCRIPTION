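Package: stagetrend
Title: Trend Genes Along Ordered Disease Stages via Fuzzy Gamma Screening and SOM Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose expression rises or falls along clinically
    ordered disease stages. Each gene is screened with a Goodman-Kruskal
    gamma rank correlation against the ordinal stage variable, using a fuzzy
    tie tolerance (a fraction of the gene's interquartile range) so that
    near-equal noisy values are treated as partial ties, with permutation
    p-values and Benjamini-Hochberg false discovery rate control. Selected
    genes are standardized, oriented, intensity-sorted and clustered on a
    self-organizing map; each pattern is annotated with the stage coordinate
    at which half of its total expression change is reached, classifying
    trends as early or late. A staged negative-binomial RNA-seq simulator
    with ground-truth trend archetypes supports validation, and a pipeline
    runner plus command-line tool make runs reproducible end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
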