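Package: crabtree
Title: Quantifying the Crabtree Effect from Batch Fermentation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative quantification of aerobic ethanol
    fermentation (the Crabtree effect) in budding yeasts. Simulates aerobic
    batch cultivations with a respiratory-bottleneck overflow-metabolism
    model, extracts physiological metrics from culture time series
    (specific growth rate, yields, specific rates, respiration ratio,
    C-mole carbon balance), classifies Crabtree phenotypes from yield
    space, and runs the grouped comparative statistics (ANOVA,
    Kruskal-Wallis, pairwise Welch t-tests, Pearson and Spearman
    correlation) over a packaged 37-strain Saccharomycetaceae physiology
    dataset with phylogenetic group assignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
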