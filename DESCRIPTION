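Package: foragr
Title: Simulation and Analysis of Dynamic Foraging (Two-Armed Bandit) Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic simulator for rodent dynamic foraging tasks
    (two-armed bandit with baited probabilistic rewards and uncued block
    reversals, in freely moving and head-fixed variants), together with
    synthetic behaving agents (win-stay/lose-switch, biased random,
    Q-learning with softmax choice), cohort generation with genotype and
    sex structure, the full behavioral-metric pipeline (learning curves,
    reversal-aligned choice probability, win-stay/lose-switch fractions,
    outcome-conditioned intertrial intervals, moving-average choice
    traces), and the group-comparison statistics used in such studies
    (mixed-design repeated-measures ANOVA, Mann-Whitney U tests with
    Bonferroni correction). All user-facing functions take data frames
    and return tibbles.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
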