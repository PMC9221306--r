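Package: courtsupp
Title: Courtship Conditioning Suppression, Olfactory Preference, and
    Differential-Expression Set Concordance Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of the conditioned courtship suppression
    paradigm in Drosophila: courtship and learning indices from scored
    ethogram event logs, sampled and exhaustive two-sided randomization
    tests (within-strain training effects, between-strain learning-index
    contrasts, and retention contrasts), the T-maze olfactory preference
    index with exact and asymptotic Mann-Whitney comparisons, and
    post-differential-expression set analytics (direction-consistent gene
    selection across replicate strains, Venn partitioning, one-sided Fisher
    gene-set enrichment with dot-plot metrics, and delta-delta-Ct fold
    changes). Includes a synthetic-data generator emulating the strain
    phenotypes the analyses are designed to detect, and deterministic
    pipeline drivers over all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
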