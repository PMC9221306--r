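#!/usr/bin/env Rscript
# Stage 1 — simulate the full study dataset.
#
# Generates a synthetic courtship-conditioning experiment with the three
# built-in strain phenotypes (control-like learner; CBS-like non-learner;
# CSE-like learner losing retention by day 8) at 20 males per cohort over
# days 0/2/8, binomial T-maze olfactory replicates (all genotypes share the
# control attraction probability — the strains retain normal repulsion),
# and five DE contrast tables with a planted, predominantly down-regulated
# and cross-contrast concordant gene signal concentrated in terms T01/T02.

library(courtsupp)

out <- "results/synthetic"
paths <- run_simulate(run_config(out_dir = out, seed = 20220526))

eth <- suppressMessages(read_ethograms(paths[["ethograms"]]))
cat(sprintf("simulated %d males across %d strain x timepoint x condition groups\n",
            nrow(eth), nrow(unique(eth[c("strain", "condition", "timepoint")]))))
cat(sprintf("olfactory: %d replicates, %d genotypes\n",
            nrow(read_olfactory(paths[["olfactory"]])), 4))
cat("wrote:", paste(basename(paths), collapse = ", "), "\n")
cat("outputs under", out, "\n")
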