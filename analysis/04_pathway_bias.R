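#!/usr/bin/env Rscript
# Pathway bias: fit the pAKT->pERK scale factor by minimizing the two-sample
# Cramer-von Mises distance between the fold-change distributions, then
# compute the arctangent bias angle per (cell line, ligand); 45 deg means
# balanced ERK/AKT activation.

suppressMessages(library(gfresponse))

responses <- readr::read_csv("results/condition_responses.csv",
                             show_col_types = FALSE)
bias <- pathway_bias_table(responses)    # alpha fitted on doubly-significant pairs
readr::write_csv(bias, "results/pathway_bias.csv")

cat(sprintf("Fitted pathway scale factor alpha = %.3f\n", bias$alpha[1]))
both <- bias[bias$sig_perk & bias$sig_pakt, ]
cat(sprintf("Median bias angle over %d doubly-significant pairs: %.1f deg\n",
            nrow(both), median(both$bias_angle)))
by_lig <- tapply(both$bias_angle, both$ligand, median)
cat("Most ERK-biased ligand:", names(which.min(by_lig)),
    sprintf("(%.1f deg)\n", min(by_lig)))
cat("Most AKT-biased ligand:", names(which.max(by_lig)),
    sprintf("(%.1f deg)\n", max(by_lig)))
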