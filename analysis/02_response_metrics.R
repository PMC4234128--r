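#!/usr/bin/env Rscript
# Replicate averaging, control model, fold-changes and significance calls.
# A cell-ligand combination is significant when any post-stimulation time
# point reaches 2 SD above the control mean (about a 1.2-fold change here).

suppressMessages(library(gfresponse))

cube <- read_response_table("results/data/response_cube.csv")
model <- fit_control_model(cube)
responses <- compute_fold_changes(cube, model)
dir.create("results", showWarnings = FALSE)
readr::write_csv(responses, "results/condition_responses.csv")

hi <- responses[responses$dose == 100, ]
for (tg in c("pERK", "pAKT")) {
  cat(sprintf("%s: %.1f%% of cell-ligand combinations significant at 100 ng/ml\n",
              tg, 100 * mean(hi$significant[hi$target == tg])))
}
strongest <- hi[which.max(hi$max_fc), ]
cat(sprintf("Strongest response: %s/%s %s, %.0f-fold\n",
            strongest$cell_line, strongest$ligand, strongest$target,
            10^strongest$max_fc))
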