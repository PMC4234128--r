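#!/usr/bin/env Rscript
# Kinetic classification (k-means, k = 4: sustained / transient / late / none)
# and dose-sensitivity classification (75% rule) with the summary table.

suppressMessages(library(gfresponse))

responses <- readr::read_csv("results/condition_responses.csv",
                             show_col_types = FALSE)
responses <- assign_kinetics(responses, k = 4, seed = 20140321L, restarts = 10)
smry <- build_response_summary(responses)
write_summary_table(smry, "results/response_summary.csv")
cent <- tibble::as_tibble(attr(responses, "centroids"),
                          .name_repair = ~paste0("t", c(10, 30, 90)))
cent$label <- attr(responses, "centroid_labels")
readr::write_csv(cent, "results/kinetic_centroids.csv")
readr::write_csv(responses, "results/condition_responses_classified.csv")

sig <- responses$kinetic[responses$significant]
cat("Kinetic classes among significant responses:\n")
print(round(100 * prop.table(table(sig)), 1))
cat("Sensitivity classes among responsive (cell, ligand, target):\n")
resp <- smry$sensitivity[smry$sensitivity != "none"]
print(round(100 * prop.table(table(resp)), 1))
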