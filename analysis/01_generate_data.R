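#!/usr/bin/env Rscript
# Generate the synthetic study panel: 39 breast-cancer-like cell lines x 15
# growth factors, pERK/pAKT at 10/30/90 min after 1 or 100 ng/ml stimulation,
# in duplicate, plus basal RTK profiles, subtypes and the ligand-receptor map.
# Writes the four input tables and the planted ground truth under results/data.

suppressMessages(library(gfresponse))

seed <- 20140321L   # fixed workflow seed
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

pan <- generate_panel(39, 15, seed = seed)

write_response_table(pan$cube, file.path(outdir, "response_cube.csv"))
write_basal_table(pan$basal, file.path(outdir, "basal_profiles.csv"))
readr::write_csv(pan$lr_map, file.path(outdir, "ligand_receptor_map.csv"))
readr::write_csv(pan$subtypes, file.path(outdir, "subtypes.csv"))
readr::write_csv(pan$truth, file.path(outdir, "ground_truth.csv"))

cat("Panel:", length(unique(pan$subtypes$cell_line)), "cell lines,",
    length(unique(pan$lr_map$ligand)), "ligands,",
    nrow(pan$cube), "measurements\n")
cat("Censored basal values:", sum(pan$basal$below_detection), "of",
    nrow(pan$basal), "\n")
cat("Planted responder fraction (pERK):",
    round(mean(pan$truth$sig_high[pan$truth$target == "pERK"]), 3), "\n")
cat("Planted responder fraction (pAKT):",
    round(mean(pan$truth$sig_high[pan$truth$target == "pAKT"]), 3), "\n")
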