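#!/usr/bin/env Rscript
# Node-edge signaling graphs: one per cell line plus interquartile-mean
# aggregates per subtype, normalized panel-wide; exported as GraphML/JSON.

suppressMessages(library(gfresponse))

responses <- readr::read_csv("results/condition_responses.csv",
                             show_col_types = FALSE)
basal <- read_basal_table("results/data/basal_profiles.csv")
subtypes <- read_subtype_table("results/data/subtypes.csv")
lr_map <- read_ligand_receptor_map("results/data/ligand_receptor_map.csv")

induction <- overall_max_induction(responses)
norms <- graph_norms(basal, induction)
gdir <- "results/graphs"
dir.create(gdir, recursive = TRUE, showWarnings = FALSE)

for (cl in unique(induction$cell_line)) {
  g <- build_graph(cl, basal, induction, lr_map, norms)
  export_graph(g, file.path(gdir, paste0(cl, ".graphml")), "graphml")
}
for (st in unique(subtypes$subtype)) {
  g <- build_subtype_graph(st, basal, induction, lr_map, subtypes, norms)
  export_graph(g, file.path(gdir, paste0("subtype_", st, ".json")), "json")
  e <- igraph::as_data_frame(g, "edges")
  resp <- e[e$kind == "response" & e$significant, ]
  cat(sprintf("%s: %d significant aggregate response edges, strongest %s -> %s\n",
              st, nrow(resp), resp$from[which.max(resp$weight01)],
              resp$to[which.max(resp$weight01)]))
}
cat("Wrote", length(unique(induction$cell_line)), "per-line GraphML files and",
    length(unique(subtypes$subtype)), "subtype JSON graphs to", gdir, "\n")
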