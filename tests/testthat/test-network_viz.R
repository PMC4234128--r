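panel_fixture <- function(seed = 19, sigma = 0) {
  pan <- generate_panel(6, 3, seed = seed,
                        config = panel_config(sigma = sigma))
  res <- compute_fold_changes(pan$cube)
  ind <- overall_max_induction(res)
  norms <- graph_norms(pan$basal, ind)
  list(pan = pan, ind = ind, norms = norms)
}

test_that("interquartile mean matches its brute-force oracle", {
  expect_equal(interquartile_mean(c(5, 5, 5, 5)), 5)
  expect_equal(interquartile_mean(c(1, 2, 3, 4, 100)),
               iqm_oracle(c(1, 2, 3, 4, 100)))
  expect_equal(interquartile_mean(7.3), 7.3)
  withr::with_seed(23, {
    for (i in 1:100) {
      x <- rnorm(sample(1:30, 1), sd = 10)
      expect_equal(interquartile_mean(x), iqm_oracle(x), tolerance = 1e-12)
      expect_gte(interquartile_mean(x), min(x))
      expect_lte(interquartile_mean(x), max(x))
    }
  })
  expect_error(interquartile_mean(numeric(0)), "no finite")
})

test_that("interquartile mean is robust to a single extreme outside the IQR", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- x; y[1] <- -1e9       # stays below the 25th percentile
  z <- x; z[7] <- 1e9        # stays above the 75th percentile
  expect_equal(interquartile_mean(y), interquartile_mean(x))
  expect_equal(interquartile_mean(z), interquartile_mean(x))
})

test_that("normalization maps panel extrema to 0 and 1", {
  fx <- panel_fixture()
  graphs <- lapply(unique(fx$ind$cell_line), function(cl) {
    build_graph(cl, fx$pan$basal, fx$ind, fx$pan$lr_map, fx$norms)
  })
  sizes <- unlist(lapply(graphs, igraph::vertex_attr, name = "size01"))
  shades <- unlist(lapply(graphs, igraph::vertex_attr, name = "shade01"))
  weights <- unlist(lapply(graphs, igraph::edge_attr, name = "weight01"))
  expect_true(all(sizes >= 0 & sizes <= 1))
  expect_true(all(shades >= 0 & shades <= 1))
  expect_true(all(weights >= 0 & weights <= 1))
  # the panel-wide maximum expression sits at exactly 1 in some graph
  expect_equal(max(sizes), 1)
  kept <- unlist(lapply(graphs, function(g) {
    igraph::edge_attr(g, "weight01")[igraph::edge_attr(g, "kind") == "response"]
  }))
  expect_equal(max(kept), 1)
  expect_equal(min(kept), 0)
})

test_that("below-detection receptors get minimal size and a flag", {
  fx <- panel_fixture(seed = 20)   # seed chosen to include censored receptors
  basal <- fx$pan$basal
  below <- basal[basal$below_detection & basal$kind == "expression", ]
  expect_gt(nrow(below), 0)
  cl <- below$cell_line[1]
  g <- build_graph(cl, basal, fx$ind, fx$pan$lr_map, fx$norms)
  v <- igraph::as_data_frame(g, "vertices")
  hit <- v[v$name == below$analyte[1], ]
  expect_true(hit$below_detection)
  expect_equal(hit$size01, 0)
})

test_that("non-significant responses become flagged edges", {
  fx <- panel_fixture()
  ns <- fx$ind[!fx$ind$significant, ][1, ]
  expect_false(is.na(ns$cell_line))   # the fixture plants non-responders
  g <- build_graph(ns$cell_line, fx$pan$basal, fx$ind, fx$pan$lr_map,
                   fx$norms)
  e <- igraph::as_data_frame(g, "edges")
  hit <- e[e$kind == "response" & e$from == ns$ligand & e$to == ns$target, ]
  expect_false(hit$significant)
})

test_that("a singleton subtype aggregate equals the single line's graph", {
  fx <- panel_fixture()
  subtypes <- fx$pan$subtypes
  solo <- names(which(table(subtypes$subtype) == 1))
  if (length(solo) == 0) {
    subtypes$subtype[subtypes$cell_line == "CL01"] <- "HRpos"
    subtypes$subtype[subtypes$cell_line != "CL01"] <- "TNBC"
    solo <- "HRpos"
  }
  line <- subtypes$cell_line[subtypes$subtype == solo[1]]
  g_line <- build_graph(line, fx$pan$basal, fx$ind, fx$pan$lr_map, fx$norms)
  g_sub <- build_subtype_graph(solo[1], fx$pan$basal, fx$ind, fx$pan$lr_map,
                               subtypes, fx$norms)
  expect_true(graphs_equivalent(g_line, g_sub))
  expect_error(
    build_subtype_graph("HER2amp", fx$pan$basal, fx$ind, fx$pan$lr_map,
                        subtypes[subtypes$subtype != "HER2amp", ], fx$norms),
    "empty subtype")
})

test_that("aggregation happens before normalization", {
  # identical lines: the aggregate must equal each line bit for bit
  fx <- panel_fixture()
  basal2 <- fx$pan$basal[fx$pan$basal$cell_line == "CL01", ]
  basal_dup <- dplyr::bind_rows(
    basal2,
    transform(basal2, cell_line = "CL99")
  )
  ind2 <- fx$ind[fx$ind$cell_line == "CL01", ]
  ind_dup <- dplyr::bind_rows(ind2, transform(ind2, cell_line = "CL99"))
  st <- tibble::tibble(cell_line = c("CL01", "CL99"), subtype = "TNBC")
  g_line <- build_graph("CL01", basal_dup, ind_dup, fx$pan$lr_map, fx$norms)
  g_agg <- build_subtype_graph("TNBC", basal_dup, ind_dup, fx$pan$lr_map,
                               st, fx$norms)
  expect_true(graphs_equivalent(g_line, g_agg))
})

test_that("graph export round-trips losslessly in both formats", {
  fx <- panel_fixture()
  g <- build_graph("CL01", fx$pan$basal, fx$ind, fx$pan$lr_map, fx$norms)
  for (fmt in c("graphml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, path, fmt)
    back <- import_graph(path, fmt)
    expect_true(graphs_equivalent(g, back), label = fmt)
  }
  # JSON export parses under a standard parser and an edgeless graph is valid
  path <- withr::local_tempfile(fileext = ".json")
  g0 <- igraph::delete_edges(g, igraph::E(g))
  export_graph(g0, path, "json")
  doc <- jsonlite::read_json(path)
  expect_named(doc, c("nodes", "links"))
  expect_length(doc$links, 0)
  back0 <- import_graph(path, "json")
  expect_equal(igraph::vcount(back0), igraph::vcount(g))
  expect_error(export_graph(g, path, "dot"), "arg")
})
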