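# End-to-end orchestration: read (or take) the four input tables, run every
# stage, write the output bundle and a run manifest.

#' Run the full response-analysis pipeline
#'
#' Stages: control model and fold-changes with significance calls; k-means
#' kinetic classification; dose-sensitivity classification; the summary
#' table; pathway scale fit and bias records; correlation panels against the
#' basal profiles; per-line and per-subtype signaling graphs; and a manifest
#' capturing configuration, seed, package version and input checksums.
#' Identical inputs and configuration produce identical outputs.
#'
#' @param inputs Either a list with elements `cube`, `basal`, `lr_map` and
#'   optionally `subtypes` (as returned by [generate_panel()]), or a named
#'   list of file paths (`response`, `basal`, `lr_map`, `subtypes`) read with
#'   the package readers.
#' @param config Configuration list as from [default_run_config()] /
#'   [read_run_config()].
#' @param outdir Output directory; created if missing. `NULL` skips writing.
#' @return List with `responses`, `summary`, `bias`, `alpha`, `correlations`,
#'   `graphs`, `subtype_graphs`, `manifest` (invisibly writes CSV/JSON files
#'   when `outdir` is given).
#' @export
run_pipeline <- function(inputs, config = default_run_config(),
                         outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  loaded <- stage("read_inputs", load_pipeline_inputs(inputs, config))
  cube <- loaded$cube
  basal <- loaded$basal
  lr_map <- loaded$lr_map
  subtypes <- loaded$subtypes

  responses <- stage("response_metrics", {
    model <- fit_control_model(cube)
    compute_fold_changes(cube, model, sd_multiplier = config$sd_multiplier)
  })

  responses <- stage("kinetics", {
    assign_kinetics(responses, k = config$kinetics$k,
                    seed = config$kinetics$seed,
                    restarts = config$kinetics$restarts)
  })

  summary <- stage("sensitivity", {
    build_response_summary(
      responses, ratio_threshold = config$sensitivity$ratio_threshold,
      baseline = config$sensitivity$baseline)
  })

  bias <- stage("bias", {
    pathway_bias_table(
      responses, alpha = config$scale_fit$fixed_alpha,
      dose = config$scale_fit$dose,
      significant_only = isTRUE(config$scale_fit$significant_only),
      grid = config$scale_fit$grid %||% 10^seq(-1, 1, length.out = 121))
  })

  correlations <- stage("correlate", {
    out <- list()
    for (tg in PANEL_TARGETS) {
      for (lg in unique(cube$ligand[cube$ligand != CONTROL_LIGAND])) {
        slice <- dplyr::filter(responses, .data$target == tg,
                               .data$ligand == lg, .data$dose == 100)
        if (nrow(slice) < 3) next
        panel <- correlate_panel(slice, basal,
                                 method = config$correlation$method,
                                 adjust = config$correlation$adjust)
        panel$target <- tg
        panel$ligand <- lg
        out[[paste(tg, lg)]] <- panel
      }
    }
    dplyr::bind_rows(out)
  })

  induction <- overall_max_induction(responses)
  norms <- graph_norms(basal, induction)
  graphs <- stage("graphs", {
    lines <- unique(induction$cell_line)
    stats::setNames(lapply(lines, function(cl) {
      build_graph(cl, basal, induction, lr_map, norms)
    }), lines)
  })

  subtype_graphs <- NULL
  if (is.null(subtypes)) {
    warning("no subtype table supplied; skipping subtype-aggregate graphs")
  } else {
    subtype_graphs <- stage("subtype_graphs", {
      sts <- unique(subtypes$subtype)
      stats::setNames(lapply(sts, function(st) {
        build_subtype_graph(st, basal, induction, lr_map, subtypes, norms)
      }), sts)
    })
  }

  manifest <- list(
    package = "gfresponse",
    version = as.character(utils::packageVersion("gfresponse")),
    config = config,
    seed = config$kinetics$seed,
    alpha = unique(bias$alpha)[1],
    n_cell_lines = length(unique(induction$cell_line)),
    n_ligands = length(unique(induction$ligand)),
    input_checksums = loaded$checksums
  )

  result <- list(responses = responses, summary = summary, bias = bias,
                 alpha = unique(bias$alpha)[1], correlations = correlations,
                 graphs = graphs, subtype_graphs = subtype_graphs,
                 manifest = manifest)

  if (!is.null(outdir)) {
    stage("write_outputs", write_pipeline_outputs(result, outdir))
  }
  result
}

load_pipeline_inputs <- function(inputs, config) {
  checksums <- NULL
  if (!is.null(inputs$cube)) {
    cube <- response_cube(inputs$cube)
    basal <- basal_profiles(inputs$basal)
    lr_map <- validate_ligand_receptor_map(inputs$lr_map)
    subtypes <- if (is.null(inputs$subtypes)) NULL else
      validate_subtype_table(inputs$subtypes)
  } else {
    paths <- unlist(inputs[c("response", "basal", "lr_map", "subtypes")])
    checksums <- as.list(tools::md5sum(paths[file.exists(paths)]))
    cube <- read_response_table(inputs$response,
                                dialect = inputs$dialect %||% list())
    basal <- read_basal_table(inputs$basal,
                              thresholds = config$detection_threshold)
    lr_map <- read_ligand_receptor_map(inputs$lr_map)
    subtypes <- if (is.null(inputs$subtypes)) NULL else
      read_subtype_table(inputs$subtypes)
  }
  list(cube = cube, basal = basal, lr_map = lr_map, subtypes = subtypes,
       checksums = checksums)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$responses, file.path(outdir, "condition_responses.csv"))
  write_summary_table(result$summary, file.path(outdir, "response_summary.csv"))
  readr::write_csv(result$bias, file.path(outdir, "pathway_bias.csv"))
  if (nrow(result$correlations %||% tibble::tibble()) > 0) {
    readr::write_csv(result$correlations,
                     file.path(outdir, "correlation_panels.csv"))
  }
  cent <- attr(result$responses, "centroids")
  if (!is.null(cent)) {
    cent_df <- tibble::as_tibble(cent, .name_repair = ~paste0("t", POST_TIMES))
    cent_df$label <- attr(result$responses, "centroid_labels")
    readr::write_csv(cent_df, file.path(outdir, "kinetic_centroids.csv"))
  }
  gdir <- file.path(outdir, "graphs")
  dir.create(gdir, showWarnings = FALSE)
  for (nm in names(result$graphs)) {
    export_graph(result$graphs[[nm]], file.path(gdir, paste0(nm, ".graphml")),
                 format = "graphml")
  }
  for (nm in names(result$subtype_graphs %||% list())) {
    export_graph(result$subtype_graphs[[nm]],
                 file.path(gdir, paste0("subtype_", nm, ".json")),
                 format = "json")
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(outdir)
}
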