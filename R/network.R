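# Node-edge signaling graphs: ligands wired to receptors by published binding,
# ligands wired to pERK/pAKT by response strength. Node size encodes log10
# expression, node shade log10 basal phosphorylation, edge weight the maximal
# induction; everything min-max normalized against panel-wide extrema.

#' Panel-wide normalization extrema for graph attributes
#'
#' @param basal Basal-profile tibble covering the whole panel.
#' @param induction Output of [overall_max_induction()] for the whole panel.
#' @return List of `c(min, max)` ranges: `expression`, `phosphorylation`, and
#'   `response` (one range per target).
#' @export
graph_norms <- function(basal, induction) {
  expr <- basal$value[basal$kind == "expression"]
  phos <- basal$value[basal$kind == "phosphorylation"]
  resp <- split(induction$max_fc, induction$target)
  list(
    expression = range(expr),
    phosphorylation = range(phos),
    response = lapply(resp, range)
  )
}

norm01 <- function(x, rng) {
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  pmin(pmax((x - rng[1]) / (rng[2] - rng[1]), 0), 1)
}

#' Build the signaling graph of one cell line
#'
#' Nodes are ligands, receptors and the two downstream targets; receptor and
#' target nodes carry `size01` (normalized log10 expression) and `shade01`
#' (normalized log10 basal phosphorylation). Edges are ligand-receptor binding
#' edges plus ligand-to-target response edges weighted by the overall maximal
#' induction normalized per target across the whole panel; non-significant
#' response edges are flagged. Below-detection nodes get the minimal size and
#' a flag; receptors with no phosphorylation measurement are marked
#' unmeasured.
#'
#' @param cell_line Cell-line identifier.
#' @param basal Basal-profile tibble (whole panel or the line's slice).
#' @param induction Output of [overall_max_induction()].
#' @param lr_map Ligand-receptor edge list.
#' @param norms Panel-wide extrema from [graph_norms()].
#' @return An `igraph` object.
#' @export
build_graph <- function(cell_line, basal, induction, lr_map, norms) {
  b <- basal[basal$cell_line == cell_line, ]
  r <- induction[induction$cell_line == cell_line, ]
  if (nrow(b) == 0 || nrow(r) == 0) {
    stop("cell line not covered by inputs: ", cell_line, call. = FALSE)
  }
  build_graph_from_values(b, r, lr_map, norms)
}

# Shared assembly for per-line and subtype-aggregate graphs: `b` holds one
# basal row per (analyte, kind), `r` one induction row per (ligand, target).
build_graph_from_values <- function(b, r, lr_map, norms) {
  receptors <- unique(lr_map$receptor)
  ligands <- unique(lr_map$ligand)
  kinase_of <- c(pERK = "ERK", pAKT = "AKT")

  node_attr <- function(analyte, kind, rng) {
    row <- b[b$analyte == analyte & b$kind == kind, ]
    if (nrow(row) == 0) {
      return(list(value = NA_real_, size = NA_real_, below = FALSE,
                  measured = FALSE))
    }
    list(value = row$value[1], size = norm01(row$value[1], rng),
         below = isTRUE(row$below_detection[1]), measured = TRUE)
  }

  nodes <- list()
  for (lg in ligands) {
    nodes[[lg]] <- tibble::tibble(name = lg, role = "ligand", size01 = 1,
                                  shade01 = 0, below_detection = FALSE,
                                  measured = TRUE)
  }
  for (rc in receptors) {
    ex <- node_attr(rc, "expression", norms$expression)
    ph <- node_attr(paste0("p", rc), "phosphorylation", norms$phosphorylation)
    size <- if (ex$below) 0 else ex$size
    nodes[[rc]] <- tibble::tibble(
      name = rc, role = "receptor",
      size01 = ifelse(is.na(size), 0, size),
      shade01 = ifelse(ph$measured, ph$size, 0),
      below_detection = ex$below, measured = ph$measured
    )
  }
  for (tg in PANEL_TARGETS) {
    ex <- node_attr(kinase_of[[tg]], "expression", norms$expression)
    ph <- node_attr(tg, "phosphorylation", norms$phosphorylation)
    size <- if (isTRUE(ex$below)) 0 else ex$size
    nodes[[tg]] <- tibble::tibble(
      name = tg, role = "target",
      size01 = ifelse(is.na(size), 0.5, size),
      shade01 = ifelse(ph$measured, ph$size, 0),
      below_detection = isTRUE(ex$below) | isTRUE(ph$below),
      measured = ph$measured
    )
  }
  node_df <- dplyr::bind_rows(nodes)

  bind_edges <- tibble::tibble(
    from = lr_map$ligand, to = lr_map$receptor, kind = "binding",
    weight01 = 1, significant = TRUE, target = NA_character_
  )
  resp_edges <- tibble::tibble(
    from = r$ligand, to = r$target, kind = "response",
    weight01 = vapply(seq_len(nrow(r)), function(i) {
      norm01(r$max_fc[i], norms$response[[r$target[i]]])
    }, numeric(1)),
    significant = r$significant, target = r$target
  )
  edge_df <- dplyr::bind_rows(bind_edges, resp_edges)
  igraph::graph_from_data_frame(edge_df, directed = TRUE, vertices = node_df)
}

#' Interquartile mean
#'
#' Mean of the values lying within the closed interval between the 25th and
#' 75th percentiles (linear-interpolation quantiles, type 7). Falls back to
#' the plain mean when no value lies inside the interval (possible only for
#' n = 2).
#'
#' @param values Numeric vector with at least one finite value.
#' @return The interquartile mean.
#' @export
interquartile_mean <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  inside <- values[values >= q[1] & values <= q[2]]
  if (length(inside) == 0) return(mean(values))
  mean(inside)
}

#' Build the aggregate signaling graph of a subtype
#'
#' Node and edge attributes are interquartile means across the subtype's cell
#' lines of the raw (pre-normalization) log10 values, normalized afterwards
#' with the panel-wide extrema; an aggregate response edge is significant when
#' at least half the lines respond, and a node is below detection when every
#' line is.
#'
#' @param subtype Subtype label.
#' @param basal Panel basal-profile tibble.
#' @param induction Output of [overall_max_induction()] for the panel.
#' @param lr_map Ligand-receptor edge list.
#' @param subtypes Subtype table (`cell_line`, `subtype`).
#' @param norms Panel-wide extrema from [graph_norms()].
#' @return An `igraph` object.
#' @export
build_subtype_graph <- function(subtype, basal, induction, lr_map, subtypes,
                                norms) {
  lines <- subtypes$cell_line[subtypes$subtype == subtype]
  if (length(lines) == 0) stop("empty subtype: ", subtype, call. = FALSE)
  b <- basal[basal$cell_line %in% lines, ] |>
    dplyr::group_by(.data$analyte, .data$kind) |>
    dplyr::summarise(value = interquartile_mean(.data$value),
                     below_detection = all(.data$below_detection),
                     .groups = "drop")
  r <- induction[induction$cell_line %in% lines, ] |>
    dplyr::group_by(.data$ligand, .data$target) |>
    dplyr::summarise(max_fc = interquartile_mean(.data$max_fc),
                     significant = mean(.data$significant) >= 0.5,
                     .groups = "drop")
  build_graph_from_values(b, r, lr_map, norms)
}

#' Export a signaling graph
#'
#' GraphML via igraph, or a node-link JSON document. Both formats round-trip
#' all node and edge attributes through [import_graph()].
#'
#' @param graph An `igraph` object.
#' @param path Output path.
#' @param format `"graphml"` or `"json"`.
#' @return The path, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    nodes <- igraph::as_data_frame(graph, what = "vertices")
    links <- igraph::as_data_frame(graph, what = "edges")
    jsonlite::write_json(list(nodes = nodes, links = links), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Import a signaling graph written by [export_graph()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"json"`.
#' @return An `igraph` object.
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # graphml stores logicals as 0/1; restore the flag types
    for (at in c("below_detection", "measured")) {
      if (at %in% igraph::vertex_attr_names(g)) {
        g <- igraph::set_vertex_attr(g, at,
                                     value = as.logical(igraph::vertex_attr(g, at)))
      }
    }
    if ("significant" %in% igraph::edge_attr_names(g)) {
      g <- igraph::set_edge_attr(g, "significant",
                                 value = as.logical(igraph::edge_attr(g, "significant")))
    }
    if ("target" %in% igraph::edge_attr_names(g)) {
      tg <- igraph::edge_attr(g, "target")
      tg[tg %in% c("NA", "")] <- NA_character_
      g <- igraph::set_edge_attr(g, "target", value = tg)
    }
    g
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- tibble::as_tibble(doc$nodes)
    links <- tibble::as_tibble(doc$links)
    if (nrow(links) == 0) {
      links <- tibble::tibble(from = character(0), to = character(0))
    }
    if ("target" %in% names(links)) {
      links$target <- as.character(links$target)
      links$target[links$target == "NA"] <- NA_character_
    }
    igraph::graph_from_data_frame(links, directed = TRUE, vertices = nodes)
  }
}
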