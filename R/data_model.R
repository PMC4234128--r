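# Shared data model: long-format tibbles validated at the package boundary.
#
# ResponseCube  one measurement per row:
#   cell_line, ligand ("control" at time 0), dose (ng/ml, NA for controls),
#   time (min), target (pERK/pAKT), replicate, value (log10 signal).
# BasalProfile  one analyte per row:
#   cell_line, analyte, kind (expression/phosphorylation), value (log10),
#   below_detection.
# LigandReceptorMap  edge list: ligand, receptor.
# SubtypeTable  cell_line, subtype (TNBC/HER2amp/HRpos).

CUBE_COLUMNS <- c("cell_line", "ligand", "dose", "time", "target",
                  "replicate", "value")
BASAL_COLUMNS <- c("cell_line", "analyte", "kind", "value", "below_detection")

#' Construct and validate a response cube
#'
#' A response cube holds the raw log10 phosphoprotein measurements indexed by
#' cell line, ligand, dose (ng/ml), time (minutes), downstream target and
#' replicate. Time-0 rows are unstimulated controls and must carry
#' `ligand = "control"` with a missing dose.
#'
#' @param df Data frame with columns `cell_line`, `ligand`, `dose`, `time`,
#'   `target`, `replicate`, `value`.
#' @return A validated tibble with class `response_cube`.
#' @export
response_cube <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(CUBE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("response cube is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[CUBE_COLUMNS]
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))
    stop("non-numeric measurement value(s) at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$value))) {
    stop("non-finite measurement value(s) at row(s): ",
         paste(head(which(!is.finite(df$value)), 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$target %in% PANEL_TARGETS)) {
    stop("unknown target(s): ",
         paste(setdiff(unique(df$target), PANEL_TARGETS), collapse = ", "),
         "; targets must be one of ", paste(PANEL_TARGETS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$time %in% PANEL_TIMES)) {
    stop("time points must lie in {", paste(PANEL_TIMES, collapse = ", "),
         "} minutes; found: ",
         paste(setdiff(unique(df$time), PANEL_TIMES), collapse = ", "),
         call. = FALSE)
  }
  stim <- df$time > 0
  if (any(!df$dose[stim] %in% PANEL_DOSES)) {
    stop("stimulated doses must lie in {", paste(PANEL_DOSES, collapse = ", "),
         "} ng/ml; found: ",
         paste(setdiff(unique(df$dose[stim]), PANEL_DOSES), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$ligand[!stim] != CONTROL_LIGAND)) {
    stop("time-0 rows must carry ligand = \"control\"", call. = FALSE)
  }
  if (any(!is.na(df$dose[!stim]))) {
    stop("control rows must carry a missing dose", call. = FALSE)
  }
  if (any(df$ligand[stim] == CONTROL_LIGAND)) {
    stop("stimulated rows may not use the reserved ligand name \"control\"",
         call. = FALSE)
  }
  # every cell line with stimulated data needs its time-0 control
  stim_lines <- unique(df$cell_line[stim])
  ctrl_lines <- unique(df$cell_line[!stim])
  orphans <- setdiff(stim_lines, ctrl_lines)
  if (length(orphans) > 0) {
    stop("missing time-0 controls for cell line(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("response_cube", class(df))
  df
}

#' Read a response cube from a delimited file
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect Optional named list: `delim` (default `","`) and a `columns`
#'   mapping from canonical names (`cell_line`, `ligand`, ...) to the file's
#'   column names.
#' @return A validated [response_cube()].
#' @export
read_response_table <- function(path, dialect = list()) {
  df <- read_dialect_table(path, dialect, CUBE_COLUMNS)
  df$dose <- suppressWarnings(as.numeric(df$dose))
  df$time <- as.numeric(df$time)
  df$replicate <- as.integer(df$replicate)
  val <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(val) & !is.na(df$value))) {
    stop("non-numeric value(s) at row(s): ",
         paste(head(which(is.na(val) & !is.na(df$value)), 5), collapse = ", "),
         call. = FALSE)
  }
  df$value <- val
  response_cube(df)
}

#' Write a response cube to a delimited file
#'
#' @param cube A [response_cube()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return The path, invisibly.
#' @export
write_response_table <- function(cube, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(unclass_cube(cube)), path, delim = delim)
  invisible(path)
}

unclass_cube <- function(cube) {
  class(cube) <- setdiff(class(cube), "response_cube")
  cube
}

read_dialect_table <- function(path, dialect, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- dialect$delim %||% ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  mapping <- dialect$columns %||% list()
  for (canon in names(mapping)) {
    src <- mapping[[canon]]
    if (!src %in% names(df)) {
      stop("dialect maps '", canon, "' to missing column '", src, "'",
           call. = FALSE)
    }
    names(df)[names(df) == src] <- canon
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[required]
}

#' Validate a collection of basal RTK profiles
#'
#' Basal profiles carry the unstimulated expression and phosphorylation level
#' of each analyte (RTKs plus ERK/AKT) in log10 units. Values below the assay's
#' detection threshold must be floored to the threshold and flagged; when
#' `thresholds` is supplied, flagged rows are checked against it.
#'
#' @param df Data frame with columns `cell_line`, `analyte`, `kind`, `value`,
#'   `below_detection`.
#' @param thresholds Optional named numeric vector of per-analyte detection
#'   thresholds (log10 units), or a single number used for all analytes.
#' @return A validated tibble.
#' @export
basal_profiles <- function(df, thresholds = NULL) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(BASAL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("basal profile table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[BASAL_COLUMNS]
  df$value <- as.numeric(df$value)
  df$below_detection <- as.logical(df$below_detection)
  if (!all(df$kind %in% c("expression", "phosphorylation"))) {
    stop("kind must be 'expression' or 'phosphorylation'", call. = FALSE)
  }
  if (any(!is.finite(df$value))) stop("non-finite basal value", call. = FALSE)
  if (!is.null(thresholds)) {
    thr <- analyte_thresholds(thresholds, unique(df$analyte))
    flagged <- which(df$below_detection)
    bad <- flagged[df$value[flagged] != thr[df$analyte[flagged]]]
    if (length(bad) > 0) {
      stop("below-detection row(s) whose value differs from the detection ",
           "threshold: row(s) ", paste(head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  df
}

analyte_thresholds <- function(thresholds, analytes) {
  if (is.null(names(thresholds)) && length(thresholds) == 1) {
    thr <- rep(as.numeric(thresholds), length(analytes))
    names(thr) <- analytes
    return(thr)
  }
  thr <- as.numeric(thresholds)
  names(thr) <- names(thresholds)
  missing_thr <- setdiff(analytes, names(thr))
  if (length(missing_thr) > 0) {
    stop("no detection threshold for analyte(s): ",
         paste(missing_thr, collapse = ", "), call. = FALSE)
  }
  thr[analytes]
}

#' Read basal profiles from a delimited file
#'
#' @inheritParams read_response_table
#' @param thresholds Optional per-analyte detection thresholds passed to
#'   [basal_profiles()] for invariant checking.
#' @return A validated basal-profile tibble.
#' @export
read_basal_table <- function(path, dialect = list(), thresholds = NULL) {
  df <- read_dialect_table(path, dialect, BASAL_COLUMNS)
  df$value <- as.numeric(df$value)
  df$below_detection <- as.logical(df$below_detection)
  basal_profiles(df, thresholds = thresholds)
}

#' Write basal profiles to a delimited file
#' @param profiles Basal-profile tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return The path, invisibly.
#' @export
write_basal_table <- function(profiles, path, delim = ",") {
  readr::write_delim(profiles, path, delim = delim)
  invisible(path)
}

#' Read a ligand-receptor binding map
#'
#' A two-column edge list (`ligand`, `receptor`); every ligand must have at
#' least one receptor.
#'
#' @inheritParams read_response_table
#' @return Tibble with columns `ligand`, `receptor`.
#' @export
read_ligand_receptor_map <- function(path, dialect = list()) {
  df <- read_dialect_table(path, dialect, c("ligand", "receptor"))
  validate_ligand_receptor_map(df)
}

validate_ligand_receptor_map <- function(df) {
  df <- tibble::as_tibble(df)[c("ligand", "receptor")]
  if (any(is.na(df$ligand) | is.na(df$receptor) | df$receptor == "")) {
    stop("every ligand must map to at least one named receptor", call. = FALSE)
  }
  df
}

#' Read a cell-line subtype table
#'
#' @inheritParams read_response_table
#' @return Tibble with columns `cell_line`, `subtype`.
#' @export
read_subtype_table <- function(path, dialect = list()) {
  df <- read_dialect_table(path, dialect, c("cell_line", "subtype"))
  validate_subtype_table(df)
}

validate_subtype_table <- function(df) {
  df <- tibble::as_tibble(df)[c("cell_line", "subtype")]
  if (anyDuplicated(df$cell_line)) {
    stop("each cell line may appear only once in the subtype table",
         call. = FALSE)
  }
  if (!all(df$subtype %in% c("TNBC", "HER2amp", "HRpos"))) {
    stop("subtype must be one of TNBC, HER2amp, HRpos", call. = FALSE)
  }
  df
}

SUMMARY_COLUMNS <- c("cell_line", "ligand", "target", "fc_low", "fc_high",
                     "sig_low", "sig_high", "kinetic_low", "kinetic_high",
                     "sensitivity")

#' Write the per-condition response summary table
#'
#' One row per (cell line, ligand, target) with maximal log10 fold-changes and
#' kinetic classes at both doses plus the dose-sensitivity class: the tabular
#' twin of the usual per-panel summary heat map.
#'
#' @param summary Tibble as produced by [build_response_summary()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return The path, invisibly.
#' @export
write_summary_table <- function(summary, path, delim = ",") {
  missing_cols <- setdiff(SUMMARY_COLUMNS, names(summary))
  if (length(missing_cols) > 0) {
    stop("summary is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_delim(summary[SUMMARY_COLUMNS], path, delim = delim)
  invisible(path)
}

#' Read a response summary table written by [write_summary_table()]
#' @inheritParams read_response_table
#' @return Summary tibble.
#' @export
read_summary_table <- function(path, dialect = list()) {
  df <- read_dialect_table(path, dialect, SUMMARY_COLUMNS)
  df$fc_low <- as.numeric(df$fc_low)
  df$fc_high <- as.numeric(df$fc_high)
  df$sig_low <- as.logical(df$sig_low)
  df$sig_high <- as.logical(df$sig_high)
  df
}

#' Read a run configuration file
#'
#' YAML key/value file naming input paths, column mappings, detection
#' thresholds and rule parameters; unknown keys are kept verbatim.
#'
#' @param path Path to a YAML file.
#' @return A named list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), user %||% list())
}

#' Default pipeline configuration
#'
#' Houses the analysis constants: the 2-SD significance rule, k = 4 kinetic
#' clusters, the 75% dose-sensitivity threshold, and the pathway scale-factor
#' policy (fitted by default; a fixed override such as 2.386 may be supplied).
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    sd_multiplier = 2,
    kinetics = list(k = 4, seed = 1L, restarts = 10),
    sensitivity = list(ratio_threshold = 0.75, baseline = "fold_minus_one"),
    scale_fit = list(grid = NULL, significant_only = TRUE, fixed_alpha = NULL,
                     dose = 100),
    correlation = list(method = "pearson", adjust = "none"),
    detection_threshold = 2.0
  )
}
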