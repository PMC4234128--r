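# Per-condition response quantities: replicate averaging in the log10 domain,
# the control model behind the two-standard-deviation significance rule, and
# maximal fold-change summaries.

#' Average replicate measurements in the log10 domain
#'
#' Measurements are carried as log10 signals, so the arithmetic mean here is
#' the geometric mean of the linear signals.
#'
#' @param values Numeric vector of log10 measurements (>= 1 finite value).
#' @return The mean log10 level.
#' @export
average_replicates_log <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    stop("no finite replicate values to average", call. = FALSE)
  }
  mean(values)
}

#' Fit the control model from time-0 measurements
#'
#' Pools all unstimulated (time-0) control replicates per (cell line, target)
#' and returns their mean and sample standard deviation in log10 units. These
#' statistics define the significance threshold: a response must reach the
#' control mean plus `sd_multiplier` standard deviations.
#'
#' @param cube A [response_cube()].
#' @return Tibble with columns `cell_line`, `target`, `control_mean`,
#'   `control_sd`, `n_controls`.
#' @export
fit_control_model <- function(cube) {
  ctrl <- dplyr::filter(cube, .data$time == 0)
  if (nrow(ctrl) == 0) stop("cube contains no time-0 controls", call. = FALSE)
  model <- ctrl |>
    dplyr::group_by(.data$cell_line, .data$target) |>
    dplyr::summarise(control_mean = mean(.data$value),
                     control_sd = sd(.data$value),
                     n_controls = dplyr::n(), .groups = "drop")
  few <- model$n_controls < 2
  if (any(few)) {
    stop("fewer than 2 control replicates for: ",
         paste(paste(model$cell_line[few], model$target[few]), collapse = "; "),
         call. = FALSE)
  }
  model
}

#' Call significance of a response against the control model
#'
#' A response is significant when its maximal replicate-averaged log10 level
#' reaches the control mean plus `sd_multiplier` control standard deviations
#' (the boundary itself counts as significant) and strictly exceeds the
#' control mean. The second clause only matters in the degenerate case
#' `control_sd = 0`, where it keeps exactly-flat responses non-significant.
#' With `2 * control_sd = log10(1.2)` the rule reproduces the ~1.2-fold
#' minimal significant change.
#'
#' @param max_level Maximal replicate-averaged log10 level across time points.
#' @param control_mean,control_sd Control statistics (log10 units).
#' @param sd_multiplier Number of standard deviations (default 2).
#' @return Logical.
#' @export
call_significance <- function(max_level, control_mean, control_sd,
                              sd_multiplier = 2) {
  stopifnot(sd_multiplier > 0, all(control_sd >= 0))
  (max_level >= control_mean + sd_multiplier * control_sd) &
    (max_level > control_mean)
}

#' Compute per-condition fold-changes and significance calls
#'
#' For every (cell line, ligand, dose, target): replicates are averaged in the
#' log10 domain per time point, fold-changes are taken relative to the cell
#' line's time-0 control mean, the maximum across post-stimulation time points
#' is recorded, and significance is called with the 2-SD rule.
#'
#' @param cube A [response_cube()].
#' @param model Control model from [fit_control_model()]; fitted from `cube`
#'   when omitted.
#' @param sd_multiplier Significance rule multiplier.
#' @return Tibble with one row per condition: `cell_line`, `ligand`, `dose`,
#'   `target`, `fc_10`, `fc_30`, `fc_90` (log10 fold-changes), `max_level`,
#'   `max_fc` (log10), `significant`.
#' @export
compute_fold_changes <- function(cube, model = NULL, sd_multiplier = 2) {
  model <- model %||% fit_control_model(cube)
  stim <- dplyr::filter(cube, .data$time > 0)
  resp <- stim |>
    dplyr::group_by(.data$cell_line, .data$ligand, .data$dose, .data$target,
                    .data$time) |>
    dplyr::summarise(level = average_replicates_log(.data$value),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time", values_from = "level",
                       names_prefix = "level_")
  resp <- dplyr::left_join(resp, model, by = c("cell_line", "target"))
  if (any(is.na(resp$control_mean))) {
    bad <- resp[is.na(resp$control_mean), c("cell_line", "target")]
    stop("no control model for: ",
         paste(unique(paste(bad$cell_line, bad$target)), collapse = "; "),
         call. = FALSE)
  }
  lvl <- as.matrix(resp[paste0("level_", POST_TIMES)])
  fc <- lvl - resp$control_mean
  colnames(fc) <- paste0("fc_", POST_TIMES)
  resp$max_level <- apply(lvl, 1, max)
  resp$max_fc <- apply(fc, 1, max)
  resp$significant <- call_significance(resp$max_level, resp$control_mean,
                                        resp$control_sd, sd_multiplier)
  dplyr::bind_cols(
    resp[c("cell_line", "ligand", "dose", "target")],
    tibble::as_tibble(fc),
    resp[c("max_level", "max_fc", "significant", "control_mean",
           "control_sd")]
  )
}

#' Overall maximal induction per (cell line, ligand, target)
#'
#' The maximum log10 fold-change across all time points and both doses, with a
#' response counted significant if either dose is; this is the per-edge
#' quantity of the signaling graphs.
#'
#' @param responses Output of [compute_fold_changes()].
#' @return Tibble with `cell_line`, `ligand`, `target`, `max_fc`,
#'   `significant`.
#' @export
overall_max_induction <- function(responses) {
  responses |>
    dplyr::group_by(.data$cell_line, .data$ligand, .data$target) |>
    dplyr::summarise(max_fc = max(.data$max_fc),
                     significant = any(.data$significant), .groups = "drop")
}
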