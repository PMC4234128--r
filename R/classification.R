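# The two classifiers: k-means kinetic classes over (10, 30, 90)-minute
# fold-change trajectories, and the 75%-rule dose-sensitivity classes.

#' Cluster response trajectories with k-means
#'
#' Standard squared-Euclidean k-means on the log10 fold-change trajectories at
#' 10, 30 and 90 minutes, pooled across cell lines, ligands, targets and
#' doses; no per-trajectory rescaling, so amplitude separates non-responses
#' from real responses. Best of `restarts` random initializations by
#' within-cluster sum of squares; deterministic given `seed`.
#'
#' @param trajectories Numeric matrix (n x 3) or data frame of trajectories.
#' @param k Number of clusters (default 4).
#' @param seed Integer seed.
#' @param restarts Number of random restarts.
#' @return List with `centroids` (k x 3 matrix), `cluster` (integer vector),
#'   `tot_withinss`.
#' @export
cluster_kinetics <- function(trajectories, k = 4, seed = 1L, restarts = 10) {
  x <- as.matrix(trajectories)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("trajectories must be finite", call. = FALSE)
  if (nrow(x) < k) {
    stop("need at least k = ", k, " trajectories, got ", nrow(x),
         call. = FALSE)
  }
  fit <- with_seed(seed, {
    # kmeans() errors when duplicate points make a start degenerate; Lloyd
    # with many restarts is robust to the flat-trajectory ties common here
    suppressWarnings(
      kmeans(x, centers = k, nstart = restarts, iter.max = 300,
             algorithm = "Lloyd")
    )
  })
  list(centroids = unname(fit$centers), cluster = unname(fit$cluster),
       tot_withinss = fit$tot.withinss)
}

#' Label k-means centroids with kinetic classes
#'
#' The centroid with the smallest amplitude (peak value) becomes `none`.
#' Among the rest, a centroid peaking at 10 or 30 minutes whose final/peak
#' ratio is below 0.5 is `transient`; one peaking at 90 minutes whose
#' initial/peak ratio is below 0.5 is `late`; anything else is `sustained`.
#' Ties for smallest amplitude go to the flatter (smaller-range) centroid.
#'
#' @param centroids k x 3 matrix of centroids (k = 4 expected).
#' @return Character vector of labels, one per centroid row.
#' @export
label_clusters <- function(centroids) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  amp <- apply(centroids, 1, max)
  rng <- apply(centroids, 1, function(z) diff(range(z)))
  none_idx <- which(amp == min(amp))
  if (length(none_idx) > 1) none_idx <- none_idx[which.min(rng[none_idx])]
  labels <- character(k)
  labels[none_idx] <- "none"
  for (i in setdiff(seq_len(k), none_idx)) {
    z <- centroids[i, ]
    peak_at <- which.max(z)
    peak <- z[peak_at]
    if (peak_at <= 2 && peak > 0 && z[3] / peak < 0.5) {
      labels[i] <- "transient"
    } else if (peak_at == 3 && peak > 0 && z[1] / peak < 0.5) {
      labels[i] <- "late"
    } else {
      labels[i] <- "sustained"
    }
  }
  labels
}

#' Assign kinetic classes to per-condition responses
#'
#' Pools all trajectories, clusters them with [cluster_kinetics()], labels the
#' centroids with [label_clusters()], and overrides the label of any
#' non-significant response with `none` regardless of cluster geometry.
#'
#' @param responses Output of [compute_fold_changes()].
#' @param k,seed,restarts Passed to [cluster_kinetics()].
#' @return `responses` with added columns `cluster` and `kinetic`; the
#'   centroid matrix and labels are attached as attributes `centroids` and
#'   `centroid_labels`.
#' @export
assign_kinetics <- function(responses, k = 4, seed = 1L, restarts = 10) {
  traj <- as.matrix(responses[paste0("fc_", POST_TIMES)])
  fit <- cluster_kinetics(traj, k = k, seed = seed, restarts = restarts)
  labels <- label_clusters(fit$centroids)
  responses$cluster <- fit$cluster
  responses$kinetic <- ifelse(responses$significant, labels[fit$cluster],
                              "none")
  attr(responses, "centroids") <- fit$centroids
  attr(responses, "centroid_labels") <- labels
  responses
}

#' Classify dose sensitivity of a response
#'
#' Four-way classification of how a response depends on dose: `none` when
#' neither dose is significant; `high_only` when only the high dose is; among
#' responses significant at the low dose, `equal` when the low-dose response
#' is at least `ratio_threshold` (default 75%) of the high-dose response and
#' `high_greater` otherwise. With `baseline = "fold_minus_one"` (default) the
#' ratio compares linear fold-changes above baseline,
#' `(10^fc_low - 1) / (10^fc_high - 1)`; with `baseline = "fold"` it compares
#' raw linear fold-changes.
#'
#' @param fc_low,fc_high Maximal log10 fold-changes at 1 and 100 ng/ml.
#' @param sig_low,sig_high Significance calls at the two doses.
#' @param ratio_threshold Equality threshold in (0, 1].
#' @param baseline Ratio convention, `"fold_minus_one"` or `"fold"`.
#' @return Character vector of class labels.
#' @export
classify_sensitivity <- function(fc_low, fc_high, sig_low, sig_high,
                                 ratio_threshold = 0.75,
                                 baseline = c("fold_minus_one", "fold")) {
  baseline <- match.arg(baseline)
  stopifnot(ratio_threshold > 0, ratio_threshold <= 1)
  if (any(!is.finite(fc_low)) || any(!is.finite(fc_high))) {
    stop("fold-changes must be finite", call. = FALSE)
  }
  n <- max(length(fc_low), length(fc_high), length(sig_low), length(sig_high))
  fc_low <- rep_len(fc_low, n); fc_high <- rep_len(fc_high, n)
  sig_low <- rep_len(sig_low, n); sig_high <- rep_len(sig_high, n)
  num <- if (baseline == "fold_minus_one") 10^fc_low - 1 else 10^fc_low
  den <- if (baseline == "fold_minus_one") 10^fc_high - 1 else 10^fc_high
  ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  out <- rep("none", n)
  out[!sig_low & sig_high] <- "high_only"
  low_sig <- sig_low
  out[low_sig] <- ifelse(!is.nan(ratio[low_sig]) &
                           ratio[low_sig] >= ratio_threshold,
                         "equal", "high_greater")
  out
}

#' Assign sensitivity classes per (cell line, ligand, target)
#'
#' @param responses Output of [compute_fold_changes()] covering both doses.
#' @inheritParams classify_sensitivity
#' @return Tibble with `cell_line`, `ligand`, `target`, `fc_low`, `fc_high`,
#'   `sig_low`, `sig_high`, `sensitivity`.
#' @export
assign_sensitivity <- function(responses, ratio_threshold = 0.75,
                               baseline = "fold_minus_one") {
  wide <- responses |>
    dplyr::select("cell_line", "ligand", "dose", "target", "max_fc",
                  "significant") |>
    tidyr::pivot_wider(names_from = "dose",
                       values_from = c("max_fc", "significant"))
  need <- c("max_fc_1", "max_fc_100", "significant_1", "significant_100")
  if (!all(need %in% names(wide))) {
    stop("responses must cover both doses (1 and 100 ng/ml)", call. = FALSE)
  }
  tibble::tibble(
    cell_line = wide$cell_line, ligand = wide$ligand, target = wide$target,
    fc_low = wide$max_fc_1, fc_high = wide$max_fc_100,
    sig_low = wide$significant_1, sig_high = wide$significant_100,
    sensitivity = classify_sensitivity(wide$max_fc_1, wide$max_fc_100,
                                       wide$significant_1, wide$significant_100,
                                       ratio_threshold = ratio_threshold,
                                       baseline = baseline)
  )
}

#' Build the per-panel response summary table
#'
#' One row per (cell line, ligand, target) with the maximal fold-changes,
#' significance calls and kinetic classes at both doses and the sensitivity
#' class: the tabular twin of the summary reference figure.
#'
#' @param responses Output of [assign_kinetics()] (both doses present).
#' @inheritParams classify_sensitivity
#' @return Summary tibble with the columns of [write_summary_table()].
#' @export
build_response_summary <- function(responses, ratio_threshold = 0.75,
                                   baseline = "fold_minus_one") {
  if (!"kinetic" %in% names(responses)) {
    stop("responses must carry kinetic labels; run assign_kinetics() first",
         call. = FALSE)
  }
  sens <- assign_sensitivity(responses, ratio_threshold = ratio_threshold,
                             baseline = baseline)
  kin <- responses |>
    dplyr::select("cell_line", "ligand", "dose", "target", "kinetic") |>
    tidyr::pivot_wider(names_from = "dose", values_from = "kinetic",
                       names_prefix = "kinetic_")
  out <- dplyr::left_join(sens, kin, by = c("cell_line", "ligand", "target"))
  dplyr::rename(out, kinetic_low = "kinetic_1", kinetic_high = "kinetic_100")[
    SUMMARY_COLUMNS]
}
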