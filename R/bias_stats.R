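# Pathway-bias machinery (two-sample Cramer-von Mises scale fitting and the
# arctangent bias angle) plus the correlation / rank-sum statistical panels.

#' Two-sample Cramer-von Mises distance
#'
#' Rank-based discrepancy between two empirical distribution functions:
#' `T = n m / (n + m)^2 * sum_z (F_a(z) - F_b(z))^2`, the sum running over
#' every observation of the pooled sample. Zero iff the two empirical
#' distributions coincide; invariant under any common strictly increasing
#' transform of both samples.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return Nonnegative statistic.
#' @export
cvm_distance <- function(sample_a, sample_b) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(a, b)
  fa <- stats::ecdf(a)(pooled)
  fb <- stats::ecdf(b)(pooled)
  n * m / (n + m)^2 * sum((fa - fb)^2)
}

#' Fit the pAKT/pERK pathway scale factor
#'
#' Finds the multiplicative factor `alpha` minimizing the Cramer-von Mises
#' distance between the distribution of `alpha * pakt_fcs` and `perk_fcs`
#' (linear fold-changes). Because the statistic is piecewise constant in
#' `alpha`, the search is a coarse log-spaced grid followed by one linear
#' refinement pass around the coarse minimum; among tied minima the middle
#' grid point is returned, centering the answer in the zero-distance window.
#'
#' @param pakt_fcs,perk_fcs Nonempty vectors of linear fold-changes.
#' @param grid Positive candidate scale factors; default 121 log-spaced points
#'   on `[0.1, 10]`.
#' @param refine Run the refinement pass (default `TRUE`).
#' @return The fitted scale factor. Warns when the optimum sits on the grid
#'   boundary.
#' @export
fit_pathway_scale <- function(pakt_fcs, perk_fcs,
                              grid = 10^seq(-1, 1, length.out = 121),
                              refine = TRUE) {
  if (length(grid) == 0) stop("scale grid must be nonempty", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid <= 0)) {
    stop("scale grid must be positive and finite", call. = FALSE)
  }
  grid <- sort(grid)
  pick <- function(g) {
    d <- vapply(g, function(a) cvm_distance(a * pakt_fcs, perk_fcs),
                numeric(1))
    ties <- which(d == min(d))
    ties[ceiling(length(ties) / 2)]
  }
  i <- pick(grid)
  if (i == 1L || i == length(grid)) {
    warning("fitted scale factor lies on the grid boundary (",
            signif(grid[i], 4), "); consider widening the grid")
    return(grid[i])
  }
  if (!refine) return(grid[i])
  fine <- seq(grid[i - 1], grid[i + 1], length.out = 121)
  fine[pick(fine)]
}

#' Pathway-bias angle
#'
#' `atan2(alpha * pakt_fc, perk_fc)` in degrees: 45 means balanced ERK/AKT
#' activation, below 45 is ERK-biased, above 45 AKT-biased. Undefined (NA)
#' when both fold-changes are zero.
#'
#' @param perk_fc,pakt_fc Nonnegative linear fold-changes (vectorized).
#' @param alpha Scale factor applied to pAKT.
#' @return Angle(s) in degrees in `[0, 90]`.
#' @export
pathway_bias <- function(perk_fc, pakt_fc, alpha = 1) {
  stopifnot(alpha > 0)
  if (any(perk_fc < 0, na.rm = TRUE) || any(pakt_fc < 0, na.rm = TRUE)) {
    stop("fold-changes must be nonnegative", call. = FALSE)
  }
  ang <- atan2(alpha * pakt_fc, perk_fc) * 180 / pi
  ang[perk_fc == 0 & pakt_fc == 0] <- NA_real_
  ang
}

#' Per-(cell line, ligand) pathway-bias records
#'
#' Extracts linear maximal fold-changes of both targets at the high dose,
#' fits (or takes) the scale factor, and computes the bias angle.
#'
#' @param responses Output of [compute_fold_changes()].
#' @param alpha Fixed scale factor; fitted with [fit_pathway_scale()] when
#'   `NULL`.
#' @param dose Dose at which responses are compared (default 100 ng/ml).
#' @param significant_only Restrict the scale fit to (cell, ligand) pairs
#'   significant for both targets (default `TRUE`).
#' @param grid Scale grid for the fit.
#' @return Tibble with `cell_line`, `ligand`, `perk_fc`, `pakt_fc` (linear),
#'   `sig_perk`, `sig_pakt`, `alpha`, `bias_angle`.
#' @export
pathway_bias_table <- function(responses, alpha = NULL, dose = 100,
                               significant_only = TRUE,
                               grid = 10^seq(-1, 1, length.out = 121)) {
  wide <- responses |>
    dplyr::filter(.data$dose == !!dose) |>
    dplyr::select("cell_line", "ligand", "target", "max_fc", "significant") |>
    tidyr::pivot_wider(names_from = "target",
                       values_from = c("max_fc", "significant"))
  perk <- 10^wide$max_fc_pERK
  pakt <- 10^wide$max_fc_pAKT
  if (is.null(alpha)) {
    keep <- if (significant_only) {
      wide$significant_pERK & wide$significant_pAKT
    } else {
      rep(TRUE, nrow(wide))
    }
    if (sum(keep) == 0) {
      stop("no responses available to fit the scale factor", call. = FALSE)
    }
    alpha <- fit_pathway_scale(pakt[keep], perk[keep], grid = grid)
  }
  tibble::tibble(
    cell_line = wide$cell_line, ligand = wide$ligand,
    perk_fc = perk, pakt_fc = pakt,
    sig_perk = wide$significant_pERK, sig_pakt = wide$significant_pAKT,
    alpha = alpha,
    bias_angle = pathway_bias(perk, pakt, alpha)
  )
}

#' Correlate responses with basal profiles
#'
#' For each basal predictor (analyte, kind), correlates a response statistic
#' across cell lines with the predictor's basal level. The response statistic
#' is either the maximal log10 fold-change (`value = "fold_change"`) or the
#' maximal replicate-averaged post-stimulation log10 level
#' (`value = "absolute"`).
#'
#' @param responses Output of [compute_fold_changes()], pre-filtered to one
#'   (ligand, dose, target) of interest (or any slice with one row per cell
#'   line).
#' @param basal Basal-profile tibble.
#' @param method `"pearson"` or `"spearman"`.
#' @param value Response statistic, `"fold_change"` or `"absolute"`.
#' @param predictors Optional tibble with columns `analyte`, `kind` selecting
#'   panel entries; all basal (analyte, kind) pairs when `NULL`.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, matching unadjusted p < 0.05 reporting).
#' @return Tibble with `analyte`, `kind`, `coefficient`, `p_value`, `n`,
#'   `significant`, `degenerate`.
#' @export
correlate_panel <- function(responses, basal,
                            method = c("pearson", "spearman"),
                            value = c("fold_change", "absolute"),
                            predictors = NULL, adjust = "none") {
  method <- match.arg(method)
  value <- match.arg(value)
  if (anyDuplicated(responses$cell_line)) {
    stop("responses must contain one row per cell line; ",
         "filter to a single (ligand, dose, target) first", call. = FALSE)
  }
  y <- if (value == "fold_change") responses$max_fc else responses$max_level
  names(y) <- responses$cell_line
  if (is.null(predictors)) {
    predictors <- dplyr::distinct(basal, .data$analyte, .data$kind)
  }
  rows <- purrr::pmap(predictors[c("analyte", "kind")], function(analyte, kind) {
    pred <- basal[basal$analyte == analyte & basal$kind == kind, ]
    shared <- intersect(names(y), pred$cell_line)
    x <- pred$value[match(shared, pred$cell_line)]
    yy <- y[shared]
    n <- length(shared)
    if (n < 3) {
      stop("fewer than 3 paired observations for predictor ", analyte,
           call. = FALSE)
    }
    if (sd(x) == 0 || sd(yy) == 0) {
      return(tibble::tibble(analyte = analyte, kind = kind,
                            coefficient = NA_real_, p_value = NA_real_,
                            n = n, degenerate = TRUE))
    }
    ct <- suppressWarnings(cor.test(x, yy, method = method, exact = FALSE))
    tibble::tibble(analyte = analyte, kind = kind,
                   coefficient = unname(ct$estimate), p_value = ct$p.value,
                   n = n, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}

#' Compare a per-cell-line statistic between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test; exact enumeration for
#' small tie-free groups (both sizes <= 8), normal approximation with tie
#' correction otherwise.
#'
#' @param values Named or plain numeric vector of per-cell-line statistics.
#' @param labels Group label per value.
#' @param groups Length-2 character vector choosing the two labels to
#'   compare; defaults to the two unique labels present.
#' @return List with `p_value`, `group_a`, `group_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values, labels, groups = NULL) {
  stopifnot(length(values) == length(labels))
  groups <- groups %||% unique(labels)
  if (length(groups) != 2) {
    stop("exactly two groups are required", call. = FALSE)
  }
  x <- values[labels == groups[1]]
  y <- values[labels == groups[2]]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact)$p.value
  )
  list(p_value = p, group_a = groups[1], group_b = groups[2],
       n_a = length(x), n_b = length(y))
}

#' Responder-vs-nonresponder enrichment of a basal level
#'
#' Splits cell lines by a significance call and asks whether basal levels
#' differ between responders and non-responders (two-sided Wilcoxon rank-sum),
#' reporting median and interquartile summaries per group. Undefined and
#' flagged when one group is empty; flagged low-power when a group has a
#' single member.
#'
#' @param sig_calls Logical vector: does the cell line respond?
#' @param levels Numeric vector of basal levels, aligned with `sig_calls`.
#' @return List with `p_value`, `summary` (tibble: group, n, median, q25,
#'   q75), `defined`, `low_power`.
#' @export
responder_enrichment <- function(sig_calls, levels) {
  stopifnot(length(sig_calls) == length(levels))
  resp <- levels[sig_calls]
  nonresp <- levels[!sig_calls]
  smry <- tibble::tibble(
    group = c("responder", "nonresponder"),
    n = c(length(resp), length(nonresp)),
    median = c(median_or_na(resp), median_or_na(nonresp)),
    q25 = c(quantile_or_na(resp, 0.25), quantile_or_na(nonresp, 0.25)),
    q75 = c(quantile_or_na(resp, 0.75), quantile_or_na(nonresp, 0.75))
  )
  if (length(resp) == 0 || length(nonresp) == 0) {
    return(list(p_value = NA_real_, summary = smry, defined = FALSE,
                low_power = TRUE))
  }
  exact <- length(resp) <= 8 && length(nonresp) <= 8 &&
    !any(duplicated(c(resp, nonresp)))
  p <- suppressWarnings(
    wilcox.test(resp, nonresp, alternative = "two.sided", exact = exact)$p.value
  )
  list(p_value = p, summary = smry, defined = TRUE,
       low_power = min(length(resp), length(nonresp)) < 2)
}

median_or_na <- function(x) if (length(x) == 0) NA_real_ else stats::median(x)
quantile_or_na <- function(x, p) {
  if (length(x) == 0) NA_real_ else unname(quantile(x, p, type = 7))
}
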