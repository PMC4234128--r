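template_points <- function(n_per_class, p = 1, noise = 0, seed = 1) {
  shapes <- list(sustained = c(p, p, p),
                 transient = c(p, p / 2, p / 10),
                 late = c(p / 10, p / 2, p),
                 none = c(0, 0, 0))
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(shapes, function(s) {
      matrix(rep(s, each = n_per_class), ncol = 3) +
        rnorm(3 * n_per_class, 0, noise)
    }))
    list(x = x, class = rep(names(shapes), each = n_per_class))
  })
}

test_that("k-means recovers well-separated template clusters exactly", {
  tp <- template_points(20, p = 1, noise = 0)
  fit <- cluster_kinetics(tp$x, k = 4, seed = 3)
  # clusters must be pure: one planted class per cluster index
  tab <- table(fit$cluster, tp$class)
  expect_true(all(rowSums(tab > 0) == 1))
  labels <- label_clusters(fit$centroids)
  expect_setequal(labels, c("sustained", "transient", "late", "none"))
  expect_equal(unname(labels[fit$cluster]), tp$class)
})

test_that("clustering is deterministic given the seed", {
  tp <- template_points(10, noise = 0.1)
  a <- cluster_kinetics(tp$x, seed = 7)
  b <- cluster_kinetics(tp$x, seed = 7)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$centroids, b$centroids)
})

test_that("k-means with restarts attains the brute-force optimum on tiny inputs", {
  # enumerate every assignment of 7 points to 2 clusters
  withr::with_seed(11, {
    x <- matrix(rnorm(21), ncol = 3)
  })
  wss_of <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      pts <- x[assign == g, , drop = FALSE]
      ctr <- colMeans(pts)
      sum(sweep(pts, 2, ctr)^2)
    }, numeric(1)))
  }
  best <- Inf
  for (code in 0:(2^7 - 1)) {
    assign <- as.integer(intToBits(code))[1:7]
    if (length(unique(assign)) < 2) next
    best <- min(best, wss_of(assign))
  }
  fit <- cluster_kinetics(x, k = 2, seed = 5, restarts = 50)
  expect_equal(fit$tot_withinss, best, tolerance = 1e-8)
})

test_that("cluster labeling follows the template geometry", {
  cents <- rbind(c(1, 1, 1), c(1, 0.5, 0.1), c(0.1, 0.5, 1), c(0, 0, 0))
  expect_equal(label_clusters(cents),
               c("sustained", "transient", "late", "none"))
  # labeling is invariant to permutation of cluster indices
  perm <- c(3, 1, 4, 2)
  expect_equal(label_clusters(cents[perm, ]),
               c("sustained", "transient", "late", "none")[perm])
  # smallest-amplitude centroid becomes none even when not exactly flat
  cents2 <- rbind(c(1, 1, 1), c(1.2, 0.6, 0.1), c(0.1, 0.6, 1.2),
                  c(0.05, 0.02, 0.04))
  expect_equal(label_clusters(cents2)[4], "none")
  # amplitude tie: the flatter centroid becomes none; a slow riser whose
  # initial/peak ratio stays >= 0.5 falls back to sustained
  cents3 <- rbind(c(0.5, 0.5, 0.5), c(0.3, 0.4, 0.5), c(2, 2, 2),
                  c(2, 1, 0.2))
  labs3 <- label_clusters(cents3)
  expect_equal(labs3[1], "none")
  expect_equal(labs3[2], "sustained")
})

test_that("non-significant trajectories are labeled none regardless of cluster", {
  tp <- template_points(10, p = 1, noise = 0)
  responses <- tibble::tibble(
    cell_line = "CL1", ligand = paste0("L", seq_len(nrow(tp$x))),
    dose = 100, target = "pERK",
    fc_10 = tp$x[, 1], fc_30 = tp$x[, 2], fc_90 = tp$x[, 3],
    max_level = 2 + apply(tp$x, 1, max), max_fc = apply(tp$x, 1, max),
    significant = FALSE
  )
  out <- assign_kinetics(responses, seed = 2)
  expect_true(all(out$kinetic == "none"))
})

test_that("sensitivity classification matches the hand-written truth table", {
  # rows: sig_low, sig_high, linear (fold-1) ratio, expected label
  cases <- list(
    list(FALSE, FALSE, 0.9, "none"),
    list(FALSE, TRUE, 0.9, "high_only"),
    list(TRUE, TRUE, 0.80, "equal"),
    list(TRUE, TRUE, 0.75, "equal"),        # boundary is inclusive
    list(TRUE, TRUE, 0.7499, "high_greater"),
    list(TRUE, TRUE, 0.50, "high_greater"),
    list(TRUE, FALSE, 1.20, "equal")        # low-dose-only responder
  )
  fc_high <- log10(5)
  for (cs in cases) {
    ratio <- cs[[3]]
    fc_low <- log10(1 + ratio * (10^fc_high - 1))
    expect_equal(
      classify_sensitivity(fc_low, fc_high, cs[[1]], cs[[2]]),
      cs[[4]], info = sprintf("ratio=%g sig=(%d,%d)", ratio, cs[[1]], cs[[2]]))
  }
})

test_that("sensitivity classification is total and partitions its inputs", {
  grid <- expand.grid(sig_low = c(TRUE, FALSE), sig_high = c(TRUE, FALSE),
                      ratio = c(0, 0.1, 0.5, 0.74999, 0.75, 0.75001, 1, 2))
  fc_high <- log10(4)
  labels <- mapply(function(sl, sh, r) {
    classify_sensitivity(log10(1 + r * 3), fc_high, sl, sh)
  }, grid$sig_low, grid$sig_high, grid$ratio)
  expect_true(all(labels %in% c("equal", "high_greater", "high_only", "none")))
  expect_length(labels, nrow(grid))
  # the fold (not fold-minus-one) convention shifts the boundary
  expect_equal(
    classify_sensitivity(log10(3), log10(4), TRUE, TRUE, baseline = "fold"),
    "equal")
})

test_that("zero-noise kinetic labels equal the planted classes", {
  pan <- generate_panel(8, 4, seed = 17, config = panel_config(sigma = 0))
  res <- assign_kinetics(compute_fold_changes(pan$cube), seed = 4)
  truth <- pan$truth
  m <- match(truth_key(res), truth_key(truth))
  planted <- ifelse(res$dose == 100, truth$kinetic_high[m],
                    truth$kinetic_low[m])
  expect_equal(res$kinetic, planted)
})
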