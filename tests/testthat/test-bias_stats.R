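test_that("the CvM distance is zero iff the empirical distributions match", {
  expect_equal(cvm_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cvm_distance(c(5, 5, 7), c(7, 5, 5)), 0)   # order-free
  # fully separated samples of size 3 each: hand-computed ECDF sum
  expect_equal(cvm_distance(c(1, 2, 3), c(11, 12, 13)), 19 / 36)
  expect_gt(cvm_distance(c(1, 2, 3), c(2, 3, 4)), 0)
  expect_error(cvm_distance(numeric(0), 1), "nonempty")
})

test_that("the CvM distance is rank-based", {
  withr::with_seed(31, {
    for (i in 1:20) {
      a <- rnorm(8)
      b <- rnorm(11, 0.5)
      expect_equal(cvm_distance(exp(a), exp(b)), cvm_distance(a, b))
      expect_equal(cvm_distance(a * 3 + 2, b * 3 + 2), cvm_distance(a, b))
    }
  })
})

test_that("the CvM distance matches an independent brute-force oracle", {
  withr::with_seed(57, {
    for (i in 1:50) {
      n <- sample(1:12, 1)
      m <- sample(1:12, 1)
      a <- round(rnorm(n), 1)   # rounding induces ties
      b <- round(rnorm(m, 0.3), 1)
      expect_equal(cvm_distance(a, b), cvm_oracle(a, b), tolerance = 1e-12)
    }
  })
})

test_that("scale fitting recovers identity and planted compressions", {
  withr::with_seed(5, {
    perk <- 10^rnorm(300, 1.5, 0.2)
  })
  expect_equal(fit_pathway_scale(perk, perk), 1, tolerance = 0.05)
  a <- fit_pathway_scale(perk / 2.386, perk)
  expect_lt(abs(a - 2.386) / 2.386, 0.1)
  # grid excluding the optimum returns the boundary with a warning
  expect_warning(
    out <- fit_pathway_scale(perk / 2.386, perk, grid = c(0.2, 0.3, 0.5)),
    "boundary")
  expect_equal(out, 0.5)
  expect_error(fit_pathway_scale(perk, perk, grid = numeric(0)), "nonempty")
  expect_error(fit_pathway_scale(perk, perk, grid = c(-1, 1)), "positive")
})

test_that("the bias angle follows its arctangent geometry", {
  expect_equal(pathway_bias(2, 2, alpha = 1), 45)
  expect_equal(pathway_bias(5, 0, alpha = 1), 0)
  expect_equal(pathway_bias(0, 5, alpha = 1), 90)
  expect_equal(pathway_bias(1, sqrt(3), alpha = 1), 60)
  expect_equal(pathway_bias(4, sqrt(3) * 2, alpha = 2), 60, tolerance = 1e-12)
  expect_true(is.na(pathway_bias(0, 0)))
  expect_error(pathway_bias(-1, 1), "nonnegative")
  # scale invariance under a common positive factor
  withr::with_seed(77, {
    perk <- runif(200, 0.01, 50)
    pakt <- runif(200, 0.01, 50)
    k <- runif(200, 0.01, 100)
    expect_equal(pathway_bias(k * perk, k * pakt, alpha = 2.386),
                 pathway_bias(perk, pakt, alpha = 2.386), tolerance = 1e-9)
  })
})

test_that("the bias table fits alpha on doubly-significant pairs", {
  pan <- generate_panel(20, 6, seed = 13, config = panel_config(sigma = 0))
  res <- compute_fold_changes(pan$cube)
  bias <- pathway_bias_table(res)
  alpha_true <- attr(pan$truth, "alpha_true")
  expect_lt(abs(bias$alpha[1] - alpha_true) / alpha_true, 0.1)
  expect_true(all(bias$bias_angle >= 0 & bias$bias_angle <= 90, na.rm = TRUE))
  # fixed alpha short-circuits the fit
  bias2 <- pathway_bias_table(res, alpha = 2.386)
  expect_equal(unique(bias2$alpha), 2.386)
})

test_that("correlation panels report coefficients, p-values and degeneracies", {
  responses <- tibble::tibble(
    cell_line = sprintf("CL%02d", 1:10),
    max_fc = seq(0.1, 1, by = 0.1),
    max_level = seq(2.1, 3, by = 0.1)
  )
  basal <- tibble::tibble(
    cell_line = rep(responses$cell_line, 2),
    analyte = rep(c("EGFR", "FLAT"), each = 10),
    kind = "expression",
    value = c(responses$max_fc, rep(1, 10)),   # EGFR == response, FLAT constant
    below_detection = FALSE
  )
  panel <- correlate_panel(responses, basal)
  egfr <- panel[panel$analyte == "EGFR", ]
  expect_equal(egfr$coefficient, 1, tolerance = 1e-12)
  expect_lt(egfr$p_value, 1e-10)
  expect_true(egfr$significant)
  flat <- panel[panel$analyte == "FLAT", ]
  expect_true(flat$degenerate)
  expect_true(is.na(flat$coefficient))

  expect_error(
    correlate_panel(responses[1:2, ], basal),
    "fewer than 3")
  expect_error(
    correlate_panel(rbind(responses, responses), basal),
    "one row per cell line")
})

test_that("group comparison uses the exact rank-sum distribution when possible", {
  res <- compare_groups(c(1, 2, 3, 10, 11, 12),
                        rep(c("a", "b"), each = 3), c("a", "b"))
  expect_equal(res$p_value, 0.1)   # smallest attainable two-sided p for 3v3
  same <- compare_groups(c(1, 2, 3, 1.1, 2.1, 3.1),
                         rep(c("a", "b"), each = 3), c("a", "b"))
  expect_gt(same$p_value, 0.5)
  expect_error(compare_groups(1:3, c("a", "a", "a"), c("a", "b")),
               "nonempty|two groups")
})

test_that("a planted subtype receptor shift is detected by the rank-sum test", {
  pan <- generate_panel(39, 15, seed = 5)
  e3 <- pan$basal[pan$basal$analyte == "ErbB3" &
                    pan$basal$kind == "expression", ]
  lab <- pan$subtypes$subtype[match(e3$cell_line, pan$subtypes$cell_line)]
  res <- compare_groups(e3$value, ifelse(lab == "HRpos", "HRpos", "other"),
                        c("HRpos", "other"))
  expect_lt(res$p_value, 0.05)
})

test_that("responder enrichment reports rank-sum p and quartile summaries", {
  same <- responder_enrichment(rep(c(TRUE, FALSE), each = 6), rep(1:6, 2))
  expect_gt(same$p_value, 0.9)
  expect_true(same$defined)

  sep <- responder_enrichment(rep(c(TRUE, FALSE), each = 4),
                              c(11, 12, 13, 14, 1, 2, 3, 4))
  expect_equal(sep$p_value, 2 / choose(8, 4))   # minimal two-sided exact p
  expect_equal(sep$summary$median, c(12.5, 2.5))

  solo <- responder_enrichment(c(TRUE, TRUE, TRUE, FALSE), c(5, 6, 7, 1))
  expect_true(solo$defined)
  expect_true(solo$low_power)

  all_resp <- responder_enrichment(rep(TRUE, 4), 1:4)
  expect_false(all_resp$defined)
  expect_true(is.na(all_resp$p_value))
})
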