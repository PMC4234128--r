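# Fixtures built in code: a minimal hand-written cube plus keyed comparison
# helpers shared across the suite.

# A 2-line, 1-ligand cube with duplicate controls and single-replicate
# stimulated rows; values chosen so CL1/EGF/pERK responds and pAKT does not.
tiny_cube_df <- function() {
  ctrl <- expand.grid(cell_line = c("CL1", "CL2"), target = c("pERK", "pAKT"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  ctrl$ligand <- "control"
  ctrl$dose <- NA_real_
  ctrl$time <- 0
  ctrl$value <- 2.0
  stim <- expand.grid(cell_line = c("CL1", "CL2"), target = c("pERK", "pAKT"),
                      dose = c(1, 100), time = c(10, 30, 90),
                      replicate = 1L, stringsAsFactors = FALSE)
  stim$ligand <- "EGF"
  stim$value <- 2.0
  up <- stim$cell_line == "CL1" & stim$target == "pERK"
  stim$value[up] <- 2.0 + 0.5 * (stim$dose[up] / 100)
  cols <- c("cell_line", "ligand", "dose", "time", "target", "replicate",
            "value")
  rbind(ctrl[cols], stim[cols])
}

truth_key <- function(df) paste(df$cell_line, df$ligand, df$target)

# Score a pipeline run against planted ground truth; returns agreement
# fractions for significance, kinetic labels and sensitivity classes.
score_against_truth <- function(summary, truth) {
  m <- match(truth_key(summary), truth_key(truth))
  list(
    significance = mean(summary$sig_high == truth$sig_high[m] &
                          summary$sig_low == truth$sig_low[m]),
    kinetic = mean(summary$kinetic_high == truth$kinetic_high[m] &
                     summary$kinetic_low == truth$kinetic_low[m]),
    sensitivity = mean(summary$sensitivity == truth$sens_class[m])
  )
}

# Graph comparison on the attributes the exporters guarantee to preserve.
graphs_equivalent <- function(a, b, tol = 1e-9) {
  va <- igraph::as_data_frame(a, "vertices")
  vb <- igraph::as_data_frame(b, "vertices")
  ea <- igraph::as_data_frame(a, "edges")
  eb <- igraph::as_data_frame(b, "edges")
  vcols <- c("name", "role", "size01", "shade01", "below_detection",
             "measured")
  ecols <- c("from", "to", "kind", "weight01", "significant", "target")
  ord_v <- order(va$name)
  ord_e <- order(ea$from, ea$to, ea$kind)
  isTRUE(all.equal(va[ord_v, vcols], vb[order(vb$name), vcols],
                   tolerance = tol, check.attributes = FALSE)) &&
    isTRUE(all.equal(ea[ord_e, ecols],
                     eb[order(eb$from, eb$to, eb$kind), ecols],
                     tolerance = tol, check.attributes = FALSE))
}

# Independent brute-force two-sample CvM oracle: evaluate both ECDFs at every
# pooled observation by explicit counting.
cvm_oracle <- function(a, b) {
  pooled <- c(a, b)
  fa <- vapply(pooled, function(z) sum(a <= z) / length(a), numeric(1))
  fb <- vapply(pooled, function(z) sum(b <= z) / length(b), numeric(1))
  length(a) * length(b) / (length(a) + length(b))^2 * sum((fa - fb)^2)
}

# Independent interquartile-mean oracle under the linear-interpolation
# (type 7) percentile convention, written out by hand.
iqm_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  q_at <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  q1 <- q_at(0.25)
  q3 <- q_at(0.75)
  inside <- x[x >= q1 & x <= q3]
  if (length(inside) == 0) mean(x) else mean(inside)
}
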