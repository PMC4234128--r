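# Synthetic panel generator with planted ground truth.
#
# Emulates the structure of a growth-factor response screen: a panel of cell
# lines stimulated with ligands at 1 and 100 ng/ml, pERK/pAKT read out at 10,
# 30 and 90 minutes in duplicate, plus basal RTK expression/phosphorylation
# profiles, a subtype table and a ligand-receptor binding map. Every planted
# quantity (kinetic class, sensitivity class, amplitudes, receptor effects,
# pathway scale factor) is returned so downstream stages can be scored.

# Canonical ligand -> receptor wiring used when ligand names are not supplied;
# mirrors the usual growth-factor families of breast-cancer panels. The first
# receptor listed is treated as the cognate (primary) receptor.
DEFAULT_LIGAND_RECEPTORS <- list(
  "EGF"      = c("EGFR"),
  "BTC"      = c("EGFR", "ErbB4"),
  "EPR"      = c("EGFR", "ErbB4"),
  "HRG"      = c("ErbB3", "ErbB4"),
  "IGF-1"    = c("IGF1R"),
  "IGF-2"    = c("IGF1R", "InsR"),
  "INS"      = c("InsR"),
  "FGF-1"    = c("FGFR1", "FGFR2", "FGFR3", "FGFR4"),
  "FGF-2"    = c("FGFR1", "FGFR2", "FGFR3", "FGFR4"),
  "HGF"      = c("cMet"),
  "SCF"      = c("cKit"),
  "PDGF-BB"  = c("PDGFRb"),
  "VEGF165"  = c("VEGFR2"),
  "EFNA1"    = c("EphA2"),
  "NGF-beta" = c("TrkA")
)

#' Default ligand-receptor binding map
#'
#' @param n_ligands Number of ligands (first `n_ligands` of the canonical
#'   15-ligand set; extra generic ligands are appended beyond 15).
#' @return Tibble edge list with columns `ligand`, `receptor`.
#' @export
default_ligand_receptor_map <- function(n_ligands = 15) {
  stopifnot(n_ligands >= 1)
  lig <- names(DEFAULT_LIGAND_RECEPTORS)
  pairs <- list()
  for (i in seq_len(n_ligands)) {
    if (i <= length(lig)) {
      pairs[[i]] <- tibble::tibble(ligand = lig[i],
                                   receptor = DEFAULT_LIGAND_RECEPTORS[[i]])
    } else {
      pairs[[i]] <- tibble::tibble(ligand = sprintf("LIG%02d", i),
                                   receptor = sprintf("RTK%02d", i))
    }
  }
  dplyr::bind_rows(pairs)
}

#' Configuration of the synthetic panel generator
#'
#' Defaults encode the study conditions the generator emulates: duplicate
#' measurements, log10-domain Gaussian noise with `sigma = log10(1.2)/2` (so
#' that the two-standard-deviation significance rule corresponds to a 1.2-fold
#' change), a pAKT/pERK scale factor `alpha_true = 2.386`, per-target
#' non-responder proportions of 40% (pERK) and 50% (pAKT), and responsive
#' classes split 50/25/25 between sustained, transient and late. Planted high
#' dose amplitudes depend log-linearly on the cognate receptor level
#' (positive) and on basal pErbB2 (negative), and are clipped to
#' `amp_range` so that the four kinetic classes remain geometrically
#' separable for unscaled k-means.
#'
#' @param ... Overrides for any default listed below.
#' @return Named list of generator parameters.
#' @export
panel_config <- function(...) {
  cfg <- list(
    sigma = log10(1.2) / 2,          # replicate noise SD, log10 units
    alpha_true = 2.386,              # pERK fc = alpha * pAKT fc (linear)
    class_probs = list(
      pERK = c(sustained = 0.30, transient = 0.15, late = 0.15, none = 0.40),
      pAKT = c(sustained = 0.25, transient = 0.125, late = 0.125, none = 0.50)
    ),
    sens_probs = c(equal = 0.4, high_greater = 0.3, high_only = 0.3),
    amp_mean = 1.6,                  # mean pERK log10 fold-change at 100 ng/ml
    amp_receptor_coef = 0.12,        # per log10 unit of cognate receptor
    amp_perbb2_coef = -0.11,         # per log10 unit of basal pErbB2
    amp_jitter_sd = 0.03,
    amp_range = c(1.4, 1.8),         # clip band for pERK amplitudes
    low_dose_frac = c(equal = 0.875, high_greater = 0.70),
    high_only_low_frac = 0.5,        # position below threshold, see below
    receptor_mean = 3.0, receptor_sd = 0.8,
    perbb2_mean = 3.5, perbb2_sd = 0.5,
    her2amp_erbb2_shift = 1.5,       # HER2amp lines overexpress/activate ErbB2
    hrpos_erbb3_shift = 0.8,         # HRpos lines carry more ErbB3
    basal_mean = c(pERK = 2.0, pAKT = 2.4),
    basal_sd = c(pERK = 0.3, pAKT = 0.4),
    receptor_phospho_mean = 2.2, receptor_phospho_sd = 0.4,
    kinase_expr_mean = 3.2, kinase_expr_sd = 0.2,
    detection_threshold = 2.0,
    n_replicates = 2L,
    n_control_replicates = 6L
  )
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown panel_config parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, user)
  for (tg in names(cfg$class_probs)) {
    p <- cfg$class_probs[[tg]]
    if (!setequal(names(p), KINETIC_CLASSES) || abs(sum(p) - 1) > 1e-8) {
      stop("class_probs for ", tg, " must be named over {",
           paste(KINETIC_CLASSES, collapse = ", "), "} and sum to 1",
           call. = FALSE)
    }
  }
  if (abs(sum(cfg$sens_probs) - 1) > 1e-8) {
    stop("sens_probs must sum to 1", call. = FALSE)
  }
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (cfg$alpha_true <= 0) stop("alpha_true must be > 0", call. = FALSE)
  cfg
}

# Trajectory templates on log10 fold-change at (10, 30, 90) minutes for peak
# amplitude p: sustained rises and holds, transient peaks early then decays,
# late rises monotonically to 90 min, none stays flat.
kinetic_template <- function(class, p) {
  switch(class,
    sustained = c(p, p, p),
    transient = c(p, p / 2, p / 10),
    late      = c(p / 10, p / 2, p),
    none      = c(0, 0, 0),
    stop("unknown kinetic class: ", class, call. = FALSE)
  )
}

# Planted low-dose peak amplitudes (log10) given the high-dose peak and the
# sensitivity class. Fractions act on linear fold-change above baseline so the
# 75% rule is exactly recoverable; "high_only" places the low dose halfway
# between no response and the significance threshold (flat when sigma = 0).
planted_low_amplitude <- function(sens_class, amp_high, cfg) {
  thr_lin <- 10^(2 * cfg$sigma)
  fc_high <- 10^amp_high
  lin <- switch(sens_class,
    equal        = 1 + cfg$low_dose_frac[["equal"]] * (fc_high - 1),
    high_greater = 1 + cfg$low_dose_frac[["high_greater"]] * (fc_high - 1),
    high_only    = 1 + cfg$high_only_low_frac * (thr_lin - 1),
    none         = 1
  )
  log10(lin)
}

#' Generate a synthetic response panel with planted ground truth
#'
#' @param n_cell_lines Number of cell lines (>= 1).
#' @param n_ligands Number of ligands (>= 1).
#' @param seed Integer seed; generation is a pure function of (seed, config).
#' @param config A [panel_config()].
#' @return List with elements `cube` (a [response_cube()]), `basal` (profile
#'   tibble), `subtypes`, `lr_map`, and `truth`. `truth` is a tibble with the
#'   planted kinetic class, sensitivity class, per-dose peak amplitudes and
#'   per-dose significance per (cell line, ligand, target); its attributes
#'   carry `alpha_true`, `sigma`, `seed` and the planted receptor levels.
#' @export
generate_panel <- function(n_cell_lines = 39, n_ligands = 15, seed = 1L,
                           config = panel_config()) {
  stopifnot(n_cell_lines >= 1, n_ligands >= 1)
  cfg <- config
  with_seed(seed, {
    cells <- sprintf("CL%02d", seq_len(n_cell_lines))
    subtypes <- tibble::tibble(
      cell_line = cells,
      subtype = rep(c("TNBC", "HER2amp", "HRpos"),
                    length.out = n_cell_lines)
    )
    lr_map <- default_ligand_receptor_map(n_ligands)
    ligands <- unique(lr_map$ligand)
    # ErbB2 is always profiled: it has no ligand of its own but its basal
    # phosphorylation is a planted (negative) driver of responsiveness
    receptors <- union(unique(lr_map$receptor), "ErbB2")
    cognate <- vapply(ligands, function(l) lr_map$receptor[lr_map$ligand == l][1],
                      character(1))

    # planted basal receptor landscape (log10 levels)
    recept_levels <- matrix(
      rnorm(n_cell_lines * length(receptors), cfg$receptor_mean,
            cfg$receptor_sd),
      nrow = n_cell_lines, dimnames = list(cells, receptors)
    )
    if ("ErbB3" %in% receptors) {
      hr <- subtypes$subtype == "HRpos"
      recept_levels[hr, "ErbB3"] <- recept_levels[hr, "ErbB3"] +
        cfg$hrpos_erbb3_shift
    }
    perbb2 <- rnorm(n_cell_lines, cfg$perbb2_mean, cfg$perbb2_sd)
    her2 <- subtypes$subtype == "HER2amp"
    perbb2[her2] <- perbb2[her2] + cfg$her2amp_erbb2_shift
    names(perbb2) <- cells
    recept_levels[her2, "ErbB2"] <- recept_levels[her2, "ErbB2"] +
      cfg$her2amp_erbb2_shift

    # planted classes and amplitudes per (cell, ligand, target)
    truth <- tidyr::expand_grid(cell_line = cells, ligand = ligands,
                                target = PANEL_TARGETS)
    truth$kinetic_class <- vapply(truth$target, function(tg) {
      p <- cfg$class_probs[[tg]]
      sample(names(p), 1, prob = p)
    }, character(1))
    truth$sens_class <- ifelse(
      truth$kinetic_class == "none", "none",
      sample(names(cfg$sens_probs), nrow(truth), replace = TRUE,
             prob = cfg$sens_probs)
    )
    base_amp <- cfg$amp_mean +
      cfg$amp_receptor_coef *
        (recept_levels[cbind(truth$cell_line, cognate[truth$ligand])] -
           cfg$receptor_mean) +
      cfg$amp_perbb2_coef * (perbb2[truth$cell_line] - cfg$perbb2_mean) +
      rnorm(nrow(truth), 0, cfg$amp_jitter_sd)
    base_amp <- pmin(pmax(base_amp, cfg$amp_range[1]), cfg$amp_range[2])
    # pAKT fold-change distribution = pERK distribution compressed by 1/alpha
    base_amp <- base_amp -
      ifelse(truth$target == "pAKT", log10(cfg$alpha_true), 0)
    truth$amp_high <- ifelse(truth$kinetic_class == "none", 0, base_amp)
    truth$amp_low <- vapply(seq_len(nrow(truth)), function(i) {
      planted_low_amplitude(truth$sens_class[i], truth$amp_high[i], cfg)
    }, numeric(1))
    thr_amp <- 2 * cfg$sigma
    truth$sig_high <- truth$amp_high > thr_amp
    truth$sig_low <- truth$amp_low > thr_amp
    truth$kinetic_high <- ifelse(truth$sig_high, truth$kinetic_class, "none")
    truth$kinetic_low <- ifelse(truth$sig_low, truth$kinetic_class, "none")

    # basal log10 levels of the two readouts per cell line
    basal_target <- sapply(PANEL_TARGETS, function(tg) {
      rnorm(n_cell_lines, cfg$basal_mean[[tg]], cfg$basal_sd[[tg]])
    })
    rownames(basal_target) <- cells

    # assemble the measurement cube
    ctrl <- tidyr::expand_grid(cell_line = cells, target = PANEL_TARGETS,
                               replicate = seq_len(cfg$n_control_replicates))
    ctrl$ligand <- CONTROL_LIGAND
    ctrl$dose <- NA_real_
    ctrl$time <- 0
    ctrl$value <- basal_target[cbind(ctrl$cell_line, ctrl$target)] +
      rnorm(nrow(ctrl), 0, cfg$sigma)

    stim <- tidyr::expand_grid(
      cell_line = cells, ligand = ligands, dose = PANEL_DOSES,
      target = PANEL_TARGETS, time = POST_TIMES,
      replicate = seq_len(cfg$n_replicates)
    )
    key <- function(df) paste(df$cell_line, df$ligand, df$target)
    truth_idx <- match(key(stim), key(truth))
    amp <- ifelse(stim$dose == 100, truth$amp_high[truth_idx],
                  truth$amp_low[truth_idx])
    tmpl <- matrix(NA_real_, nrow(stim), 1)
    t_pos <- match(stim$time, POST_TIMES)
    cls <- truth$kinetic_class[truth_idx]
    # template value at this time point for this class and amplitude
    frac <- numeric(nrow(stim))
    frac[cls == "sustained"] <- 1
    frac[cls == "none"] <- 1   # amplitude is 0 anyway
    tr <- cls == "transient"
    frac[tr] <- c(1, 0.5, 0.1)[t_pos[tr]]
    lt <- cls == "late"
    frac[lt] <- c(0.1, 0.5, 1)[t_pos[lt]]
    # low-dose flat cases (sens high_only/none at low dose) keep shape but the
    # amplitude already encodes the planted low-dose peak
    stim$value <- basal_target[cbind(stim$cell_line, stim$target)] +
      amp * frac + rnorm(nrow(stim), 0, cfg$sigma)

    cube <- response_cube(dplyr::bind_rows(ctrl[CUBE_COLUMNS],
                                           stim[CUBE_COLUMNS]))

    basal <- build_basal_profiles(cells, receptors, recept_levels, perbb2,
                                  basal_target, cfg)

    attr(truth, "alpha_true") <- cfg$alpha_true
    attr(truth, "sigma") <- cfg$sigma
    attr(truth, "seed") <- as.integer(seed)
    attr(truth, "receptor_levels") <- recept_levels
    attr(truth, "perbb2") <- perbb2
    attr(truth, "cognate") <- cognate

    list(cube = cube, basal = basal, subtypes = subtypes, lr_map = lr_map,
         truth = truth)
  })
}

build_basal_profiles <- function(cells, receptors, recept_levels, perbb2,
                                 basal_target, cfg) {
  expr <- tidyr::expand_grid(cell_line = cells, analyte = receptors)
  expr$kind <- "expression"
  expr$value <- recept_levels[cbind(expr$cell_line, expr$analyte)]

  phos <- tidyr::expand_grid(cell_line = cells, analyte = receptors)
  phos$kind <- "phosphorylation"
  phos$analyte <- paste0("p", phos$analyte)
  phos$value <- rnorm(nrow(phos), cfg$receptor_phospho_mean,
                      cfg$receptor_phospho_sd)
  phos$value[phos$analyte == "pErbB2"] <-
    perbb2[phos$cell_line[phos$analyte == "pErbB2"]]

  kin <- tidyr::expand_grid(cell_line = cells, analyte = c("ERK", "AKT"))
  kin$kind <- "expression"
  kin$value <- rnorm(nrow(kin), cfg$kinase_expr_mean, cfg$kinase_expr_sd)

  tgt <- tidyr::expand_grid(cell_line = cells, analyte = PANEL_TARGETS)
  tgt$kind <- "phosphorylation"
  tgt$value <- basal_target[cbind(tgt$cell_line, tgt$analyte)]

  prof <- dplyr::bind_rows(expr, phos, kin, tgt)
  prof$below_detection <- FALSE
  prof <- censor_at_threshold(prof, cfg$detection_threshold)
  basal_profiles(prof[BASAL_COLUMNS], thresholds = cfg$detection_threshold)
}

#' Floor basal values at the detection threshold
#'
#' Values below the per-analyte detection threshold are replaced by the
#' threshold and flagged `below_detection`; other rows are untouched.
#'
#' @param profiles Basal-profile tibble.
#' @param thresholds Named numeric vector of per-analyte thresholds (log10
#'   units), or a single number applied to all analytes.
#' @return The censored profile tibble.
#' @export
censor_at_threshold <- function(profiles, thresholds) {
  thr <- analyte_thresholds(thresholds, unique(profiles$analyte))
  if (any(!is.finite(thr))) stop("thresholds must be finite", call. = FALSE)
  lim <- thr[profiles$analyte]
  below <- profiles$value < lim
  profiles$value[below] <- lim[below]
  profiles$below_detection <- below | (profiles$below_detection %||% FALSE)
  profiles
}

#' Draw planted linear fold-change pairs from the amplitude model
#'
#' Convenience sampler for scale-fitting experiments: pERK linear fold-changes
#' follow the generator's amplitude distribution and pAKT fold-changes are the
#' same distribution compressed by `1/alpha_true`.
#'
#' @param n Number of pairs.
#' @param alpha_true Planted scale factor.
#' @param seed Integer seed.
#' @param config A [panel_config()].
#' @return List with numeric vectors `perk` and `pakt` (linear fold-changes).
#' @export
sample_fold_change_pairs <- function(n, alpha_true = 2.386, seed = 1L,
                                     config = panel_config()) {
  cfg <- config
  with_seed(seed, {
    amp <- cfg$amp_mean + rnorm(
      n, 0, sqrt((cfg$amp_receptor_coef * cfg$receptor_sd)^2 +
                   (cfg$amp_perbb2_coef * cfg$perbb2_sd)^2 +
                   cfg$amp_jitter_sd^2))
    amp <- pmin(pmax(amp, cfg$amp_range[1]), cfg$amp_range[2])
    perk <- 10^amp
    list(perk = perk, pakt = perk / alpha_true)
  })
}
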