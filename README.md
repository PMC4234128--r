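# gfresponse

Analysis of immediate-early growth-factor signaling across panels of cancer
cell lines. Starting from basal receptor tyrosine kinase (RTK) profiles and a
pERK/pAKT time-course "response cube" — phosphoprotein levels measured per
cell line × ligand × dose (1 and 100 ng/ml) × time (0, 10, 30, 90 min) ×
replicate — the package computes, for every cell-ligand combination:

* **Significance calls** — replicates are averaged in the log10 domain and a
  response is significant when any post-stimulation time point reaches
  `mean(controls) + 2 · sd(controls)`; with the calibration
  `2σ = log10(1.2)` this corresponds to a minimal ~1.2-fold change.
* **Fold-change summaries** — log10 fold-changes against the time-0 control
  mean, with the maximum across time points (and, for graphs, across doses).
* **Kinetic classes** — unsupervised k-means (k = 4, squared-Euclidean, best
  of 10 restarts) on the fold-change trajectories at (10, 30, 90) min,
  with centroids labeled *sustained*, *transient*, *late* or *none* from
  their geometry; non-significant responses are forced to *none*.
* **Dose-sensitivity classes** — *equal* when the low-dose response is at
  least 75% of the high-dose response on the linear fold-change-above-baseline
  scale, i.e. `(10^fc_low − 1)/(10^fc_high − 1) ≥ 0.75`; *high_greater* when
  significant but below 75%; *high_only*; *none*.
* **Pathway bias** — the pAKT fold-change distribution is rescaled onto the
  pERK distribution by the factor `α` minimizing the two-sample
  Cramér–von Mises distance
  `T = nm/(n+m)² · Σ_z (F_pAKT·α(z) − F_pERK(z))²`, and each (cell, ligand)
  pair gets a bias angle `θ = atan2(α·fc_pAKT, fc_pERK)` in degrees —
  45° balanced, < 45° ERK-biased, > 45° AKT-biased.
* **Statistical panels** — Pearson/Spearman correlations of fold-change or
  absolute response against basal RTK levels, Wilcoxon rank-sum subtype
  comparisons, and responder-vs-nonresponder enrichment tests.
* **Signaling graphs** — per-line and subtype-aggregate (interquartile-mean)
  node-edge graphs with min–max normalized node sizes/shades and
  response-weighted edges, exported as GraphML or node-link JSON.

Because the original ELISA dataset lives on an unversioned external website,
the package ships a **synthetic-data generator** (`generate_panel()`) that
emulates the study design — 39 lines × 15 ligands, duplicate measurements,
log-normal noise, detection-threshold censoring — with planted kinetic and
sensitivity classes, a planted receptor→response dependence (positive for
the cognate receptor, negative for basal pErbB2) and a planted pAKT/pERK
scale factor, so every stage can be scored against known ground truth.

## Worked example

```r
library(gfresponse)

pan <- generate_panel(n_cell_lines = 39, n_ligands = 15, seed = 20140321)
responses <- compute_fold_changes(pan$cube)          # fold-changes + 2-SD calls
responses <- assign_kinetics(responses, seed = 20140321)
summary <- build_response_summary(responses)         # the reference table
bias <- pathway_bias_table(responses)                # CvM-fitted alpha + angles
```

On this panel the pipeline prints (via `analysis/02–04`):

```
pERK: 62.4% of cell-ligand combinations significant at 100 ng/ml
pAKT: 56.4% of cell-ligand combinations significant at 100 ng/ml
Kinetic classes among significant responses:
     late      none sustained transient
     21.4      13.6      45.4      19.6
Fitted pathway scale factor alpha = 2.388
Median bias angle over 206 doubly-significant pairs: 45.7 deg
```

That is: roughly 60%/55% of combinations respond, about half of the
significant responses are sustained, and after rescaling pAKT by the fitted
`α ≈ 2.39` (the generator plants `α = 2.386`) the panel-median bias angle
sits at ~45°, i.e. balanced pathway activation.

The full workflow is the numbered scripts under `analysis/`
(`01_generate_data.R` … `06_networks.R`); each writes its tables under
`results/` and prints a short narrative of what it found.

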