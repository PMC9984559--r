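---
title: "Classifying missense variants from backbone-torsion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying missense variants from backbone-torsion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`dlrpmds` classifies missense protein variants as *deleterious* or
*unknown* (non-deleterious / undetermined) from the backbone torsion
angles of molecular-dynamics trajectories. Two related methods are
implemented:

1. **RP-MDS** — a statistical deviation score. Each variant's pooled
   (φ, ψ) angles become a Ramachandran density plot (RDP); the score
   counts grid cells that deviate from a wildtype + benign reference
   and a cut-off scan converts scores into binary calls.
2. **DL-RP-MDS** — a deep-learning pipeline. A time-lagged autoencoder
   embeds each trajectory frame into a low-dimensional latent space, the
   training classes are balanced with SMOTE, and a neural classifier
   produces per-frame probabilities that are averaged per variant.

The canonical data interchange format is the *torsion table*: one row
per (frame, residue) with `phi`/`psi` in degrees and a per-frame
timestamp in picoseconds (`read_torsion_table()` /
`write_torsion_table()`). Everything downstream runs from this table, so
the package is fully testable without trajectory files; an optional
adapter (`torsion_from_pdb()`, via **bio3d**) extracts the table from a
multi-model PDB.

# The analysis window

MD production runs are assumed to be saved on a regular grid (the
conventional setup is a 40 ns run saved every 30 ps, i.e. 1334 frames
from t = 0). Analysis uses the equilibrated tail of the run:
`select_window(traj, 30000, 40000)` keeps frames with
`30000 <= t < 40000` ps — a half-open window, which for the conventional
setup contains exactly 334 frames.

# Ramachandran density plots and the deviation score

`variant_rdp()` pools the (φ, ψ) points of all residues and windowed
frames and estimates a density on a 32 × 32 grid over the torus with a
Gaussian product kernel (`kde_density()`):

* **Periodicity.** Distances are computed on the circle
  (`min(|d|, 360 − |d|)` per axis), so mass near φ = ±180° wraps
  correctly. For truncation radii below 180° this is algebraically
  identical to replicating every point at ±360° shifts.
* **Truncation.** The kernel is truncated at 4 bandwidths per axis, a
  standard KDE speed-up. A side effect worth knowing: cells far from
  every occupied basin are exactly zero in every grid, so the reference
  SD there is zero and such cells can never be counted as significant.
  Significant-cell counts therefore scale with the size of the occupied
  region.
* **Bandwidth.** Scott's rule per axis (`n^(-1/6) · sd`), or a fixed
  bandwidth in degrees.
* The grid is renormalized to sum to exactly 1.

`build_reference()` averages the wildtype + benign grids and records the
per-cell population SD. `deviation_score()` marks a cell significant
when `|d - mean| > k_sd * sd` (default `k_sd = 1`), counts the
significant cells `n`, and reports `log(n + 1)` (`transform =
"log_count"`), the compressive scale of the published deviation axis.

## Lognormal model and cut-off scan

Benign and pathogenic score sets are modelled as lognormal
(`fit_lognormal()`, the closed-form MLE: mean and population SD of the
log scores). Goodness of fit (`gof_tests()`) uses the one-sample
Kolmogorov–Smirnov test against the fitted CDF plus the
Anderson–Darling test of the log scores against normality with
estimated parameters (the composite "case 3" test, which is exactly the
composite lognormality test). Because the K-S parameters are estimated
from the same sample its p-value is conservative; lean on the A-D
p-value for borderline samples.

`optimize_cutoff()` sweeps candidate cut-offs on an equal grid (default
2.7–4.0 at bin 0.01, i.e. 131 candidates). At each candidate a variant
is called deleterious iff its score **strictly exceeds** the cut-off;
the optimum minimizes `|TP% − TN%|`, ties broken toward the smallest
cut-off. Two numerical choices matter:

* Grid candidates are rounded to 10 decimals so accumulated
  floating-point error cannot move a candidate across a score that sits
  exactly on the grid. With benign scores all at 3.0 and pathogenic all
  at 3.5, the returned optimum is exactly 3.00 (the lowest candidate
  achieving TP% = TN% = 100% under the strict-`>` rule).
* The published 2.7–4.0 window reflects the score scale of the proteins
  it was derived on. Synthetic log-count scores can sit elsewhere
  (roughly `ln` of the number of occupied-region cells that fluctuate
  past one SD), so the CV driver and the package's own benchmark runs
  pass an explicit scan range spanning the observed scores;
  `optimize_cutoff()` keeps the published default.

# The deep-learning pipeline

## Frame representation

`frame_matrix()` flattens each trajectory frame into a vector of
`2 × n_residues` angles (columns `res<r>_phi`, `res<r>_psi`). An
optional sine/cosine featurization removes the ±180° discontinuity.
Features are z-scored with statistics fitted **on training frames
only** (`standardize()`); held-out data always reuses the training
parameters.

## Time-lagged autoencoder

`train_autoencoder()` trains an MLP `p → hidden → q → hidden → p`
(default hidden layers 1000/1000, dropout 0.1, Adam at learning rate
0.001) to reconstruct the standardized configuration at frame `t + 1`
from the configuration at frame `t`. Lag pairs never cross variant
boundaries. The latent bottleneck and the output layer are linear;
hidden units are Leaky-ReLU (slope 0.01). Early stopping monitors a 10%
validation split of the lag pairs (patience 5) and restores the best
weights. `max_pairs` optionally caps the number of lag pairs by a
seeded subsample — an unsupervised reconstruction objective does not
need every frame to converge, and this is the main speed lever at desk
scale.

The engine behind both networks (`mlp_new()` / `mlp_train()`) is a
small dense-matrix implementation written for this package:
Glorot-uniform initialization, inverted dropout, Adam with bias
correction, mini-batches, and per-layer linear overrides for the
bottleneck. No external deep-learning framework is required.

## Class balancing and classifier

Training latents are balanced with SMOTE (`smote_oversample()`): each
synthetic minority point is `x_i + u (x_j − x_i)` with `x_j` one of the
`k = 5` nearest minority neighbours. **SMOTE touches training data
only** — validation and test frames are never oversampled.

`train_classifier()` maps latents through one hidden layer (default
1024 units) to two sigmoid outputs, one per label (deleterious D,
unknown U), trained with multi-label binary cross-entropy. A loss of
the form `−Σ y log ŷ` alone provides no gradient on the cold output of
a sigmoid pair (nothing ever pushes an output *down*), so the
complement term `−Σ (1 − y) log(1 − ŷ)` is included — the standard
meaning of cross-entropy with independent sigmoid outputs. The two
outputs are deliberately not renormalized (`normalize_probs = TRUE`
restores the normalized convention).

`aggregate_variant()` averages the per-frame probabilities over a
variant's full time series and takes the larger mean, with exact ties
going to "unknown" (conservative).

## Hyperparameters

`tune_hyperparameters()` searches the grid of latent dimensions ×
classifier widths × dropout rates, scoring each trial by the F2 score
(recall-weighted, β = 2) of frame-level validation predictions. A
budget caps the number of trials; any black-box optimizer could sit in
this slot, and exhaustive/budgeted grid search keeps the package
dependency-free and reproducible. Published gene-specific latent
dimensions were 14, 8, and 20; the package default is `q = 14`.

# Cross-validated evaluation

`stratified_cv()` runs stratified k-fold CV with repeats (default
4 × 5 = 20 models). Per model:

* **RP-MDS** — the reference is rebuilt from the training-fold benign
  grids plus wildtype grids; scores are recomputed; ROC curves come
  from the cut-off sweep at bin 0.01; the cut-off is optimized on the
  training scores over a range spanning the data, and the test balanced
  accuracy is reported.
* **DL-RP-MDS** — autoencoder, SMOTE, and classifier are refit from
  scratch on the training split; frame-level ROC/AUC uses the predicted
  probabilities; variant-level balanced accuracy uses the aggregated
  calls.

`grouping = "by_variant"` keeps all frames of a variant together
(realistic generalization to unseen variants); `"by_frame"` treats
frames as independent samples (the optimistic published convention for
frame-level AUC). `average_roc()` vertically averages the per-model ROC
curves on a fixed FPR grid.

# Synthetic benchmark generator

`synthetic_spec()` + `make_dataset()` generate labelled torsion
trajectories with the statistical structure the pipeline assumes, and
nothing more:

* each residue samples a basin near a canonical Ramachandran region
  (α at (−63, −43), β at (−120, 130), left-handed α at (57, 47), with
  ±10° per-residue offsets; weights 0.45/0.40/0.15);
* angles follow a wrapped AR(1) process around the basin centre
  (coefficient 0.9, stationary SD 12°); multi-basin residues switch
  basins in geometric segments (mean 100 frames);
* every non-wildtype variant gets a small per-variant basin-centre
  jitter (SD 2°); pathogenic variants additionally shift a contiguous
  central block of 10% of residues by `perturb_shift` degrees (default
  30°) in both φ and ψ — a localized structural deformity.

Because benign and pathogenic variants receive the *same* jitter, a
zero perturbation makes the two classes statistically exchangeable —
the null case used to verify that the pipeline finds nothing when there
is nothing to find. The generator is a calibration instrument for the
pipeline's statistics, not a physical model of protein dynamics.

# Problem sizes

The package's own benchmark runs (tests and `scripts/acceptance.R`) use
desk-scale problem sizes chosen as the package's default
reduced-compute configuration:

* default synthetic benchmark: 60 residues, 24 benign / 81 pathogenic
  variants, 1334 frames at 30 ps, analysis window = last 10 ns
  (334 frames per variant);
* reduced networks: autoencoder hidden 128/128 with `max_pairs = 3000`,
  classifier hidden 128, 20 epochs each, `q = 14`;
* by-frame CV at one 4-fold round per seed.

At these sizes a full 4-fold round (4 models, ~35,000 frames) takes on
the order of a couple of minutes on one CPU. The published-scale
architecture (hidden 1000/1000 and 1024) is the package default for
real analyses.

# Limitations

* The package starts from torsion tables; running MD simulations and
  computing trajectories is out of scope (the PDB adapter is a
  convenience, not a trajectory engine).
* The deviation score ignores *which* cells deviate — only the count
  matters — and inherits the truncation-induced occupancy dependence
  described above.
* The published cut-off window (2.7–4.0) and latent dimensions are
  protein-family-specific settings, not universal constants.
* The probabilistic outputs of the classifier are not calibrated
  probabilities; they are scores whose ordering carries the signal.
* By-frame CV overstates generalization to unseen variants because
  frames of one variant appear on both sides of the split; use
  by-variant grouping for honest variant-level claims.
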