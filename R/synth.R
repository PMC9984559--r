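## Synthetic torsion trajectories with the statistical structure the pipeline
## assumes: per-residue basins in the canonical Ramachandran regions, wrapped
## AR(1) temporal dynamics, and a class-dependent basin perturbation applied
## to a contiguous residue block (a localized structural deformity).

#' Specification of a synthetic gene/variant family
#'
#' Defaults emulate the MD output conventions the pipeline expects: a 40 ns
#' production run saved every 30 ps (1334 frames from t = 0), 60 residues,
#' AR(1) coefficient 0.9. Every residue gets one basin whose centre is drawn
#' near a canonical region (alpha, beta, or left-handed alpha) with a small
#' per-residue offset; multi-basin residues can be supplied explicitly via
#' `basins` (per residue, a data frame with `phi`, `psi`, `spread`, `weight`).
#'
#' @param n_residues Number of residues (default 60).
#' @param n_frames Frames per trajectory (default 1334).
#' @param dt_ps Saving interval in ps (default 30).
#' @param basins Optional list (length `n_residues`) of basin data frames;
#'   by default generated from `seed`.
#' @param perturb_shift Centre shift (degrees, both phi and psi) applied to
#'   the perturbed residue block of pathogenic variants (default 30).
#' @param perturb_extra_spread Extra spread (degrees) for the perturbed block
#'   (default 0).
#' @param perturb_frac Fraction of residues in the contiguous perturbed block
#'   (default 0.1), centred in the chain.
#' @param temporal_corr AR(1) coefficient in `[0, 1)` (default 0.9).
#' @param spread Within-basin SD in degrees (default 12).
#' @param benign_jitter_sd Per-variant basin-centre jitter SD in degrees
#'   applied to every non-wildtype variant (default 2).
#' @param seed Seed for the basin layout (part of the gene definition).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 60, n_frames = 1334, dt_ps = 30,
                           basins = NULL, perturb_shift = 30,
                           perturb_extra_spread = 0, perturb_frac = 0.1,
                           temporal_corr = 0.9, spread = 12,
                           benign_jitter_sd = 2, seed = 1L) {
  if (n_residues < 3 || n_frames < 2 || dt_ps <= 0)
    stop_dlrpmds("invalid synthetic dimensions")
  if (temporal_corr < 0 || temporal_corr >= 1)
    stop_dlrpmds("temporal_corr must lie in [0, 1)")
  if (spread <= 0 || perturb_extra_spread < 0)
    stop_dlrpmds("spreads must be positive")
  if (is.null(basins)) {
    # canonical Ramachandran regions: alpha, beta, left-handed alpha
    regions <- rbind(alpha = c(-63, -43), beta = c(-120, 130), alphaL = c(57, 47))
    basins <- with_seed(seed, {
      reg <- sample(1:3, n_residues, replace = TRUE, prob = c(0.45, 0.40, 0.15))
      lapply(seq_len(n_residues), function(r)
        data.frame(phi = regions[reg[r], 1] + stats::runif(1, -10, 10),
                   psi = regions[reg[r], 2] + stats::runif(1, -10, 10),
                   spread = spread, weight = 1))
    })
  }
  if (length(basins) != n_residues)
    stop_dlrpmds("basins must have one entry per residue")
  for (b in basins) {
    if (abs(sum(b$weight) - 1) > 1e-9)
      stop_dlrpmds("basin weights per residue must sum to 1")
    if (any(b$spread <= 0)) stop_dlrpmds("basin spreads must be positive")
  }
  m <- max(1L, round(perturb_frac * n_residues))
  block <- seq(floor((n_residues - m) / 2) + 1L, length.out = m)
  structure(list(n_residues = n_residues, n_frames = n_frames, dt_ps = dt_ps,
                 basins = basins, perturb_shift = perturb_shift,
                 perturb_extra_spread = perturb_extra_spread,
                 perturb_block = block, temporal_corr = temporal_corr,
                 benign_jitter_sd = benign_jitter_sd),
            class = "synthetic_spec")
}

# AR(1) series around 0 with stationary SD `spread`; wrapped later.
ar1_series <- function(n, rho, spread) {
  innov_sd <- spread * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, spread)
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) x[t] <- rho * x[t - 1] + e[t - 1]
  }
  x
}

#' Simulate one labelled torsion trajectory
#'
#' Per residue, basins are chosen per trajectory segment (segments of
#' geometric length, mean 100 frames, sampled by basin weight) and the
#' (phi, psi) angles follow a wrapped AR(1) process around the basin centre.
#' Benign and pathogenic variants both receive a small per-variant
#' basin-centre jitter; pathogenic variants additionally shift the perturbed
#' residue block by `perturb_shift` degrees (phi and psi) and widen its
#' spread by `perturb_extra_spread`, so a zero perturbation makes the two
#' classes statistically exchangeable.
#'
#' @param spec A [synthetic_spec()].
#' @param class_label `"wt"`, `"benign"` or `"pathogenic"`.
#' @param seed RNG seed for this variant.
#' @param variant_id,gene Labels.
#' @return A [torsion_trajectory()].
#' @export
simulate_trajectory <- function(spec, class_label = c("wt", "benign", "pathogenic"),
                                seed = NULL, variant_id = class_label[1],
                                gene = "synthgene") {
  class_label <- match.arg(class_label)
  nf <- spec$n_frames; nr <- spec$n_residues
  with_seed(seed, {
    ang <- array(NA_real_, c(nf, nr, 2))
    for (r in seq_len(nr)) {
      b <- spec$basins[[r]]
      centers <- as.matrix(b[, c("phi", "psi")])
      spreads <- b$spread
      if (class_label != "wt" && spec$benign_jitter_sd > 0)
        centers <- centers + stats::rnorm(length(centers), 0, spec$benign_jitter_sd)
      if (class_label == "pathogenic" && r %in% spec$perturb_block) {
        centers <- centers + spec$perturb_shift
        spreads <- spreads + spec$perturb_extra_spread
      }
      # basin id per frame: geometric segments (mean 100 frames) when >1 basin
      if (nrow(b) > 1) {
        bid <- integer(0)
        while (length(bid) < nf) {
          len <- 1L + stats::rgeom(1, 1 / 100)
          bid <- c(bid, rep(sample.int(nrow(b), 1, prob = b$weight), len))
        }
        bid <- bid[seq_len(nf)]
      } else bid <- rep(1L, nf)
      for (ax in 1:2) {
        dev <- ar1_series(nf, spec$temporal_corr, 1)
        ang[, r, ax] <- wrap_angle(centers[bid, ax] + dev * spreads[bid])
      }
    }
    torsion_trajectory(ang, times = (seq_len(nf) - 1) * spec$dt_ps,
                       variant_id = variant_id, gene = gene)
  })
}

#' Generate a labelled synthetic benchmark dataset
#'
#' Reproducible manifest plus trajectories; the default class imbalance is
#' configurable to mimic realistic benign/pathogenic ratios (e.g. 24:81).
#'
#' @param n_benign,n_pathogenic Labelled variant counts (each >= 1).
#' @param n_wt Wildtype replicates (default 1; excluded from labelled classes).
#' @param spec A [synthetic_spec()].
#' @param seed Master seed; each variant simulates from a derived child seed.
#' @param gene Gene label.
#' @return List with `manifest` ([variant_manifest()]) and `trajectories`
#'   (named list of [torsion_trajectory()]s).
#' @export
make_dataset <- function(n_benign = 24, n_pathogenic = 81, n_wt = 1,
                         spec = synthetic_spec(), seed = 1L,
                         gene = "synthgene") {
  if (n_benign < 1 || n_pathogenic < 1)
    stop_dlrpmds("need at least one benign and one pathogenic variant")
  ids <- c(if (n_wt > 0) sprintf("WT%d", seq_len(n_wt)),
           sprintf("BEN%03d", seq_len(n_benign)),
           sprintf("PAT%03d", seq_len(n_pathogenic)))
  cls <- c(rep("wt", n_wt), rep("benign", n_benign),
           rep("pathogenic", n_pathogenic))
  seeds <- derive_seeds(seed, length(ids))
  trajs <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids))
    trajs[[i]] <- simulate_trajectory(spec, cls[i], seed = seeds[[i]],
                                      variant_id = ids[i], gene = gene)
  list(manifest = variant_manifest(ids, gene, cls),
       trajectories = trajs)
}

#' Materialize a dataset as torsion tables plus a manifest CSV
#'
#' @param dataset A [make_dataset()] result.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$data_path <- file.path(dir, paste0(man$variant_id, ".tsv"))
  for (i in seq_len(nrow(man)))
    write_torsion_table(dataset$trajectories[[man$variant_id[i]]],
                        man$data_path[i])
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
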