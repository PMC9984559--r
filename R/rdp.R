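## Ramachandran density plots (RDPs) and the RP-MDS structural-deviation score.
##
## An RDP is a periodic Gaussian KDE of pooled (phi, psi) points evaluated at
## the centers of a 32 x 32 grid over the torus and renormalized to sum to 1.
## Deviation scoring compares a variant's RDP cell-by-cell with a reference
## built from the wildtype + benign densities.

GRID_DIM <- 32L

#' Ramachandran grid constructor
#'
#' @param density Non-negative `n x n` matrix summing to 1.
#' @param grid_edges Bin edges (length n+1) shared by both axes, spanning
#'   `[-180, 180]`.
#' @return An object of class `ramachandran_grid`.
#' @export
ramachandran_grid <- function(density,
                              grid_edges = seq(-180, 180, length.out = nrow(density) + 1L)) {
  if (!is.matrix(density) || nrow(density) != ncol(density))
    stop_dlrpmds("density must be a square matrix")
  if (any(density < 0)) stop_dlrpmds("density must be non-negative")
  s <- sum(density)
  if (abs(s - 1) > 1e-9)
    stop_dlrpmds("density must sum to 1 (got %.12g)", s)
  if (length(grid_edges) != nrow(density) + 1L)
    stop_dlrpmds("grid_edges must have length nrow(density) + 1")
  structure(list(density = density, grid_edges = grid_edges),
            class = "ramachandran_grid")
}

#' @export
print.ramachandran_grid <- function(x, ...) {
  n <- nrow(x$density)
  cat(sprintf("ramachandran_grid %dx%d (max cell %.4g, %d nonzero cells)\n",
              n, n, max(x$density), sum(x$density > 0)))
  invisible(x)
}

# Cell centers for an edge vector.
grid_centers <- function(edges) (edges[-length(edges)] + edges[-1]) / 2

# Scott's rule per axis for 2-D data; falls back to one cell width for
# degenerate samples (n = 1 or zero spread).
scott_bandwidth <- function(pts, n_grid = GRID_DIM) {
  n <- nrow(pts)
  cell <- 360 / n_grid
  h <- apply(pts, 2, stats::sd) * n^(-1 / 6)
  h[!is.finite(h) | h <= 0] <- cell
  h
}

#' Periodic kernel density estimate on the Ramachandran torus
#'
#' Gaussian product kernel with toroidal (wrapped) distances, truncated at 4
#' bandwidths per axis, evaluated at the centers of an `n_grid x n_grid` grid
#' and renormalized to sum to 1. For truncation radii below 180 deg the
#' wrapped-distance evaluation is identical to replicating every point at
#' +-360 deg shifts in both axes.
#'
#' @param angles Two-column matrix of (phi, psi) points in `[-180, 180)`.
#' @param bandwidth `"auto"` (Scott's rule per axis) or a positive numeric
#'   scalar / length-2 vector in degrees.
#' @param n_grid Grid dimension (default 32).
#' @param truncate Kernel truncation radius in bandwidths (default 4).
#' @return A [ramachandran_grid()].
#' @export
kde_density <- function(angles, bandwidth = "auto", n_grid = GRID_DIM,
                        truncate = 4) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 1) stop_dlrpmds("need at least one (phi, psi) point")
  if (ncol(angles) != 2) stop_dlrpmds("angles must have two columns (phi, psi)")
  if (any(!is.finite(angles))) stop_dlrpmds("angles contain non-finite values")
  angles <- wrap_angle(angles)
  if (identical(bandwidth, "auto")) {
    h <- scott_bandwidth(angles, n_grid)
  } else {
    h <- as.numeric(bandwidth)
    if (length(h) == 1) h <- rep(h, 2)
    if (any(!is.finite(h)) || any(h <= 0))
      stop_dlrpmds("bandwidth must be positive")
  }
  edges <- seq(-180, 180, length.out = n_grid + 1L)
  centers <- grid_centers(edges)
  # Separable kernel: density[i, j] = sum_p Kx[i, p] * Ky[j, p].
  kern_axis <- function(x, hh) {
    d <- abs(outer(centers, x, "-"))
    d <- pmin(d, 360 - d)                 # wrapped distance on the circle
    z <- d / hh
    k <- exp(-0.5 * z^2)
    k[z > truncate] <- 0
    k
  }
  kx <- kern_axis(angles[, 1], h[1])
  ky <- kern_axis(angles[, 2], h[2])
  dens <- kx %*% t(ky)
  s <- sum(dens)
  if (s <= 0)
    stop_dlrpmds("all kernel mass truncated; increase bandwidth or truncate")
  ramachandran_grid(dens / s, edges)
}

#' RDP of a variant trajectory
#'
#' Pools the (phi, psi) pairs of all residues over all frames of the (already
#' windowed) trajectory into a single periodic KDE.
#'
#' @param traj A [torsion_trajectory()], windowed to the analysis interval.
#' @param ... Passed to [kde_density()].
#' @return A [ramachandran_grid()].
#' @export
variant_rdp <- function(traj, ...) {
  pts <- cbind(as.vector(traj$angles[, , 1]), as.vector(traj$angles[, , 2]))
  out <- kde_density(pts, ...)
  attr(out, "variant_id") <- traj$variant_id
  out
}

#' Reference model from wildtype + benign densities
#'
#' Elementwise mean and population standard deviation across the supplied
#' grids; this is the "training data" the deviation score compares against.
#'
#' @param rdps List of at least two [ramachandran_grid()]s of identical shape.
#' @return An object of class `reference_model` with `mean`, `sd`,
#'   `n_sources`.
#' @export
build_reference <- function(rdps) {
  if (length(rdps) < 2) stop_dlrpmds("need at least 2 grids to build a reference")
  dims <- vapply(rdps, function(g) nrow(g$density), integer(1))
  if (length(unique(dims)) != 1) stop_dlrpmds("grids have mismatched shapes")
  arr <- vapply(rdps, function(g) g$density, rdps[[1]]$density)
  m <- apply(arr, c(1, 2), mean)
  s <- sqrt(apply(arr, c(1, 2), function(v) mean((v - mean(v))^2)))
  structure(list(mean = m, sd = s, n_sources = length(rdps),
                 grid_edges = rdps[[1]]$grid_edges),
            class = "reference_model")
}

#' Structural-deviation score of a variant RDP
#'
#' Marks a grid cell significant when the variant density lies beyond
#' `k_sd` reference standard deviations from the reference mean
#' (`|d - mean| > k_sd * sd`), counts the significant cells, and maps the
#' count to a score: the count itself (`"count"`) or `log(n + 1)`
#' (`"log_count"`, default — the compressive scale of the published
#' deviation axis).
#'
#' @param rdp A [ramachandran_grid()].
#' @param ref A [build_reference()] model of matching shape.
#' @param k_sd Significance multiple of the reference SD (default 1).
#' @param transform `"log_count"` or `"count"`.
#' @param side `"both"` (default, absolute deviation), `"above"` or
#'   `"below"` for one-sided variants.
#' @return An object of class `deviation_score` with `variant_id`,
#'   `n_significant_cells`, `score`.
#' @export
deviation_score <- function(rdp, ref, k_sd = 1, transform = c("log_count", "count"),
                            side = c("both", "above", "below")) {
  transform <- match.arg(transform)
  side <- match.arg(side)
  if (!identical(dim(rdp$density), dim(ref$mean)))
    stop_dlrpmds("grid and reference shapes differ")
  if (k_sd <= 0) stop_dlrpmds("k_sd must be positive")
  dev <- rdp$density - ref$mean
  sig <- switch(side,
                both  = abs(dev) > k_sd * ref$sd,
                above = dev > k_sd * ref$sd,
                below = -dev > k_sd * ref$sd)
  n <- sum(sig)
  structure(list(variant_id = attr(rdp, "variant_id"),
                 n_significant_cells = n,
                 score = if (transform == "count") n else log(n + 1),
                 transform = transform, k_sd = k_sd),
            class = "deviation_score")
}

#' Serialize / read a grid as columnar text
#'
#' `cell_i<TAB>cell_j<TAB>value` rows at full double precision; round-trips
#' exactly. Works for both densities and reference means/SDs.
#'
#' @param grid A [ramachandran_grid()].
#' @param path File path.
#' @export
write_grid <- function(grid, path) {
  n <- nrow(grid$density)
  idx <- expand.grid(cell_i = seq_len(n), cell_j = seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("cell_i\tcell_j\tvalue", con)
  writeLines(sprintf("%d\t%d\t%.17g", idx$cell_i, idx$cell_j,
                     grid$density[cbind(idx$cell_i, idx$cell_j)]), con)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- max(df$cell_i)
  d <- matrix(0, n, n)
  d[cbind(df$cell_i, df$cell_j)] <- df$value
  ramachandran_grid(d)
}
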