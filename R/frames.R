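## Per-frame feature vectors: each trajectory frame becomes a length-p vector
## of (phi, psi) angles over all residues (p = 2 * n_residues), the input
## representation of the deep-learning stage.

#' Flatten trajectories into a per-frame feature matrix
#'
#' Stacks every frame of every trajectory into one matrix whose columns are
#' `res<r>_phi, res<r>_psi` for each residue. An optional sine/cosine
#' featurization (`features = "sincos"`, length 2p) removes the +-180
#' wrap-around discontinuity for periodicity-sensitive datasets.
#'
#' @param trajectories Named list of [torsion_trajectory()]s (all with the
#'   same residue set).
#' @param manifest Optional [variant_manifest()] supplying `class_label` per
#'   variant id.
#' @param features `"angles"` (default; raw degrees) or `"sincos"`.
#' @return An object of class `frame_set`: list with matrix `x` (frames x p),
#'   `variant_id`, `frame_index`, `label` (per frame), `feature_names`.
#' @export
frame_matrix <- function(trajectories, manifest = NULL,
                         features = c("angles", "sincos")) {
  features <- match.arg(features)
  if (!length(trajectories)) stop_dlrpmds("no trajectories supplied")
  nr <- vapply(trajectories, n_residues, integer(1))
  if (length(unique(nr)) != 1)
    stop_dlrpmds("all trajectories must share one residue set")
  blocks <- lapply(trajectories, function(tr) {
    nf <- n_frames(tr)
    m <- matrix(aperm(tr$angles, c(1, 3, 2)), nrow = nf)  # phi,psi interleaved
    m
  })
  x <- do.call(rbind, blocks)
  ids <- rep(unname(vapply(trajectories, function(tr) tr$variant_id, character(1))),
             vapply(trajectories, n_frames, integer(1)))
  fidx <- unname(unlist(lapply(trajectories, function(tr) seq_len(n_frames(tr)))))
  rid <- trajectories[[1]]$residue_ids
  feature_names <- as.vector(t(cbind(sprintf("res%d_phi", rid),
                                     sprintf("res%d_psi", rid))))
  if (features == "sincos") {
    rad <- x * pi / 180
    x <- cbind(sin(rad), cos(rad))
    feature_names <- c(paste0("sin_", feature_names), paste0("cos_", feature_names))
  }
  colnames(x) <- feature_names
  label <- rep(NA_character_, nrow(x))
  if (!is.null(manifest))
    label <- manifest$class_label[match(ids, manifest$variant_id)]
  structure(list(x = x, variant_id = ids, frame_index = fidx,
                 label = label, features = features),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d frames x %d features from %d variants\n",
              nrow(x$x), ncol(x$x), length(unique(x$variant_id))))
  invisible(x)
}

# Row subset of a frame_set.
frame_subset <- function(fs, rows) {
  structure(list(x = fs$x[rows, , drop = FALSE],
                 variant_id = fs$variant_id[rows],
                 frame_index = fs$frame_index[rows],
                 label = fs$label[rows], features = fs$features),
            class = "frame_set")
}

#' Z-score standardization fitted on a training subset
#'
#' Per-feature mean/SD computed on the training rows only; held-out data must
#' be transformed with the same parameters. Constant features (SD = 0) are
#' flagged, standardized with SD 1 (i.e. centred to 0), and a warning is
#' issued.
#'
#' @param x Numeric matrix (rows = samples) to transform.
#' @param params Optional existing parameters (list with `center`, `scale`)
#'   from a previous call; when `NULL` they are fitted on `fit_rows` of `x`.
#' @param fit_rows Rows used to fit the parameters (default: all rows).
#' @return List with the transformed matrix `x` and the `params` used.
#' @export
standardize <- function(x, params = NULL, fit_rows = seq_len(nrow(x))) {
  x <- as.matrix(x)
  if (is.null(params)) {
    if (!length(fit_rows)) stop_dlrpmds("empty training subset")
    xt <- x[fit_rows, , drop = FALSE]
    center <- colMeans(xt)
    scale <- apply(xt, 2, stats::sd)
    if (nrow(xt) == 1) scale <- rep(0, ncol(xt))
    const <- !is.finite(scale) | scale == 0
    if (any(const)) {
      warning(sprintf("%d constant feature(s) standardized with SD 1", sum(const)))
      scale[const] <- 1
    }
    params <- list(center = center, scale = scale)
  }
  list(x = sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/"),
       params = params)
}
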