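# Shared fixture builders. Everything is generated in code at test time.

# A small torsion trajectory with deterministic angles.
tiny_trajectory <- function(n_frames = 3, n_residues = 2, dt = 30,
                            variant_id = "toy") {
  ang <- array(seq_len(n_frames * n_residues * 2) * 7 %% 360 - 180,
               c(n_frames, n_residues, 2))
  torsion_trajectory(ang, times = (seq_len(n_frames) - 1) * dt,
                     variant_id = variant_id)
}

# Deterministic pseudo-random grids for reference-model tests.
random_grid <- function(seed, n = 32) {
  set.seed(seed)
  d <- matrix(rexp(n * n), n, n)
  ramachandran_grid(d / sum(d))
}

# Small synthetic dataset for pipeline tests (desk scale).
small_dataset <- function(seed = 1, n_benign = 4, n_pathogenic = 6, n_wt = 1,
                          n_residues = 20, n_frames = 120, shift = 30) {
  spec <- synthetic_spec(n_residues = n_residues, n_frames = n_frames,
                         dt_ps = 30, perturb_shift = shift, seed = seed)
  make_dataset(n_benign, n_pathogenic, n_wt, spec = spec, seed = seed + 1000)
}

# Fast network settings for tests that train; overrides win over the
# test defaults.
test_ae <- function(...) {
  do.call(ae_config, utils::modifyList(
    list(hidden = c(32, 32), epochs = 8, batch_size = 128, max_pairs = 2000),
    list(...)))
}
test_clf <- function(...) {
  do.call(classifier_config, utils::modifyList(
    list(hidden = 32, epochs = 8, batch_size = 256), list(...)))
}

# Random rigid motion (rotation + translation) applied to 3-vectors.
random_rigid <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, sd = 5)
  function(p) as.vector(R %*% p + t)
}
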