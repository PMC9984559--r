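## Time-lagged autoencoder: encoder p -> q and decoder q -> p trained to
## reconstruct the standardized torsion configuration at time t+1 from the one
## at time t, so the latent coordinates capture the slow structural dynamics.

#' Default autoencoder configuration
#'
#' Two hidden layers of 1000 Leaky-ReLU nodes on each side, dropout 0.1,
#' Adam with learning rate 0.001, batch 256, up to 50 epochs with early
#' stopping (patience 5 on a 10% validation split of the lag pairs), time
#' lag of one saved frame.
#'
#' @param hidden Hidden-layer widths of the encoder (mirrored in the decoder).
#' @param dropout Dropout rate on hidden layers.
#' @param lr,epochs,batch_size,patience,val_frac Training controls.
#' @param lag Time lag in saved frames.
#' @param max_pairs Optional cap on lag pairs used for fitting (seeded
#'   subsample); `NULL` uses all pairs.
#' @return A named list of settings.
#' @export
ae_config <- function(hidden = c(1000, 1000), dropout = 0.1, lr = 0.001,
                      epochs = 50, batch_size = 256, patience = 5,
                      val_frac = 0.1, lag = 1L, max_pairs = NULL) {
  list(hidden = hidden, dropout = dropout, lr = lr, epochs = epochs,
       batch_size = batch_size, patience = patience, val_frac = val_frac,
       lag = as.integer(lag), max_pairs = max_pairs)
}

# (t, t + lag) index pairs within each variant; pairs never span variants.
lag_pairs <- function(variant_id, frame_index, lag = 1L) {
  idx_in <- integer(0); idx_out <- integer(0)
  for (v in unique(variant_id)) {
    rows <- which(variant_id == v)
    rows <- rows[order(frame_index[rows])]
    if (length(rows) > lag) {
      idx_in <- c(idx_in, rows[seq_len(length(rows) - lag)])
      idx_out <- c(idx_out, rows[-seq_len(lag)])
    }
  }
  if (!length(idx_in)) stop_dlrpmds("no valid time-lag pairs (need >= lag+1 consecutive frames per variant)")
  list(input = idx_in, target = idx_out)
}

#' Train a time-lagged autoencoder
#'
#' Standardizes the frames (statistics fitted on the supplied training
#' frames only), builds (t, t+lag) pairs within each variant, and minimizes
#' the mean squared error between the reconstruction of frame t and the
#' standardized frame t+lag. Glorot-uniform init, Leaky-ReLU activations,
#' linear latent and output layers.
#'
#' @param frames A [frame_matrix()] `frame_set` (training data, time-ordered
#'   within each variant).
#' @param q Latent dimension (must be < number of features). The published
#'   gene-specific choices were 14 (TP53-like), 8 (MLH1-like), 20 (MSH2-like).
#' @param config An [ae_config()] list.
#' @param seed Seed for initialization, shuffling and dropout.
#' @return An object of class `ae_model`: the underlying `mlp`, latent layer
#'   index, standardization parameters and config.
#' @export
train_autoencoder <- function(frames, q = 14, config = ae_config(), seed = NULL) {
  p <- ncol(frames$x)
  if (q >= p) stop_dlrpmds("latent dimension q (%d) must be < input dimension p (%d)", q, p)
  std <- standardize(frames$x)
  pairs <- lag_pairs(frames$variant_id, frames$frame_index, config$lag)
  seeds <- derive_seeds(seed, 3)
  keep <- seq_along(pairs$input)
  if (!is.null(config$max_pairs) && length(keep) > config$max_pairs)
    keep <- with_seed(seeds[[1]], sort(sample(keep, config$max_pairs)))
  X <- std$x[pairs$input[keep], , drop = FALSE]
  Y <- std$x[pairs$target[keep], , drop = FALSE]
  sizes <- c(p, config$hidden, q, rev(config$hidden), p)
  latent <- length(config$hidden) + 1L   # latent bottleneck stays linear
  net <- mlp_new(sizes, out_activation = "linear", linear_layers = latent,
                 seed = seeds[[2]])
  net <- mlp_train(net, X, Y, loss = "mse", lr = config$lr,
                   epochs = config$epochs, batch_size = config$batch_size,
                   dropout = config$dropout, val_frac = config$val_frac,
                   patience = config$patience, seed = seeds[[3]])
  structure(list(net = net, latent_layer = length(config$hidden) + 1L,
                 p = p, q = as.integer(q), std = std$params, config = config,
                 history = attr(net, "history")),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("ae_model: p = %d -> q = %d (hidden %s), %d epochs trained\n",
              x$p, x$q, paste(x$config$hidden, collapse = "/"),
              nrow(x$history)))
  invisible(x)
}

#' Encode frames into the latent space
#'
#' Deterministic forward pass through the encoder half (dropout disabled);
#' frames are standardized with the model's training statistics.
#'
#' @param model An [train_autoencoder()] model.
#' @param frames A `frame_set` or a plain matrix with `p` columns.
#' @return Matrix of latent coordinates (rows = frames, `q` columns).
#' @export
encode <- function(model, frames) {
  x <- if (inherits(frames, "frame_set")) frames$x else as.matrix(frames)
  if (ncol(x) != model$p)
    stop_dlrpmds("frames have %d features; model expects %d", ncol(x), model$p)
  x <- standardize(x, params = model$std)$x
  A <- x
  for (l in seq_len(model$latent_layer)) {
    A <- sweep(A %*% model$net$W[[l]], 2, model$net$b[[l]], "+")
    if (l < model$latent_layer) A <- lrelu(A, model$net$lrelu_slope)
  }
  A
}

#' Decode latent coordinates back to standardized frames
#'
#' @param model An `ae_model`.
#' @param h Latent matrix (`q` columns).
#' @return Reconstructed standardized frame matrix.
#' @export
decode <- function(model, h) {
  h <- as.matrix(h)
  if (ncol(h) != model$q) stop_dlrpmds("latent dimension mismatch")
  A <- h
  L <- length(model$net$W)
  for (l in (model$latent_layer + 1L):L) {
    A <- sweep(A %*% model$net$W[[l]], 2, model$net$b[[l]], "+")
    if (l < L) A <- lrelu(A, model$net$lrelu_slope)
  }
  A
}
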