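## Minimal feed-forward neural-network engine: Glorot-uniform init,
## Leaky-ReLU hidden units, optional inverted dropout, Adam, mini-batch
## training with early stopping on a validation loss. Everything is dense
## matrix arithmetic (rows = samples), which is what the autoencoder and the
## classifier need and nothing more.

#' Create a multilayer perceptron
#'
#' @param layer_sizes Integer vector of layer widths, input first, output last.
#' @param out_activation `"linear"` or `"sigmoid"` for the output layer;
#'   hidden layers are Leaky-ReLU.
#' @param lrelu_slope Negative-side slope of the Leaky-ReLU (default 0.01).
#' @param linear_layers Indices of intermediate layers whose output stays
#'   linear (no activation, no dropout) — e.g. the latent bottleneck of an
#'   autoencoder.
#' @param seed Seed for the Glorot-uniform weight initialization.
#' @return An object of class `mlp` (weights `W`, biases `b`, metadata).
#' @export
mlp_new <- function(layer_sizes, out_activation = c("linear", "sigmoid"),
                    lrelu_slope = 0.01, linear_layers = integer(0), seed = NULL) {
  out_activation <- match.arg(out_activation)
  if (length(layer_sizes) < 2) stop_dlrpmds("need at least input and output layers")
  if (any(layer_sizes < 1)) stop_dlrpmds("layer sizes must be >= 1")
  L <- length(layer_sizes) - 1L
  with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fin <- layer_sizes[l]; fout <- layer_sizes[l + 1]
      lim <- sqrt(6 / (fin + fout))          # Glorot uniform
      W[[l]] <- matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
      b[[l]] <- numeric(fout)
    }
    structure(list(W = W, b = b, sizes = as.integer(layer_sizes),
                   out_activation = out_activation,
                   lrelu_slope = lrelu_slope,
                   linear_layers = as.integer(linear_layers)),
              class = "mlp")
  })
}

lrelu <- function(z, slope) {
  neg <- z < 0
  z[neg] <- slope * z[neg]
  z
}
lrelu_grad <- function(z, slope) slope + (1 - slope) * (z > 0)
sigmoid <- function(z) 1 / (1 + exp(-z))
# fast column-wise bias add (column-major replication of b)
add_bias <- function(Z, b) Z + rep(b, rep.int(nrow(Z), length(b)))

# Forward pass. Returns activations per layer when keep = TRUE (for backprop);
# dropout masks are sampled inline (inverted dropout) on hidden layers only.
mlp_forward <- function(model, X, dropout = 0, keep = FALSE) {
  L <- length(model$W)
  A <- X
  acts <- if (keep) vector("list", L + 1)
  zs <- if (keep) vector("list", L)
  masks <- if (keep) vector("list", L)
  if (keep) acts[[1]] <- A
  for (l in seq_len(L)) {
    Z <- add_bias(A %*% model$W[[l]], model$b[[l]])
    if (l < L) {
      if (l %in% model$linear_layers) {
        A <- Z
      } else {
        A <- lrelu(Z, model$lrelu_slope)
        if (dropout > 0) {
          m <- matrix((stats::runif(length(A)) >= dropout) / (1 - dropout),
                      nrow(A), ncol(A))
          A <- A * m
          if (keep) masks[[l]] <- m
        }
      }
    } else {
      A <- switch(model$out_activation, linear = Z, sigmoid = sigmoid(Z))
    }
    if (keep) { zs[[l]] <- Z; acts[[l + 1]] <- A }
  }
  if (keep) list(out = A, acts = acts, zs = zs, masks = masks) else A
}

#' Deterministic forward pass of a trained network
#'
#' @param model An `mlp`.
#' @param X Matrix of inputs, rows = samples.
#' @return Matrix of outputs (dropout disabled).
#' @export
mlp_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$sizes[1])
    stop_dlrpmds("input has %d features; model expects %d", ncol(X), model$sizes[1])
  mlp_forward(model, X, dropout = 0, keep = FALSE)
}

# Gradient of the loss wrt the output pre-activation, per loss/output pairing.
#  mse + linear:    d = 2 (Yhat - Y) / n
#  bce + sigmoid:   d = (Yhat - Y) / n   (multi-label binary cross-entropy)
out_delta <- function(Yhat, Y, loss, n) {
  switch(loss,
         mse = 2 * (Yhat - Y) / n,
         bce = (Yhat - Y) / n)
}

loss_value <- function(Yhat, Y, loss) {
  eps <- 1e-12
  switch(loss,
         mse = mean(rowSums((Yhat - Y)^2)),
         bce = -mean(rowSums(Y * log(Yhat + eps) + (1 - Y) * log(1 - Yhat + eps))))
}

#' Train an MLP with Adam
#'
#' Mini-batch gradient descent with the Adam optimizer (lr 0.001,
#' beta1 = 0.9, beta2 = 0.999), optional inverted dropout on hidden layers,
#' and early stopping on the validation loss with a patience window. Loss is
#' `"mse"` (sum of squared errors per sample, averaged; pair with a linear
#' output) or `"bce"` (multi-label binary cross-entropy; pair with sigmoid
#' outputs).
#'
#' @param model An [mlp_new()] network.
#' @param X,Y Training inputs/targets (rows = samples).
#' @param loss `"mse"` or `"bce"`.
#' @param lr Learning rate (default 0.001).
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Mini-batch size (default 256).
#' @param dropout Hidden-layer dropout rate (default 0).
#' @param val Optional list(X, Y) used for early stopping; when `NULL` and
#'   `val_frac > 0`, a seeded fraction of the training rows is held out.
#' @param val_frac Fraction held out for validation when `val` is `NULL`
#'   (default 0.1; set 0 to disable early stopping).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param seed Seed controlling shuffling, dropout and the validation split.
#' @return The trained `mlp`, with a `history` attribute (per-epoch train and
#'   validation loss) and `best_epoch`.
#' @export
mlp_train <- function(model, X, Y, loss = c("mse", "bce"), lr = 0.001,
                      epochs = 50, batch_size = 256, dropout = 0,
                      val = NULL, val_frac = 0.1, patience = 5, seed = NULL) {
  loss <- match.arg(loss)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_dlrpmds("X and Y row mismatch")
  with_seed(seed, {
    if (is.null(val) && val_frac > 0 && nrow(X) >= 10) {
      n_val <- max(1L, round(val_frac * nrow(X)))
      idx <- sample.int(nrow(X), n_val)
      val <- list(X = X[idx, , drop = FALSE], Y = Y[idx, , drop = FALSE])
      X <- X[-idx, , drop = FALSE]; Y <- Y[-idx, , drop = FALSE]
    }
    L <- length(model$W)
    mW <- lapply(model$W, function(w) w * 0); vW <- mW
    mb <- lapply(model$b, function(bb) bb * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    n <- nrow(X)
    hist_tr <- hist_val <- numeric(0)
    best_loss <- Inf; best_model <- model; best_epoch <- 0L; wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1, n)]
        xb <- X[rows, , drop = FALSE]; yb <- Y[rows, , drop = FALSE]
        fw <- mlp_forward(model, xb, dropout = dropout, keep = TRUE)
        ep_loss <- ep_loss + loss_value(fw$out, yb, loss) * nrow(xb)
        ep_n <- ep_n + nrow(xb)
        delta <- out_delta(fw$out, yb, loss, nrow(xb))
        t <- t + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(model$W[[l]])
            if (!((l - 1) %in% model$linear_layers)) {
              delta <- delta * lrelu_grad(fw$zs[[l - 1]], model$lrelu_slope)
              if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
            }
          }
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          a_t <- lr * sqrt(1 - b2^t) / (1 - b1^t)
          model$W[[l]] <- model$W[[l]] - a_t * mW[[l]] / (sqrt(vW[[l]]) + eps)
          model$b[[l]] <- model$b[[l]] - a_t * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      # running training loss over the epoch's batches (pre-update outputs)
      hist_tr[ep] <- ep_loss / ep_n
      if (!is.null(val)) {
        hist_val[ep] <- loss_value(mlp_forward(model, val$X), val$Y, loss)
        if (hist_val[ep] < best_loss - 1e-12) {
          best_loss <- hist_val[ep]; best_model <- model
          best_epoch <- ep; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else {
        best_model <- model; best_epoch <- ep
      }
    }
    out <- best_model
    attr(out, "history") <- data.frame(
      epoch = seq_along(hist_tr), train_loss = hist_tr,
      val_loss = if (length(hist_val)) hist_val else NA_real_)
    attr(out, "best_epoch") <- best_epoch
    out
  })
}
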