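## Multi-label neural-network classifier over the latent space, per-variant
## probability aggregation, and hyperparameter tuning with the F2 objective.

#' Default classifier configuration
#'
#' One hidden layer of 1024 Leaky-ReLU neurons, no dropout, sigmoid outputs
#' for the two labels (deleterious D, unknown U), multi-label binary
#' cross-entropy, Adam with learning rate 0.001.
#'
#' @param hidden Hidden-layer widths.
#' @param dropout Dropout rate (default 0).
#' @param lr,epochs,batch_size,patience,val_frac Training controls.
#' @return A named list of settings.
#' @export
classifier_config <- function(hidden = 1024, dropout = 0, lr = 0.001,
                              epochs = 50, batch_size = 256, patience = 5,
                              val_frac = 0.1) {
  list(hidden = hidden, dropout = dropout, lr = lr, epochs = epochs,
       batch_size = batch_size, patience = patience, val_frac = val_frac)
}

# one-hot (D, U) targets from benign/pathogenic (or deleterious/unknown) labels
label_onehot <- function(labels) {
  del <- labels %in% c("pathogenic", "deleterious")
  unk <- labels %in% c("benign", "unknown")
  if (!all(del | unk)) stop_dlrpmds("unrecognized class label")
  cbind(D = as.numeric(del), U = as.numeric(unk))
}

#' Train the latent-space classifier
#'
#' Standardizes the latent inputs (statistics from the training data),
#' one-hot encodes the two labels, and trains a fully connected network with
#' sigmoid outputs. The two outputs are independent sigmoids and are not
#' renormalized to sum to 1 (set `normalize_probs = TRUE` in
#' [predict_frames()] for the renormalized convention).
#'
#' @param latents Matrix of latent vectors (rows = frames).
#' @param labels Per-row class labels; both classes must be present
#'   (benign/unknown vs pathogenic/deleterious).
#' @param config A [classifier_config()] list.
#' @param seed RNG seed.
#' @return An object of class `nn_classifier`.
#' @export
train_classifier <- function(latents, labels, config = classifier_config(),
                             seed = NULL) {
  latents <- as.matrix(latents)
  Y <- label_onehot(labels)
  if (length(unique(Y[, 1])) < 2)
    stop_dlrpmds("training set must contain both classes")
  std <- standardize(latents)
  seeds <- derive_seeds(seed, 2)
  net <- mlp_new(c(ncol(latents), config$hidden, 2L),
                 out_activation = "sigmoid", seed = seeds[[1]])
  net <- mlp_train(net, std$x, Y, loss = "bce", lr = config$lr,
                   epochs = config$epochs, batch_size = config$batch_size,
                   dropout = config$dropout, val_frac = config$val_frac,
                   patience = config$patience, seed = seeds[[2]])
  structure(list(net = net, std = std$params, q = ncol(latents),
                 config = config, history = attr(net, "history")),
            class = "nn_classifier")
}

#' @export
print.nn_classifier <- function(x, ...) {
  cat(sprintf("nn_classifier: q = %d -> hidden %s -> 2 sigmoid outputs\n",
              x$q, paste(x$config$hidden, collapse = "/")))
  invisible(x)
}

#' Per-frame classification probabilities
#'
#' Deterministic forward pass; returns one row per frame with columns
#' `p_deleterious`, `p_unknown`, each in `[0, 1]`.
#'
#' @param model A [train_classifier()] model.
#' @param latents Latent matrix with `q` columns.
#' @param normalize_probs Renormalize the two sigmoid outputs to sum to 1
#'   (default `FALSE`).
#' @return Data frame with `p_deleterious`, `p_unknown`.
#' @export
predict_frames <- function(model, latents, normalize_probs = FALSE) {
  latents <- as.matrix(latents)
  if (ncol(latents) != model$q)
    stop_dlrpmds("latents have %d dims; model expects %d", ncol(latents), model$q)
  x <- standardize(latents, params = model$std)$x
  p <- mlp_predict(model$net, x)
  if (normalize_probs) p <- p / pmax(rowSums(p), 1e-12)
  data.frame(p_deleterious = p[, 1], p_unknown = p[, 2])
}

#' Aggregate frame probabilities into a variant prediction
#'
#' Takes the mean of the per-frame probabilities over the full time series
#' and assigns the label with the highest mean probability; an exact tie goes
#' to "unknown" (conservative).
#'
#' @param frame_probs Data frame with `p_deleterious`, `p_unknown` (one row
#'   per frame; at least one).
#' @param variant_id Label carried through to the result.
#' @return An object of class `variant_prediction` with `p_deleterious`,
#'   `p_unknown`, `label`, `n_frames`.
#' @export
aggregate_variant <- function(frame_probs, variant_id = NA_character_) {
  if (!nrow(frame_probs)) stop_dlrpmds("no frames to aggregate")
  pd <- mean(frame_probs$p_deleterious)
  pu <- mean(frame_probs$p_unknown)
  structure(list(variant_id = variant_id, p_deleterious = pd, p_unknown = pu,
                 label = if (pd > pu) "deleterious" else "unknown",
                 n_frames = nrow(frame_probs)),
            class = "variant_prediction")
}

#' @export
print.variant_prediction <- function(x, ...) {
  cat(sprintf("variant %s: P(D) = %.3f, P(U) = %.3f over %d frames -> %s\n",
              x$variant_id, x$p_deleterious, x$p_unknown, x$n_frames, x$label))
  invisible(x)
}

#' Hyperparameter tuning with the F2 objective
#'
#' Exhaustive (budget-capped) search over the cartesian grid of latent
#' dimensions x hidden widths x dropout rates. For each configuration an
#' autoencoder is trained on the training frames, latents are encoded, the
#' classifier is trained (after SMOTE balancing), and the F2 score of the
#' frame-level predictions on the validation split is the objective.
#'
#' @param train,val `frame_set`s with labels; disjoint splits.
#' @param q_grid Latent dimensions to try (non-empty).
#' @param hidden_grid List of classifier hidden-size vectors.
#' @param dropout_grid Classifier dropout rates.
#' @param ae Base [ae_config()] shared by all trials.
#' @param clf Base [classifier_config()] modified per trial.
#' @param smote_k SMOTE neighbourhood size.
#' @param budget Maximum number of trials (default: whole grid).
#' @param seed RNG seed (one child seed per trial).
#' @return List with `best` (q, hidden, dropout, f2) and `trials` data frame.
#' @export
tune_hyperparameters <- function(train, val, q_grid, hidden_grid = list(1024),
                                 dropout_grid = 0, ae = ae_config(),
                                 clf = classifier_config(), smote_k = 5,
                                 budget = NULL, seed = NULL) {
  if (!length(q_grid)) stop_dlrpmds("q_grid must be non-empty")
  if (any(unlist(hidden_grid) < 1)) stop_dlrpmds("hidden sizes must be >= 1")
  grid <- expand.grid(qi = seq_along(q_grid), hi = seq_along(hidden_grid),
                      di = seq_along(dropout_grid))
  if (is.null(budget)) budget <- nrow(grid)
  if (budget < 1) stop_dlrpmds("budget must be >= 1")
  grid <- grid[seq_len(min(budget, nrow(grid))), , drop = FALSE]
  seeds <- derive_seeds(seed, nrow(grid))
  trials <- data.frame()
  for (t in seq_len(nrow(grid))) {
    q <- q_grid[grid$qi[t]]
    hidden <- hidden_grid[[grid$hi[t]]]
    dropout <- dropout_grid[grid$di[t]]
    s <- derive_seeds(seeds[[t]], 3)
    aem <- train_autoencoder(train, q = q, config = ae, seed = s[[1]])
    h_tr <- encode(aem, train)
    h_val <- encode(aem, val)
    bal <- smote_oversample(h_tr, train$label, k_neighbors = smote_k, seed = s[[2]])
    cc <- clf; cc$hidden <- hidden; cc$dropout <- dropout
    cm <- train_classifier(bal$x, bal$labels, config = cc, seed = s[[3]])
    probs <- predict_frames(cm, h_val)
    preds <- ifelse(probs$p_deleterious > probs$p_unknown, "deleterious", "unknown")
    f2 <- f2_score(confusion(preds, val$label))
    trials <- rbind(trials, data.frame(trial = t, q = q,
                                       hidden = paste(hidden, collapse = "x"),
                                       dropout = dropout, f2 = f2))
  }
  best <- trials[which.max(trials$f2), ]
  list(best = list(q = best$q, hidden = hidden_grid[[grid$hi[best$trial]]],
                   dropout = best$dropout, f2 = best$f2),
       trials = trials)
}
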