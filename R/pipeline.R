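## End-to-end DL pipeline: standardized frames -> time-lagged AE -> latent
## SMOTE balancing -> neural classifier -> per-frame and per-variant calls.

#' Fit the full DL classification pipeline
#'
#' Trains the time-lagged autoencoder on the (labelled) training frames,
#' encodes them, balances the two classes in latent space with SMOTE, and
#' trains the classifier. SMOTE touches only the training data.
#'
#' @param train A labelled `frame_set` (labels benign/pathogenic), time-ordered
#'   within each variant.
#' @param q Latent dimension.
#' @param ae An [ae_config()].
#' @param clf A [classifier_config()].
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @param seed RNG seed.
#' @return An object of class `dlrpmds_model` (`ae`, `clf`).
#' @export
fit_dlrpmds <- function(train, q = 14, ae = ae_config(),
                        clf = classifier_config(), smote_k = 5, seed = NULL) {
  lab <- train$label
  if (any(is.na(lab))) stop_dlrpmds("training frames must be labelled")
  seeds <- derive_seeds(seed, 3)
  aem <- train_autoencoder(train, q = q, config = ae, seed = seeds[[1]])
  h <- encode(aem, train)
  bal <- smote_oversample(h, lab, k_neighbors = smote_k, seed = seeds[[2]])
  cm <- train_classifier(bal$x, bal$labels, config = clf, seed = seeds[[3]])
  structure(list(ae = aem, clf = cm, q = q), class = "dlrpmds_model")
}

#' @export
print.dlrpmds_model <- function(x, ...) {
  cat(sprintf("dlrpmds_model: p = %d, q = %d, classifier hidden %s\n",
              x$ae$p, x$q, paste(x$clf$config$hidden, collapse = "/")))
  invisible(x)
}

#' Per-frame and per-variant predictions from a fitted pipeline
#'
#' @param model A [fit_dlrpmds()] model.
#' @param frames A `frame_set`.
#' @param normalize_probs See [predict_frames()].
#' @return List with `frames` (per-frame probabilities plus variant ids) and
#'   `variants` (data frame: variant_id, p_deleterious, p_unknown, label,
#'   n_frames).
#' @export
predict_dlrpmds <- function(model, frames, normalize_probs = FALSE) {
  h <- encode(model$ae, frames)
  probs <- predict_frames(model$clf, h, normalize_probs = normalize_probs)
  probs$variant_id <- frames$variant_id
  vids <- unique(frames$variant_id)
  agg <- lapply(vids, function(v)
    aggregate_variant(probs[probs$variant_id == v, c("p_deleterious", "p_unknown")], v))
  variants <- data.frame(
    variant_id = vids,
    p_deleterious = vapply(agg, `[[`, numeric(1), "p_deleterious"),
    p_unknown = vapply(agg, `[[`, numeric(1), "p_unknown"),
    label = vapply(agg, `[[`, character(1), "label"),
    n_frames = vapply(agg, `[[`, integer(1), "n_frames"))
  list(frames = probs, variants = variants)
}
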