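## Stratified 4-fold x 5-repeat cross-validation driver for both methods
## (RP-MDS deviation scoring and the DL pipeline) and both grouping
## strategies (by variant: all 334 frames of a variant travel together;
## by frame: each frame is an independent sample).

#' Stratified fold assignment
#'
#' Seeded random permutation, then round-robin assignment within each class,
#' so per-fold class proportions are within one sample of the global ones.
#'
#' @param labels Class label per item.
#' @param folds Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id (1..folds) per item.
#' @export
stratified_folds <- function(labels, folds, seed = NULL) {
  n <- length(labels)
  for (cl in unique(labels))
    if (sum(labels == cl) < folds)
      stop_dlrpmds("class '%s' has %d members; cannot stratify into %d folds",
                   cl, sum(labels == cl), folds)
  with_seed(seed, {
    perm <- sample.int(n)
    fold <- integer(n)
    for (cl in unique(labels)) {
      rows <- perm[labels[perm] == cl]
      fold[rows] <- rep_len(seq_len(folds), length(rows))
    }
    fold
  })
}

#' Cross-validation configuration for the two methods
#'
#' @param window Analysis window in ps (half-open), default last 10 ns of a
#'   40 ns run.
#' @param q Latent dimension for the DL pipeline.
#' @param ae,clf [ae_config()] / [classifier_config()] for the DL pipeline.
#' @param smote_k SMOTE neighbourhood size.
#' @param k_sd,transform Deviation-score settings for RP-MDS.
#' @param bandwidth KDE bandwidth for RP-MDS grids.
#' @param roc_bin Cut-off sweep step for RP-MDS ROC curves.
#' @return A named list of settings.
#' @export
cv_config <- function(window = c(30000, 40000), q = 14, ae = ae_config(),
                      clf = classifier_config(), smote_k = 5, k_sd = 1,
                      transform = "log_count", bandwidth = "auto",
                      roc_bin = 0.01) {
  list(window = window, q = q, ae = ae, clf = clf, smote_k = smote_k,
       k_sd = k_sd, transform = transform, bandwidth = bandwidth,
       roc_bin = roc_bin)
}

#' Stratified cross-validated evaluation
#'
#' Runs `folds x repeats` models (default 4 x 5 = 20). Per repeat, items are
#' randomly permuted (seeded) and split into stratified folds; each fold
#' serves once as the test set. For `method = "rpmds"` the reference model is
#' rebuilt per model from the training-fold benign variants (plus any
#' wildtype entries), deviation scores are recomputed for every variant, and
#' ROC curves come from the cut-off sweep. For `method = "dlrpmds"` the
#' autoencoder, SMOTE balancing and classifier are refit per model on the
#' training split only; `grouping` chooses whether a variant's frames stay
#' together (`"by_variant"`) or are split independently (`"by_frame"`).
#'
#' @param dataset List with `manifest` (a [variant_manifest()]) and
#'   `trajectories` (named list of [torsion_trajectory()]s), e.g. from
#'   [make_dataset()].
#' @param folds,repeats Cross-validation layout (defaults 4 and 5).
#' @param grouping `"by_variant"` or `"by_frame"` (DL method only;
#'   RP-MDS scores are per-variant by construction).
#' @param method `"rpmds"` or `"dlrpmds"`.
#' @param seed Master seed; each repeat gets a derived child seed.
#' @param config A [cv_config()].
#' @return An object of class `cv_report`: per-model metrics (`models`),
#'   fold assignments, aggregate `summary`, and per-model ROC points.
#' @export
stratified_cv <- function(dataset, folds = 4, repeats = 5,
                          grouping = c("by_variant", "by_frame"),
                          method = c("rpmds", "dlrpmds"),
                          seed = NULL, config = cv_config()) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  manifest <- dataset$manifest
  labelled <- manifest[manifest$class_label %in% c("benign", "pathogenic"), ]
  if (!nrow(labelled)) stop_dlrpmds("no labelled variants in dataset")
  win <- lapply(dataset$trajectories, select_window,
                start_ps = config$window[1], end_ps = config$window[2])
  rep_seeds <- derive_seeds(seed, repeats)
  models <- data.frame()
  rocs <- list()
  assignments <- list()

  if (method == "rpmds") {
    grids <- lapply(win[labelled$variant_id], variant_rdp,
                    bandwidth = config$bandwidth)
    wt_ids <- manifest$variant_id[manifest$class_label == "wt"]
    wt_grids <- lapply(win[wt_ids], variant_rdp, bandwidth = config$bandwidth)
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(labelled$class_label, folds, rep_seeds[[r]])
      assignments[[r]] <- stats::setNames(fold, labelled$variant_id)
      for (k in seq_len(folds)) {
        train <- fold != k
        ref <- build_reference(c(wt_grids,
                                 grids[train & labelled$class_label == "benign"]))
        scores <- vapply(grids, function(g)
          deviation_score(g, ref, k_sd = config$k_sd,
                          transform = config$transform)$score, numeric(1))
        ben <- labelled$class_label == "benign"
        roc_tr <- roc_by_cutoff(scores[train & ben], scores[train & !ben],
                                bin = config$roc_bin)
        roc_te <- roc_by_cutoff(scores[!train & ben], scores[!train & !ben],
                                bin = config$roc_bin)
        cut <- optimize_cutoff(scores[train & ben], scores[train & !ben],
                               range = range(scores) + c(-0.01, 0.01),
                               bin = config$roc_bin)
        preds <- classify_rpmds(scores[!train], cut$cutoff)
        ba <- balanced_accuracy_counts(confusion(preds, labelled$class_label[!train]))
        m <- data.frame(repeat_id = r, fold = k,
                        auc_train = roc_tr$auc, auc_test = roc_te$auc,
                        ba_test = ba, n_train = sum(train), n_test = sum(!train))
        models <- rbind(models, m)
        rocs[[length(rocs) + 1]] <- list(repeat_id = r, fold = k,
                                         train = roc_tr$points, test = roc_te$points)
      }
    }
  } else {
    fs <- frame_matrix(win[labelled$variant_id], manifest = labelled)
    model_seeds <- derive_seeds(seed, repeats * folds + repeats)
    for (r in seq_len(repeats)) {
      if (grouping == "by_variant") {
        vfold <- stratified_folds(labelled$class_label, folds, rep_seeds[[r]])
        fold <- vfold[match(fs$variant_id, labelled$variant_id)]
        assignments[[r]] <- stats::setNames(vfold, labelled$variant_id)
      } else {
        fold <- stratified_folds(fs$label, folds, rep_seeds[[r]])
        assignments[[r]] <- fold
      }
      for (k in seq_len(folds)) {
        train <- fold != k
        fit_seed <- model_seeds[[(r - 1) * folds + k]]
        mdl <- fit_dlrpmds(frame_subset(fs, which(train)), q = config$q,
                           ae = config$ae, clf = config$clf,
                           smote_k = config$smote_k, seed = fit_seed)
        pr_tr <- predict_dlrpmds(mdl, frame_subset(fs, which(train)))
        pr_te <- predict_dlrpmds(mdl, frame_subset(fs, which(!train)))
        lab_tr <- fs$label[train]; lab_te <- fs$label[!train]
        roc_tr <- roc_auc_probabilistic(pr_tr$frames$p_deleterious, lab_tr)
        roc_te <- roc_auc_probabilistic(pr_te$frames$p_deleterious, lab_te)
        vl <- pr_te$variants
        vtruth <- labelled$class_label[match(vl$variant_id, labelled$variant_id)]
        ba <- if (length(unique(vtruth)) == 2)
          balanced_accuracy_counts(confusion(vl$label, vtruth)) else NA_real_
        m <- data.frame(repeat_id = r, fold = k,
                        auc_train = roc_tr$auc, auc_test = roc_te$auc,
                        ba_test = ba, n_train = sum(train), n_test = sum(!train))
        models <- rbind(models, m)
        rocs[[length(rocs) + 1]] <- list(repeat_id = r, fold = k,
                                         train = roc_tr$points, test = roc_te$points)
      }
    }
  }
  structure(list(method = method, grouping = grouping,
                 folds = folds, repeats = repeats,
                 n_models = nrow(models), models = models,
                 assignments = assignments, rocs = rocs,
                 summary = data.frame(
                   metric = c("auc_train", "auc_test", "ba_test"),
                   mean = c(mean(models$auc_train), mean(models$auc_test),
                            mean(models$ba_test, na.rm = TRUE)),
                   sd = c(stats::sd(models$auc_train), stats::sd(models$auc_test),
                          stats::sd(models$ba_test, na.rm = TRUE)))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s, %s, %d folds x %d repeats = %d models\n",
              x$method, x$grouping, x$folds, x$repeats, x$n_models))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Mean ROC curve across CV models (vertical averaging)
#'
#' Interpolates every model's test (or train) ROC onto a fixed FPR grid and
#' averages the TPR values — the standard way to draw one averaged curve for
#' the 20 models.
#'
#' @param report A [stratified_cv()] report.
#' @param which `"test"` or `"train"`.
#' @param fpr_grid FPR grid (default 101 points).
#' @return Data frame with `fpr` and mean `tpr`.
#' @export
average_roc <- function(report, which = c("test", "train"),
                        fpr_grid = seq(0, 1, length.out = 101)) {
  which <- match.arg(which)
  tprs <- vapply(report$rocs, function(r) {
    pts <- r[[which]]
    o <- order(pts$fpr, pts$tpr)
    stats::approx(c(0, pts$fpr[o], 1), c(0, pts$tpr[o], 1),
                  xout = fpr_grid, ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  data.frame(fpr = fpr_grid, tpr = rowMeans(tprs))
}

#' Write a CV report to disk
#'
#' JSON summary plus a CSV of per-model metrics and one CSV of ROC points per
#' model.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(method = report$method, grouping = report$grouping,
         folds = report$folds, repeats = report$repeats,
         n_models = report$n_models, summary = report$summary),
    file.path(dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$models, file.path(dir, "cv_models.csv"),
                   row.names = FALSE)
  for (rc in report$rocs) {
    for (w in c("train", "test")) {
      f <- sprintf("roc_r%d_f%d_%s.csv", rc$repeat_id, rc$fold, w)
      utils::write.csv(rc[[w]], file.path(dir, f), row.names = FALSE)
    }
  }
  invisible(dir)
}
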