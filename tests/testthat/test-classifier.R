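test_that("configuration defaults follow the published architecture", {
  ae <- ae_config()
  expect_equal(ae$hidden, c(1000, 1000))
  expect_equal(ae$dropout, 0.1)
  expect_equal(ae$lr, 0.001)
  expect_identical(ae$lag, 1L)
  clf <- classifier_config()
  expect_equal(clf$hidden, 1024)
  expect_equal(clf$dropout, 0)
  expect_equal(clf$lr, 0.001)
})

test_that("label_onehot maps both label vocabularies onto (D, U)", {
  Y <- dlrpmds:::label_onehot(c("pathogenic", "benign", "deleterious", "unknown"))
  expect_equal(Y[, "D"], c(1, 0, 1, 0))
  expect_equal(Y[, "U"], c(0, 1, 0, 1))
  expect_error(dlrpmds:::label_onehot("other"), "unrecognized")
})

test_that("the classifier learns separable latents and predicts in [0, 1]", {
  set.seed(70)
  h <- rbind(matrix(rnorm(150 * 3, -1.5), 150, 3),
             matrix(rnorm(150 * 3, 1.5), 150, 3))
  labels <- rep(c("benign", "pathogenic"), each = 150)
  cm <- train_classifier(h, labels, config = test_clf(epochs = 30), seed = 71)
  expect_s3_class(cm, "nn_classifier")
  probs <- predict_frames(cm, h)
  expect_named(probs, c("p_deleterious", "p_unknown"))
  expect_true(all(probs >= 0 & probs <= 1))
  preds <- ifelse(probs$p_deleterious > probs$p_unknown, "deleterious", "unknown")
  expect_gte(mean((preds == "deleterious") == (labels == "pathogenic")), 0.98)
  pn <- predict_frames(cm, h, normalize_probs = TRUE)
  expect_equal(pn$p_deleterious + pn$p_unknown, rep(1, 300), tolerance = 1e-9)
  expect_error(train_classifier(h, rep("benign", 300)), "both classes")
})

test_that("aggregate_variant takes the mean and breaks ties to unknown", {
  fp <- data.frame(p_deleterious = c(0.9, 0.6, 0.6), p_unknown = c(0.2, 0.1, 0.3))
  v <- aggregate_variant(fp, "V1")
  expect_equal(v$p_deleterious, 0.7)
  expect_equal(v$p_unknown, 0.2)
  expect_identical(v$label, "deleterious")
  expect_identical(v$n_frames, 3L)
  low <- aggregate_variant(data.frame(p_deleterious = 0.2, p_unknown = 0.8), "V2")
  expect_identical(low$label, "unknown")
  tie <- aggregate_variant(data.frame(p_deleterious = 0.5, p_unknown = 0.5), "V3")
  expect_identical(tie$label, "unknown")
  expect_error(aggregate_variant(fp[0, ]), "no frames")
})

test_that("the end-to-end pipeline separates the synthetic classes", {
  ds <- small_dataset(seed = 4, n_benign = 4, n_pathogenic = 6, n_wt = 0,
                      n_residues = 16, n_frames = 100)
  fs <- frame_matrix(ds$trajectories, manifest = ds$manifest)
  mdl <- fit_dlrpmds(fs, q = 4, ae = test_ae(epochs = 30),
                     clf = test_clf(epochs = 30), smote_k = 3, seed = 80)
  pred <- predict_dlrpmds(mdl, fs)
  expect_identical(nrow(pred$frames), nrow(fs$x))
  expect_identical(nrow(pred$variants), 10L)
  truth <- ds$manifest$class_label[match(pred$variants$variant_id,
                                         ds$manifest$variant_id)]
  ba <- dlrpmds:::balanced_accuracy_counts(confusion(pred$variants$label, truth))
  expect_gte(ba, 0.9)
  # per-variant probability is the mean of that variant's frame probabilities
  v1 <- pred$variants$variant_id[1]
  expect_equal(pred$variants$p_deleterious[1],
               mean(pred$frames$p_deleterious[pred$frames$variant_id == v1]),
               tolerance = 1e-12)
})

test_that("prediction on held-out frames uses exactly the supplied rows", {
  ds <- small_dataset(seed = 5, n_benign = 4, n_pathogenic = 4, n_wt = 0,
                      n_residues = 10, n_frames = 60)
  fs <- frame_matrix(ds$trajectories, manifest = ds$manifest)
  rows_tr <- which(fs$frame_index <= 45)
  rows_te <- which(fs$frame_index > 45)
  tr <- dlrpmds:::frame_subset(fs, rows_tr)
  te <- dlrpmds:::frame_subset(fs, rows_te)
  mdl <- fit_dlrpmds(tr, q = 3, ae = test_ae(), clf = test_clf(),
                     smote_k = 3, seed = 81)
  pr <- predict_dlrpmds(mdl, te)
  # SMOTE balancing never inflates the evaluation set: one row per test frame
  expect_identical(nrow(pr$frames), length(rows_te))
  expect_identical(pr$frames$variant_id, te$variant_id)
  expect_identical(sum(pr$variants$n_frames), length(rows_te))
})

test_that("tune_hyperparameters ranks configurations by validation F2", {
  ds <- small_dataset(seed = 6, n_benign = 4, n_pathogenic = 4, n_wt = 0,
                      n_residues = 10, n_frames = 60)
  fs <- frame_matrix(ds$trajectories, manifest = ds$manifest)
  tr <- dlrpmds:::frame_subset(fs, which(fs$frame_index <= 45))
  val <- dlrpmds:::frame_subset(fs, which(fs$frame_index > 45))
  res <- tune_hyperparameters(tr, val, q_grid = c(2, 4),
                              hidden_grid = list(16), dropout_grid = 0,
                              ae = test_ae(epochs = 4),
                              clf = test_clf(epochs = 4),
                              smote_k = 3, seed = 82)
  expect_identical(nrow(res$trials), 2L)
  expect_true(all(res$trials$f2 >= 0 & res$trials$f2 <= 1))
  expect_equal(res$best$f2, max(res$trials$f2))
  expect_true(res$best$q %in% c(2, 4))
  # budget caps the grid
  res1 <- tune_hyperparameters(tr, val, q_grid = c(2, 4),
                               hidden_grid = list(16), dropout_grid = 0,
                               ae = test_ae(epochs = 4),
                               clf = test_clf(epochs = 4),
                               smote_k = 3, budget = 1, seed = 82)
  expect_identical(nrow(res1$trials), 1L)
  expect_error(tune_hyperparameters(tr, val, q_grid = integer(0)), "non-empty")
})
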