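test_that("metrics match exhaustive hand computation on a fixed fixture", {
  truth <- factor(c("DU", "DU", "DU", "DU", "DU",
                    "DI", "DI", "DI", "DI", "DI"),
                  levels = c("DU", "DI"))
  pred <- factor(c("DU", "DU", "DI", "DU", "DI",
                   "DI", "DI", "DU", "DI", "DI"),
                 levels = c("DU", "DI"))
  s_du <- c(0.9, 0.8, 0.4, 0.7, 0.45, 0.2, 0.1, 0.6, 0.3, 0.45)
  scores <- cbind(DU = s_du, DI = 1 - s_du)
  rep <- evaluate_predictions(truth, pred, scores)
  # confusion: TP=3 FN=2 FP=1 TN=4, enumerated by hand
  expect_equal(unname(as.vector(rep$confusion)), c(3, 1, 2, 4))
  expect_equal(rep$accuracy, 7 / 10)
  cm <- rep$class_metrics
  expect_equal(cm$precision[cm$class == "DU"], 3 / 4)
  expect_equal(cm$recall[cm$class == "DU"], 3 / 5)
  expect_equal(cm$precision[cm$class == "DI"], 4 / 6)
  expect_equal(cm$recall[cm$class == "DI"], 4 / 5)
  # AUROC against pairwise enumeration (includes one tie at 0.45)
  expect_equal(cm$auroc[cm$class == "DU"],
               auroc_naive(as.integer(truth == "DU"), s_du))
  expect_equal(cm$auroc[cm$class == "DI"],
               auroc_naive(as.integer(truth == "DI"), 1 - s_du))
})

test_that("AUROC extremes are 1 for the label indicator and 0 for its flip", {
  truth <- factor(rep(c("DU", "DI"), each = 4), levels = c("DU", "DI"))
  ind <- as.integer(truth == "DU")
  scores <- cbind(DU = ind, DI = 1 - ind)
  rep <- evaluate_predictions(truth, truth, scores)
  expect_equal(rep$class_metrics$auroc, c(1, 1))
  anti <- cbind(DU = 1 - ind, DI = ind)
  rep2 <- evaluate_predictions(truth, truth, anti)
  expect_equal(rep2$class_metrics$auroc, c(0, 0))
})

test_that("cross-validation pools folds into consistent reports", {
  feats <- separable_200()$features
  rep <- cross_validate(feats, "decision_tree", "binary", "All",
                        k = 10, seed = 2)
  expect_equal(sum(rep$confusion), 200)
  expect_equal(unname(rowSums(rep$confusion)),
               as.numeric(table(feats$label)[rownames(rep$confusion)]))
  expect_gte(rep$accuracy, 0.99)
  expect_identical(rep$metadata$k, 10L)
  expect_true(nzchar(rep$metadata$config_hash))
  expect_length(rep$metadata$folds, 200)
  # stratified folds balance both classes
  tab <- table(rep$metadata$folds, feats$label)
  expect_true(all(tab == 10))
})

test_that("cross-validation guards its preconditions", {
  feats <- separable_200()$features
  both <- feats[c(1:3, 198:200), ]   # three of each class, n < k
  expect_error(cross_validate(both, "decision_tree", "binary",
                              "All", k = 10), "fewer observations")
  one <- feats[feats$label == "DU", ]
  expect_error(cross_validate(one, "decision_tree", "binary", "All", k = 5),
               "two classes")
})

test_that("rare multiclass strata fall back to unstratified folds", {
  y <- factor(c(rep("EF", 30), rep("DI", 30), rep("NS", 3)))
  expect_warning(f <- make_folds(y, k = 10, seed = 1), "non-stratified")
  expect_length(f, 63)
  expect_identical(sort(unique(f)), 1:10)
})

test_that("learning curve fractions ascend geometrically to exactly 100%", {
  feats <- separable_200()$features
  lc <- learning_curve(feats, "decision_tree", "All", growth_factor = 4,
                       repeats = 5, k = 5, seed = 3)
  fr <- unique(lc$points$fraction)
  expect_true(all(diff(fr) > 0))
  expect_identical(fr[1], 0.01)
  expect_identical(fr[length(fr)], 1)
  expect_true(all(fr[-length(fr)] == 0.01 * 4^(seq_along(fr[-length(fr)]) - 1)))
  expect_true(all(table(lc$points$fraction) == 5))
  expect_named(lc$points,
               c("fraction", "rep", "n_train", "accuracy", "precision_DU",
                 "recall_DU", "precision_DI", "recall_DI"))
  expect_error(learning_curve(feats, growth_factor = 1), "growth_factor")
})

test_that("ablation shares folds across the six feature sets", {
  feats <- separable_200()$features
  ab <- ablate(feats, "decision_tree", k = 5, seed = 8)
  expect_named(ab$reports, c("Meta", "Seq", "SQ", "SQC", "SQM", "All"))
  folds <- lapply(ab$reports, function(r) r$metadata$folds)
  for (f in folds[-1]) expect_identical(f, folds[[1]])
  expect_identical(ab$summary$feature_set,
                   c("Meta", "Seq", "SQ", "SQC", "SQM", "All"))
  expect_true(all(ab$summary$avg_precision >= 0 &
                  ab$summary$avg_precision <= 1))
  # the Seq report is built from a two-feature model
  expect_identical(ab$reports$Seq$metadata$feature_set, "Seq")
  expect_length(feature_set_names("Seq"), 2)
})

test_that("error profiles average only present feature values", {
  feats <- tibble::tibble(
    identity = c(0.9, 1.0, NA, 0.5),
    ap = c(0.2, NA, 0.4, 0.6))
  for (cc in setdiff(seqdedup:::NUMERIC_FEATURES, names(feats)))
    feats[[cc]] <- NA_real_
  truth <- c("DI", "DI", "DI", "DU")
  pred <- c("DU", "DU", "DU", "DU")   # three FPs, zero FNs
  ep <- error_profile(truth, pred, feats)
  expect_identical(unname(ep$counts), c(3L, 0L))
  tab <- ep$table
  expect_equal(tab$fp_mean[tab$feature == "identity"], 0.95)
  expect_identical(tab$fp_n[tab$feature == "identity"], 2)
  expect_equal(tab$fp_mean[tab$feature == "ap"], 0.3)
  expect_true(all(is.na(tab$fn_mean)))
  expect_true(all(tab$fn_n == 0))
})

test_that("relative type accuracy credits any duplicate-subtype prediction", {
  truth_bin <- c("DU", "DU", "DU", "DI", "DI")
  truth_sub <- c("EF", "EF", "NS", NA, NA)
  bin_pred <- c("DU", "DI", "DU", "DI", "DU")
  mul_pred <- c("ES", "DI", "NS", "NS", "DI")
  out <- relative_type_accuracy(bin_pred, mul_pred, truth_bin, truth_sub)
  # EF: binary 1/2; multiclass credits the ES prediction -> 1/2
  expect_equal(out$binary_accuracy[out$class == "EF"], 0.5)
  expect_equal(out$multi_accuracy[out$class == "EF"], 0.5)
  # NS duplicate predicted NS -> correct under both
  expect_equal(out$multi_accuracy[out$class == "NS"], 1)
  # DI predicted NS is wrong for the multiclass model
  expect_equal(out$multi_accuracy[out$class == "DI"], 0.5)
  expect_equal(out$binary_accuracy[out$class == "DI"], 0.5)
  expect_identical(out$n, c(2L, 0L, 1L, 2L))
})

test_that("cross-dataset evaluation requires disjoint datasets", {
  feats <- separable_200()$features
  expect_error(cross_dataset(feats, feats), "identical")
  odd <- seq(1, nrow(feats), by = 2)   # interleave so both halves see
  rep <- cross_dataset(feats[odd, ], feats[-odd, ],  # both classes
                       "decision_tree", "binary", "All", seed = 1)
  expect_gte(rep$accuracy, 0.9)
})

test_that("reports serialize to JSON with confusion and metadata", {
  feats <- separable_200()$features
  rep <- cross_validate(feats, "decision_tree", "binary", "Seq", k = 5,
                        seed = 1)
  f <- tempfile(fileext = ".json")
  report_to_json(rep, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$accuracy, rep$accuracy)
  expect_identical(back$metadata$feature_set, "Seq")
  expect_identical(back$confusion$classes, c("DU", "DI"))
  expect_equal(sum(back$confusion$matrix), 200)
})
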