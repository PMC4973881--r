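# ---------------------------------------------------------------------------
# Experimental protocols: stratified k-fold cross-validation with pooled
# (micro) metrics, learning curves with repeated seeded subsampling,
# feature-set ablation on shared folds, error profiling, binary-versus-
# multi-class relative accuracy, and cross-dataset generalisation.
# ---------------------------------------------------------------------------

#' Stratified fold assignment
#'
#' @param y Label factor/vector.
#' @param k Number of folds.
#' @param seed Seed.
#' @param stratified Stratify by class (default). In multi-class mode a
#'   class with fewer than `k` members triggers a warning and a
#'   non-stratified fallback.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(y)
  if (n < k) stop("make_folds: fewer observations (", n, ") than folds (",
                  k, ")", call. = FALSE)
  set.seed(seed)
  folds <- integer(n)
  if (stratified && min(table(y)) < k) {
    warning("class with fewer than k members; falling back to ",
            "non-stratified folds", call. = FALSE)
    stratified <- FALSE
  }
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}

safe_auroc <- function(truth01, score) {
  if (length(unique(truth01)) < 2L) return(NA_real_)
  r <- pROC::roc(response = truth01, predictor = score, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

new_evaluation_report <- function(truth, pred, scores, metadata = list()) {
  cls <- levels(truth)
  confusion <- table(truth = truth, predicted = factor(pred, levels = cls))
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- lapply(cls, function(cl) {
    tp <- confusion[cl, cl]
    prec <- if (sum(confusion[, cl]) > 0) tp / sum(confusion[, cl]) else NA_real_
    rec <- if (sum(confusion[cl, ]) > 0) tp / sum(confusion[cl, ]) else NA_real_
    auc <- if (!is.null(scores)) safe_auroc(as.integer(truth == cl),
                                            scores[, cl]) else NA_real_
    tibble::tibble(class = cl, precision = prec, recall = rec, auroc = auc,
                   n = sum(confusion[cl, ]))
  })
  structure(list(class_metrics = dplyr::bind_rows(per_class),
                 accuracy = acc, confusion = confusion,
                 n = length(truth), metadata = metadata),
            class = "evaluation_report")
}

#' Evaluate a set of predictions
#'
#' Builds an `evaluation_report` (per-class precision, recall, one-vs-rest
#' AUROC, overall accuracy, confusion matrix) from true labels, predicted
#' labels and optional per-class scores.
#'
#' @param truth Factor of true labels (its levels define the classes).
#' @param predicted Predicted labels.
#' @param scores Optional numeric matrix of per-class scores (columns named
#'   by class) for AUROC.
#' @param metadata Optional experiment metadata list.
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(truth, predicted, scores = NULL,
                                 metadata = list()) {
  if (!is.factor(truth)) truth <- factor(truth)
  new_evaluation_report(truth, predicted, scores, metadata)
}

#' @export
print.evaluation_report <- function(x, ...) {
  md <- x$metadata
  cat("<evaluation_report>",
      paste(unlist(md[intersect(c("algorithm", "mode", "feature_set"),
                                names(md))]), collapse = " | "), "\n")
  cat("  accuracy:", sprintf("%.4f", x$accuracy), " n:", x$n, "\n")
  print(as.data.frame(x$class_metrics), row.names = FALSE, digits = 4)
  invisible(x)
}

config_hash <- function(cfg) rlang::hash(cfg)

#' k-fold cross-validation of a duplicate classifier
#'
#' Stratified, seeded folds; per-class precision/recall and one-vs-rest
#' AUROC are computed from the pooled out-of-fold predictions (micro
#' pooling: one confusion matrix over all folds).
#'
#' @param features Labelled feature tibble ([compute_feature_matrix()] plus
#'   `label`, and `subtype` for multi-class).
#' @param algorithm,mode,feature_set Passed to [encode_pairs()] and
#'   [train_model()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and training.
#' @param folds Optional externally supplied fold vector (used by
#'   [ablate()] to share folds across feature sets).
#' @return An `evaluation_report`; the fold assignment is carried in
#'   `metadata$folds`.
#' @export
cross_validate <- function(features, algorithm = "decision_tree",
                           mode = c("binary", "multiclass"),
                           feature_set = "All", k = 10L, seed = 1L,
                           folds = NULL) {
  mode <- match.arg(mode)
  enc_all <- encode_pairs(features, feature_set, mode)
  y <- enc_all$y
  if (nlevels(y) < 2L) stop("cross_validate: need at least two classes")
  if (is.null(folds))
    folds <- make_folds(y, k = k, seed = seed,
                        stratified = TRUE)
  k <- max(folds)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  scores <- matrix(NA_real_, length(y), nlevels(y),
                   dimnames = list(NULL, levels(y)))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    enc_tr <- structure(list(x = enc_all$x[tr, , drop = FALSE], y = y[tr],
                             feature_set = feature_set, mode = mode,
                             evalue_cap = enc_all$evalue_cap),
                        class = "encoded_pairs")
    enc_te <- structure(list(x = enc_all$x[te, , drop = FALSE], y = y[te],
                             feature_set = feature_set, mode = mode,
                             evalue_cap = enc_all$evalue_cap),
                        class = "encoded_pairs")
    model <- train_model(enc_tr, algorithm, seed = seed + f)
    p <- predict(model, enc_te)
    pred[te] <- p$labels
    scores[te, colnames(p$scores)] <- p$scores
  }
  cfg <- list(algorithm = algorithm, mode = mode, feature_set = feature_set,
              k = k, seed = seed)
  new_evaluation_report(y, pred, scores,
                        metadata = c(cfg, list(folds = folds,
                                               config_hash = config_hash(cfg))))
}

#' Learning curve with repeated seeded subsampling
#'
#' Training fractions ascend geometrically from `min_fraction` by
#' `growth_factor` and terminate at exactly 100%. For each fraction and
#' each of `repeats` repeats, one cross-validation fold is held out, the
#' complementary training split is subsampled at the fraction, a model is
#' trained, and accuracy plus per-class precision/recall for `DU` and `DI`
#' are recorded on the held-out fold. Each repeat uses a distinct derived
#' seed; a subsample with fewer than two classes is redrawn (bounded
#' retries), then skipped with a warning.
#'
#' @param features Labelled feature tibble (binary labels).
#' @param algorithm,feature_set Model configuration.
#' @param growth_factor Multiplicative step between fractions (> 1).
#' @param repeats Repeats per fraction (default 20).
#' @param k Number of folds used for the held-out test splits.
#' @param seed Base seed.
#' @param min_fraction Starting fraction (default 0.01).
#' @return Object of class `learning_curve`: list with `points` (one row
#'   per fraction x repeat) and `summary` (mean and sd per fraction).
#' @export
learning_curve <- function(features, algorithm = "decision_tree",
                           feature_set = "All", growth_factor = 1.05,
                           repeats = 20L, k = 10L, seed = 1L,
                           min_fraction = 0.01) {
  if (growth_factor <= 1) stop("learning_curve: growth_factor must be > 1")
  fracs <- min_fraction * growth_factor^(0:ceiling(
    log(1 / min_fraction) / log(growth_factor)))
  fracs <- c(fracs[fracs < 1], 1)
  enc_all <- encode_pairs(features, feature_set, "binary")
  y <- enc_all$y
  folds <- make_folds(y, k = k, seed = seed)
  rows <- list()
  for (fi in seq_along(fracs)) {
    frac <- fracs[fi]
    for (r in seq_len(repeats)) {
      rep_seed <- seed + 1000L * fi + r
      fold <- ((r - 1L) %% k) + 1L
      tr_pool <- which(folds != fold); te <- which(folds == fold)
      m <- max(2L, round(frac * length(tr_pool)))
      set.seed(rep_seed)
      tr <- NULL
      for (try in 1:20) {
        cand <- sample(tr_pool, m)
        if (nlevels(droplevels(y[cand])) >= 2L) { tr <- cand; break }
      }
      if (is.null(tr)) {
        warning("learning_curve: subsample at fraction ", signif(frac, 3),
                " produced a single class; repeat skipped", call. = FALSE)
        next
      }
      enc_tr <- structure(list(x = enc_all$x[tr, , drop = FALSE], y = y[tr],
                               feature_set = feature_set, mode = "binary",
                               evalue_cap = enc_all$evalue_cap),
                          class = "encoded_pairs")
      enc_te <- structure(list(x = enc_all$x[te, , drop = FALSE], y = y[te],
                               feature_set = feature_set, mode = "binary",
                               evalue_cap = enc_all$evalue_cap),
                          class = "encoded_pairs")
      model <- train_model(enc_tr, algorithm, seed = rep_seed)
      p <- predict(model, enc_te)
      rep_report <- new_evaluation_report(y[te], p$labels, p$scores)
      cm <- rep_report$class_metrics
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fraction = frac, rep = r, n_train = m,
        accuracy = rep_report$accuracy,
        precision_DU = cm$precision[cm$class == "DU"],
        recall_DU = cm$recall[cm$class == "DU"],
        precision_DI = cm$precision[cm$class == "DI"],
        recall_DI = cm$recall[cm$class == "DI"])
    }
  }
  points <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(points, .data$fraction),
    dplyr::across(c("accuracy", "precision_DU", "recall_DU",
                    "precision_DI", "recall_DI"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~stats::sd(.x, na.rm = TRUE))),
    n_repeats = dplyr::n(), .groups = "drop")
  structure(list(points = points, summary = summary,
                 metadata = list(algorithm = algorithm,
                                 feature_set = feature_set,
                                 growth_factor = growth_factor,
                                 repeats = repeats, k = k, seed = seed)),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve>", x$metadata$algorithm, "| feature set",
      x$metadata$feature_set, "|", nrow(x$summary), "fractions x",
      x$metadata$repeats, "repeats\n")
  print(as.data.frame(x$summary[, c("fraction", "accuracy_mean",
                                    "accuracy_sd", "n_repeats")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Feature-set ablation study
#'
#' Cross-validates every feature set (`Meta`, `Seq`, `SQ`, `SQC`, `SQM`,
#' `All`) with a shared fold assignment so the comparisons see identical
#' splits, and summarises average precision and recall over the two classes.
#'
#' @param features Labelled feature tibble (binary labels).
#' @param algorithm Model algorithm.
#' @param k,seed Cross-validation configuration.
#' @return List with `reports` (named by feature set) and `summary` tibble
#'   (feature_set, avg_precision, avg_recall, accuracy).
#' @export
ablate <- function(features, algorithm = "decision_tree", k = 10L,
                   seed = 1L) {
  enc <- encode_pairs(features, "All", "binary")
  folds <- make_folds(enc$y, k = k, seed = seed)
  reports <- lapply(FEATURE_SETS, function(fs)
    cross_validate(features, algorithm, "binary", fs, k = k, seed = seed,
                   folds = folds))
  names(reports) <- FEATURE_SETS
  summary <- dplyr::bind_rows(lapply(FEATURE_SETS, function(fs) {
    cm <- reports[[fs]]$class_metrics
    tibble::tibble(feature_set = fs,
                   avg_precision = mean(cm$precision),
                   avg_recall = mean(cm$recall),
                   accuracy = reports[[fs]]$accuracy)
  }))
  list(reports = reports, summary = summary)
}

#' Mean numeric-feature profile of classification errors
#'
#' For binary predictions, profiles false positives (distinct pairs
#' predicted duplicate) and false negatives (duplicates predicted
#' distinct): the mean of every numeric feature over the error pairs where
#' that feature is present (missing values are excluded from the mean, not
#' zero-filled), plus instance counts.
#'
#' @param truth Factor/character of true labels (`DU`/`DI`).
#' @param predictions Factor/character of predicted labels.
#' @param features Feature tibble aligned with `truth`.
#' @return List with `counts` (named FP/FN) and `table` (tibble: feature,
#'   fp_mean, fp_n, fn_mean, fn_n).
#' @export
error_profile <- function(truth, predictions, features) {
  truth <- as.character(truth); predictions <- as.character(predictions)
  fp <- truth == "DI" & predictions == "DU"
  fn <- truth == "DU" & predictions == "DI"
  prof <- function(rows, feat) {
    v <- as.numeric(features[[feat]][rows])
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
  }
  table <- dplyr::bind_rows(lapply(NUMERIC_FEATURES, function(feat) {
    a <- prof(fp, feat); b <- prof(fn, feat)
    tibble::tibble(feature = feat, fp_mean = a[["mean"]], fp_n = a[["n"]],
                   fn_mean = b[["mean"]], fn_n = b[["n"]])
  }))
  list(counts = c(FP = sum(fp), FN = sum(fn)), table = table)
}

#' Relative per-subtype accuracy of binary and multi-class models
#'
#' A binary classifier gets credit for a duplicate of any subtype when it
#' predicts `DU`; a multi-class classifier gets credit when it predicts any
#' duplicate subtype (predicting `EF` for a true `ES` pair still identifies
#' a duplicate). For distinct pairs each model must predict `DI`.
#'
#' @param binary_preds Predictions in `{DU, DI}`.
#' @param multi_preds Predictions in `{EF, ES, NS, DI}`.
#' @param truth_binary True labels `{DU, DI}`.
#' @param truth_subtype True subtypes for duplicates (`NA` for `DI`).
#' @return Tibble: class (EF/ES/NS/DI), n, binary_accuracy,
#'   multi_accuracy.
#' @export
relative_type_accuracy <- function(binary_preds, multi_preds, truth_binary,
                                   truth_subtype) {
  binary_preds <- as.character(binary_preds)
  multi_preds <- as.character(multi_preds)
  truth_binary <- as.character(truth_binary)
  cls <- ifelse(truth_binary == "DU", as.character(truth_subtype), "DI")
  dup_types <- c("EF", "ES", "NS")
  bin_ok <- ifelse(truth_binary == "DU", binary_preds == "DU",
                   binary_preds == "DI")
  mul_ok <- ifelse(truth_binary == "DU", multi_preds %in% dup_types,
                   multi_preds == "DI")
  dplyr::bind_rows(lapply(c(dup_types, "DI"), function(cl) {
    idx <- which(cls == cl)
    tibble::tibble(class = cl, n = length(idx),
                   binary_accuracy = if (length(idx)) mean(bin_ok[idx])
                                     else NA_real_,
                   multi_accuracy = if (length(idx)) mean(mul_ok[idx])
                                    else NA_real_)
  }))
}

#' Cross-dataset generalisation
#'
#' Trains on the full training dataset and evaluates on the full, disjoint
#' test dataset.
#'
#' @param train_features,test_features Labelled feature tibbles for two
#'   disjoint datasets (identical pair sets are rejected).
#' @param algorithm,mode,feature_set Model configuration.
#' @param seed Training seed.
#' @return An `evaluation_report`.
#' @export
cross_dataset <- function(train_features, test_features,
                          algorithm = "decision_tree",
                          mode = c("binary", "multiclass"),
                          feature_set = "All", seed = 1L) {
  mode <- match.arg(mode)
  key <- function(df) sort(paste(df$accession_a, df$accession_b))
  if (all(c("accession_a", "accession_b") %in% names(train_features)) &&
      all(c("accession_a", "accession_b") %in% names(test_features)) &&
      identical(key(train_features), key(test_features)))
    stop("cross_dataset: training and test datasets are identical",
         call. = FALSE)
  enc_tr <- encode_pairs(train_features, feature_set, mode)
  enc_te <- encode_pairs(test_features, feature_set, mode)
  model <- train_model(enc_tr, algorithm, seed = seed)
  # align test label levels with the model's training classes
  y_te <- factor(as.character(enc_te$y), levels = model$levels)
  enc_te$y <- y_te
  p <- predict(model, enc_te)
  cfg <- list(algorithm = algorithm, mode = mode, feature_set = feature_set,
              seed = seed)
  new_evaluation_report(y_te, p$labels, p$scores,
                        metadata = c(cfg, list(config_hash = config_hash(cfg))))
}

#' All-ordered-pairs generalisation sweep
#'
#' For every ordered pair of distinct datasets, trains on one and tests on
#' the other: `n` datasets yield `n * (n - 1)` reports.
#'
#' @param datasets Named list of labelled feature tibbles.
#' @param ... Passed to [cross_dataset()].
#' @return Named list of `evaluation_report`s (`"train->test"` keys).
#' @export
transfer_sweep <- function(datasets, ...) {
  stopifnot(is.list(datasets), length(datasets) >= 2L,
            !is.null(names(datasets)))
  out <- list()
  for (a in names(datasets)) {
    for (b in names(datasets)) {
      if (a == b) next
      out[[paste0(a, "->", b)]] <-
        cross_dataset(datasets[[a]], datasets[[b]], ...)
    }
  }
  out
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param file Optional path; when given the JSON is written there.
#' @return JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, file = NULL) {
  md <- report$metadata
  md$folds <- NULL
  x <- list(accuracy = report$accuracy, n = report$n,
            class_metrics = report$class_metrics,
            confusion = list(classes = rownames(report$confusion),
                             matrix = unclass(unname(report$confusion))),
            metadata = md)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}
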