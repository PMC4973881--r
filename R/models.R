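# ---------------------------------------------------------------------------
# Feature-set encoding and the three classifiers (naive Bayes, decision
# tree, SVM) in binary and multi-class modes.
#
# Encoding keeps categorical features as fixed-level factors and imputes
# missing numerics (similarities -> 0, E-values -> the report cutoff); the
# has_* indicator features retain the missingness signal. Naive Bayes and
# the decision tree consume the typed frame directly (Gaussian on numerics,
# categorical on factors); the SVM one-hot encodes factors and scales every
# column to [0, 1] with parameters estimated from the training data only.
# ---------------------------------------------------------------------------

FEATURE_SETS <- c("Meta", "Seq", "SQ", "SQC", "SQM", "All")

#' Feature names belonging to a named feature set
#'
#' The ablation feature sets: `Meta` (description, literature, submitter),
#' `Seq` (local identity and length ratio), `SQ` (`Seq` plus alignment
#' quality), `SQC` (`SQ` plus CDS and translation features), `SQM` (`SQ`
#' plus `Meta`), and `All` (all 22).
#'
#' @param feature_set One of `"Meta"`, `"Seq"`, `"SQ"`, `"SQC"`, `"SQM"`,
#'   `"All"`.
#' @return Character vector of feature names.
#' @export
feature_set_names <- function(feature_set) {
  meta <- c("description", "has_literature", "literature", "submitter")
  seqf <- c("length", "identity")
  sq <- c(seqf, "has_hits", "ap", "expect_value", "over_threshold")
  cds <- c("has_cds", "cds_hits", "cds_identity", "cds_ap", "cds_expect",
           "cds_threshold", "has_trs", "trs_hits", "trs_identity", "trs_ap",
           "trs_expect", "trs_threshold")
  switch(feature_set,
         Meta = meta,
         Seq = seqf,
         SQ = sq,
         SQC = c(sq, cds),
         SQM = c(sq, meta),
         All = FEATURE_NAMES,
         stop("unknown feature set '", feature_set, "'; must be one of ",
              paste(FEATURE_SETS, collapse = ", "), call. = FALSE))
}

factor_levels_for <- function(name) {
  if (name == "submitter") c("SAME", "DIFFERENT", "NA") else c("Yes", "No")
}

#' Encode labelled pair features for model fitting
#'
#' Selects the columns of a named feature set, imputes missing numerics
#' (similarity-type features to 0, E-values to the alignment report cutoff),
#' fixes factor levels for the categorical features, and attaches the label
#' vector (`DU`/`DI` in binary mode; `EF`/`ES`/`NS`/`DI` in multi-class
#' mode, taken from the `subtype` column for duplicates).
#'
#' @param features Feature tibble with `label` (and `subtype` for
#'   multi-class) columns; rows missing a label are dropped.
#' @param feature_set Feature-set name, see [feature_set_names()].
#' @param mode `"binary"` or `"multiclass"`.
#' @param evalue_cap Imputation/cap value for missing E-values.
#' @return An object of class `encoded_pairs`: list with `x` (typed data
#'   frame, no missing values), `y` (factor), `feature_set`, `mode`.
#' @export
encode_pairs <- function(features, feature_set = "All",
                         mode = c("binary", "multiclass"), evalue_cap = 10) {
  mode <- match.arg(mode)
  cols <- feature_set_names(feature_set)
  x <- as.data.frame(features[cols], stringsAsFactors = FALSE)
  for (cc in intersect(cols, CATEGORICAL_FEATURES))
    x[[cc]] <- factor(x[[cc]], levels = factor_levels_for(cc))
  for (cc in intersect(cols, NUMERIC_FEATURES)) {
    v <- as.numeric(x[[cc]])
    fill <- if (grepl("expect", cc)) evalue_cap else 0
    v[is.na(v)] <- fill
    if (grepl("expect", cc)) v <- pmin(v, evalue_cap)
    x[[cc]] <- v
  }
  y <- NULL
  if ("label" %in% names(features)) {
    if (mode == "binary") {
      y <- factor(features$label, levels = c("DU", "DI"))
    } else {
      if (!"subtype" %in% names(features))
        stop("multiclass encoding needs a 'subtype' column")
      lab <- ifelse(features$label == "DU", features$subtype, "DI")
      y <- factor(lab, levels = c("EF", "ES", "NS", "DI"))
    }
    keep <- !is.na(y)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    y <- droplevels(y)
  }
  structure(list(x = x, y = y, feature_set = feature_set, mode = mode,
                 evalue_cap = evalue_cap),
            class = "encoded_pairs")
}

one_hot <- function(x) {
  mats <- lapply(names(x), function(cc) {
    v <- x[[cc]]
    if (is.factor(v)) {
      m <- vapply(levels(v), function(l) as.numeric(v == l),
                  numeric(length(v)))
      if (is.null(dim(m))) m <- matrix(m, nrow = length(v))
      colnames(m) <- paste(cc, levels(v), sep = ".")
      m
    } else {
      matrix(v, ncol = 1L, dimnames = list(NULL, cc))
    }
  })
  do.call(cbind, mats)
}

#' Train a duplicate-pair classifier
#'
#' Fits one of the three supported algorithms on an encoded feature matrix.
#' `naive_bayes` is the Gaussian/categorical hybrid; `decision_tree` is an
#' impurity-based CART tree with cost-complexity pruning at library
#' defaults; `svm` is an RBF-kernel C-SVM (LIBSVM) at default cost and
#' gamma, on one-hot features scaled to `[0, 1]` with training-fold
#' parameters, using one-vs-one decomposition for multi-class problems.
#'
#' @param encoded An [encode_pairs()] object with labels.
#' @param algorithm `"naive_bayes"`, `"decision_tree"` or `"svm"`.
#' @param seed Integer seed fixing any algorithmic randomness.
#' @return Object of class `dup_model`.
#' @export
train_model <- function(encoded,
                        algorithm = c("naive_bayes", "decision_tree", "svm"),
                        seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(encoded, "encoded_pairs"))
  y <- encoded$y
  if (is.null(y)) stop("train_model: encoded data has no labels")
  if (nlevels(droplevels(y)) < 2L)
    stop("train_model: need at least two classes in the labels")
  x <- encoded$x
  set.seed(seed)
  scaling <- NULL
  fit <- switch(algorithm,
    naive_bayes = {
      m <- e1071::naiveBayes(x, y)
      # zero-variance numerics (common on clean synthetic classes) give
      # degenerate Gaussian densities; floor the fitted sds
      m$tables <- lapply(m$tables, function(tab) {
        if (is.matrix(tab) && is.null(colnames(tab)) && ncol(tab) == 2L)
          tab[, 2L] <- pmax(tab[, 2L], 1e-6)   # col 2 = per-class sd
        tab
      })
      m
    },
    decision_tree = rpart::rpart(.y ~ ., data = cbind(x, .y = y),
                                 method = "class"),
    svm = {
      mm <- one_hot(x)
      lo <- apply(mm, 2L, min); hi <- apply(mm, 2L, max)
      span <- ifelse(hi > lo, hi - lo, 1)
      scaled <- sweep(sweep(mm, 2L, lo), 2L, span, "/")
      scaling <- list(lo = lo, span = span, columns = colnames(mm))
      e1071::svm(x = scaled, y = y, kernel = "radial", probability = TRUE,
                 scale = FALSE)
    })
  structure(list(algorithm = algorithm, mode = encoded$mode,
                 feature_set = encoded$feature_set, fit = fit,
                 scaling = scaling, levels = levels(y), seed = seed,
                 columns = names(x), evalue_cap = encoded$evalue_cap),
            class = "dup_model")
}

#' @export
print.dup_model <- function(x, ...) {
  cat("<dup_model>", x$algorithm, "|", x$mode, "| feature set",
      x$feature_set, "| classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict duplicate labels and per-class scores
#'
#' @param object A [train_model()] fit.
#' @param newdata An `encoded_pairs` object (or raw feature tibble, encoded
#'   with the model's feature set and mode).
#' @param ... Unused.
#' @return List with `labels` (factor over the training classes) and
#'   `scores` (matrix, one column per class; rows sum to 1 for the
#'   probabilistic models).
#' @export
predict.dup_model <- function(object, newdata, ...) {
  if (!inherits(newdata, "encoded_pairs"))
    newdata <- encode_pairs(newdata, object$feature_set, object$mode,
                            evalue_cap = object$evalue_cap)
  x <- newdata$x
  if (!identical(names(x), object$columns))
    stop("predict.dup_model: feature columns do not match the model")
  cls <- object$levels
  if (object$algorithm == "naive_bayes") {
    scores <- predict(object$fit, x, type = "raw")
    labels <- factor(cls[max.col(scores[, cls, drop = FALSE], "first")],
                     levels = cls)
  } else if (object$algorithm == "decision_tree") {
    scores <- predict(object$fit, x, type = "prob")
    labels <- predict(object$fit, x, type = "class")
  } else {
    mm <- one_hot(x)
    mm <- mm[, object$scaling$columns, drop = FALSE]
    scaled <- sweep(sweep(mm, 2L, object$scaling$lo), 2L,
                    object$scaling$span, "/")
    scaled[] <- pmin(pmax(scaled, 0), 1)   # clip outside the training range
    pr <- predict(object$fit, scaled, probability = TRUE)
    scores <- attr(pr, "probabilities")
    labels <- pr
  }
  missing_cls <- setdiff(cls, colnames(scores))
  if (length(missing_cls)) {
    add <- matrix(0, nrow(scores), length(missing_cls),
                  dimnames = list(NULL, missing_cls))
    scores <- cbind(scores, add)
  }
  scores <- scores[, cls, drop = FALSE]
  rownames(scores) <- NULL
  list(labels = factor(as.character(labels), levels = cls), scores = scores)
}

#' Save / load a trained model
#'
#' Persists the model with a format version tag so stored models can be
#' validated on load.
#'
#' @param model A `dup_model`.
#' @param file Path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "dup_model"))
  saveRDS(list(format = "seqdedup-model-v1", model = model), file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  obj <- readRDS(file)
  if (!identical(obj$format, "seqdedup-model-v1"))
    stop("not a seqdedup model file: ", file)
  obj$model
}
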