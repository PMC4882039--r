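#' Train the coding-potential random forest
#'
#' Fits a bootstrap-aggregated forest of `n_trees` decision trees (default
#' 300) with random per-split feature subsetting on the selected feature
#' columns. Non-coding training examples whose `MaxORF` falls below the
#' shortcut threshold are excluded before fitting, mirroring the deployment
#' rule that routes such transcripts past the forest entirely: the forest
#' only ever scores inputs the shortcut does not catch.
#'
#' @param X Numeric feature matrix (samples x features) whose columns are the
#'   selected features; must contain `MaxORF` unless `max_orf_values` is
#'   given.
#' @param y Class labels, values in `{"CODING", "NONCODING"}`.
#' @param n_trees Number of trees (default 300).
#' @param seed RNG seed; training is reproducible given the seed.
#' @param orf_shortcut MaxORF threshold (nt) below which a transcript is
#'   declared non-coding without consulting the forest (default 54).
#' @param decision_threshold Non-coding score at or above which the forest
#'   predicts NONCODING (default 0.5; ties go to NONCODING).
#' @param max_orf_values Optional MaxORF vector when `MaxORF` is not among
#'   the selected columns.
#' @return A `coding_potential_model`.
#' @importFrom randomForest randomForest
#' @export
train_classifier <- function(X, y, n_trees = 300L, seed = 1L,
                             orf_shortcut = 54L, decision_threshold = 0.5,
                             max_orf_values = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_trees >= 1L,
            decision_threshold > 0, decision_threshold < 1)
  y <- as.character(y)
  if (!all(y %in% c("CODING", "NONCODING"))) {
    stop("labels must be CODING or NONCODING")
  }
  if (is.null(max_orf_values)) {
    if (!"MaxORF" %in% colnames(X)) {
      stop("X must contain a MaxORF column (or pass max_orf_values)")
    }
    max_orf_values <- X[, "MaxORF"]
  }
  stopifnot(length(max_orf_values) == nrow(X))

  keep <- !(y == "NONCODING" & max_orf_values < orf_shortcut)
  n_dropped <- sum(!keep)
  Xk <- X[keep, , drop = FALSE]
  yk <- factor(y[keep], levels = c("CODING", "NONCODING"))
  if (length(unique(yk)) < 2L) {
    stop("training data contains a single class after the short-ORF filter")
  }
  set.seed(seed)
  forest <- randomForest::randomForest(x = Xk, y = yk, ntree = n_trees)
  structure(list(forest = forest,
                 selected_features = colnames(X),
                 orf_shortcut = orf_shortcut,
                 decision_threshold = decision_threshold,
                 n_trees = n_trees,
                 seed = seed,
                 training = list(n_coding = sum(yk == "CODING"),
                                 n_noncoding = sum(yk == "NONCODING"),
                                 n_shortcut_dropped = n_dropped)),
            class = "coding_potential_model")
}

#' @export
print.coding_potential_model <- function(x, ...) {
  cat("Coding-potential model\n")
  cat(sprintf("  trees: %d | features: %d | ORF shortcut: < %d nt | threshold: %.2f\n",
              x$n_trees, length(x$selected_features), x$orf_shortcut,
              x$decision_threshold))
  cat(sprintf("  trained on %d coding / %d non-coding (%d short-ORF non-coding dropped)\n",
              x$training$n_coding, x$training$n_noncoding,
              x$training$n_shortcut_dropped))
  invisible(x)
}

#' Predict non-coding scores and classes
#'
#' Transcripts with `MaxORF` below the model's shortcut threshold are
#' predicted NONCODING directly, with `noncoding_score = 1` and
#' `shortcut_applied = TRUE` (downstream ROC analysis excludes these rows by
#' default). All other transcripts receive the fraction of forest trees
#' voting non-coding as their score, thresholded at the model's decision
#' threshold with ties going to NONCODING.
#'
#' @param object A `coding_potential_model`.
#' @param newdata Feature matrix or data.frame containing all selected
#'   feature columns plus `MaxORF`; an `id` column is carried through.
#' @param ... Unused.
#' @return data.frame with columns `id`, `noncoding_score`,
#'   `predicted_class`, `shortcut_applied`, followed by the selected feature
#'   values.
#' @export
predict.coding_potential_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    ids <- if ("id" %in% names(newdata)) as.character(newdata$id) else NULL
    newdata <- as.matrix(newdata[, setdiff(names(newdata), "id"),
                                 drop = FALSE])
  } else {
    ids <- rownames(newdata)
  }
  missing_cols <- setdiff(unique(c(object$selected_features, "MaxORF")),
                          colnames(newdata))
  if (length(missing_cols)) {
    stop("newdata is missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(newdata)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  feats <- newdata[, object$selected_features, drop = FALSE]

  score <- numeric(n)
  shortcut <- newdata[, "MaxORF"] < object$orf_shortcut
  if (any(!shortcut)) {
    votes <- predict(object$forest, feats[!shortcut, , drop = FALSE],
                     type = "vote")
    score[!shortcut] <- votes[, "NONCODING"]
  }
  score[shortcut] <- 1
  predicted <- ifelse(shortcut | score >= object$decision_threshold,
                      "NONCODING", "CODING")
  out <- data.frame(id = ids, noncoding_score = score,
                    predicted_class = predicted,
                    shortcut_applied = shortcut,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(feats, check.names = FALSE, row.names = NULL))
}

#' Permutation feature importance on a held-out set
#'
#' Estimates each selected feature's contribution as the mean increase in
#' held-out misclassification error when that feature's column is randomly
#' permuted while all others are left unchanged, averaged over `repeats`
#' seeded permutations. Prediction uses the model's full decision path
#' (shortcut rule plus forest vote).
#'
#' @param model A `coding_potential_model`.
#' @param X_holdout Held-out feature matrix (selected features + `MaxORF`).
#' @param y_holdout True labels for the holdout set (both classes present).
#' @param repeats Number of permutations per feature (default 10).
#' @param seed RNG seed.
#' @return Named numeric vector of importances, sorted descending.
#' @export
permutation_importance <- function(model, X_holdout, y_holdout,
                                   repeats = 10L, seed = 1L) {
  stopifnot(inherits(model, "coding_potential_model"))
  if (repeats < 1L) stop("repeats must be >= 1")
  X_holdout <- as.matrix(X_holdout)
  y_holdout <- as.character(y_holdout)
  stopifnot(nrow(X_holdout) == length(y_holdout))
  if (length(unique(y_holdout)) < 2L) {
    stop("holdout set must contain both classes")
  }
  err <- function(M) {
    mean(predict(model, M)$predicted_class != y_holdout)
  }
  baseline <- err(X_holdout)
  feats <- model$selected_features
  set.seed(seed)
  imp <- vapply(feats, function(f) {
    mean(vapply(seq_len(repeats), function(r) {
      M <- X_holdout
      M[, f] <- M[sample.int(nrow(M)), f]
      err(M) - baseline
    }, numeric(1L)))
  }, numeric(1L))
  sort(imp, decreasing = TRUE)
}

#' Save / load a model bundle
#'
#' The bundle is a single RDS archive holding the forest, the selected
#' feature names, both thresholds and the training seeds.
#'
#' @param model A `coding_potential_model`.
#' @param path Bundle file path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "coding_potential_model"))
  saveRDS(model, path, version = 2L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "coding_potential_model")) {
    stop("file does not contain a coding_potential_model bundle: ", path)
  }
  model
}
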