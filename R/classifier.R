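#' Features shared between two cohorts and carried by enough patients
#'
#' The training feature set for the subtype classifier: features present in
#' both cohorts' catalogs and carried (value 1) by at least `min_patients`
#' patients of the training cohort, in the training cohort's column order.
#'
#' @param cohort_a training [alteration_matrix()].
#' @param cohort_b validation [alteration_matrix()].
#' @param min_patients minimum carrier count in `cohort_a` (default 3).
#' @return character vector of feature ids.
#' @export
select_shared_features <- function(cohort_a, cohort_b, min_patients = 3L) {
  Xa <- if (inherits(cohort_a, "alteration_matrix")) cohort_a$values else as.matrix(cohort_a)
  fb <- if (inherits(cohort_b, "alteration_matrix")) cohort_b$feature_ids else colnames(cohort_b)
  shared <- colnames(Xa)[colnames(Xa) %in% fb & colSums(Xa) >= min_patients]
  if (!length(shared)) stop("no shared features with enough carriers")
  shared
}

# stratified fold ids: within each class, shuffled then dealt out cyclically
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a random-forest subtype classifier
#'
#' Randomized hyperparameter search (tree count, features per split, node
#' size, tree-size cap) scored by stratified k-fold cross-validation
#' accuracy; the best configuration is refit on the full data. All
#' randomness (folds, search, forests) descends from `seed`, so the fit is
#' reproducible.
#'
#' @param X [alteration_matrix()] or binary matrix of training profiles.
#' @param labels subtype labels (character/factor), >= 2 classes, each with
#'   at least `cv_folds` members.
#' @param seed integer seed.
#' @param cv_folds folds for stratified CV (default 5).
#' @param search_iters hyperparameter draws (default 50; reduce for quick
#'   fits -- accuracy on well-separated cohorts is insensitive to it).
#' @param features optional feature subset (e.g. from
#'   [select_shared_features()]); default all columns.
#' @return object of class `subtype_model`: `feature_ids`, `forest`
#'   (randomForest), `classes`, `cv_accuracy_mean`, `cv_accuracy_sd`,
#'   `search` (per-draw record), `best`, `cv_folds`, `seed`.
#' @export
train_subtype_classifier <- function(X, labels, seed = 1L, cv_folds = 5L,
                                     search_iters = 50L, features = NULL) {
  Xm <- if (inherits(X, "alteration_matrix")) X$values else as.matrix(X)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(Xm))
    if (length(missing)) stop("features not in X: ", paste(missing, collapse = ", "))
    Xm <- Xm[, features, drop = FALSE]
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  small <- table(labels) < cv_folds
  if (any(small)) {
    stop("class(es) with fewer members than cv_folds: ",
         paste(names(which(small)), collapse = ", "))
  }
  f <- ncol(Xm)
  set.seed(seed)
  fold <- stratified_folds(labels, cv_folds)
  grid <- data.frame(
    ntree = sample(c(100L, 200L, 300L, 500L), search_iters, replace = TRUE),
    mtry = sample(seq_len(max(2L, min(f, 12L))), search_iters, replace = TRUE),
    nodesize = sample(c(1L, 3L, 5L), search_iters, replace = TRUE),
    maxnodes = sample(c(NA_integer_, 16L, 32L, 64L), search_iters, replace = TRUE)
  )
  fit_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 search_iters * cv_folds),
                      search_iters, cv_folds)
  cv_acc <- matrix(NA_real_, search_iters, cv_folds)
  cap_nodes <- function(mx, n_train) {
    if (is.na(mx)) NULL else min(mx, n_train)   # a tree cannot have more leaves
  }
  for (g in seq_len(search_iters)) {
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      set.seed(fit_seeds[g, k])
      rf <- randomForest::randomForest(
        x = Xm[tr, , drop = FALSE], y = labels[tr],
        ntree = grid$ntree[g], mtry = grid$mtry[g],
        nodesize = grid$nodesize[g],
        maxnodes = cap_nodes(grid$maxnodes[g], sum(tr)))
      pred <- predict(rf, Xm[!tr, , drop = FALSE])
      cv_acc[g, k] <- mean(pred == labels[!tr])
    }
  }
  mean_acc <- rowMeans(cv_acc)
  best <- which.max(mean_acc)
  set.seed(derive_seed(seed, 7L))
  forest <- randomForest::randomForest(
    x = Xm, y = labels, ntree = grid$ntree[best], mtry = grid$mtry[best],
    nodesize = grid$nodesize[best],
    maxnodes = cap_nodes(grid$maxnodes[best], nrow(Xm)))
  structure(list(
    feature_ids = colnames(Xm), forest = forest, classes = levels(labels),
    cv_accuracy_mean = mean_acc[best],
    cv_accuracy_sd = stats::sd(cv_acc[best, ]),
    search = cbind(grid, cv_accuracy = mean_acc),
    best = grid[best, , drop = FALSE],
    cv_folds = as.integer(cv_folds), seed = as.integer(seed)
  ), class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("subtype_model: %d classes on %d features\n",
              length(x$classes), length(x$feature_ids)))
  cat(sprintf("  %d-fold CV accuracy: %.3f (sd %.3f), seed %d\n",
              x$cv_folds, x$cv_accuracy_mean, x$cv_accuracy_sd, x$seed))
  invisible(x)
}

#' Predict subtypes for an external cohort
#'
#' @param object a [train_subtype_classifier()] model.
#' @param newdata [alteration_matrix()] or binary matrix containing the
#'   model's features.
#' @param strict if `TRUE` (default), missing model features are an error;
#'   if `FALSE` they are zero-filled with a warning.
#' @param ... unused.
#' @return list: `labels` (character, argmax with ties to the lowest class
#'   index) and `prob` (patients x classes matrix, rows sum to 1).
#' @export
predict.subtype_model <- function(object, newdata, strict = TRUE, ...) {
  Xm <- if (inherits(newdata, "alteration_matrix")) newdata$values else as.matrix(newdata)
  missing <- setdiff(object$feature_ids, colnames(Xm))
  if (length(missing)) {
    if (strict) {
      stop("cohort is missing model feature(s): ", paste(missing, collapse = ", "))
    }
    warning("zero-filling missing feature(s): ", paste(missing, collapse = ", "))
    fill <- matrix(0L, nrow(Xm), length(missing),
                   dimnames = list(rownames(Xm), missing))
    Xm <- cbind(Xm, fill)
  }
  Xm <- Xm[, object$feature_ids, drop = FALSE]
  prob <- predict(object$forest, Xm, type = "prob")
  labels <- object$classes[max.col(prob, ties.method = "first")]
  names(labels) <- rownames(Xm)
  list(labels = labels, prob = prob)
}

#' Save / load a subtype classifier
#'
#' The serialized file embeds the feature list, class order and seed, so a
#' reloaded model reproduces predictions bit-for-bit.
#'
#' @param model a `subtype_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_subtype_model <- function(model, path) {
  stopifnot(inherits(model, "subtype_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_subtype_model
#' @export
load_subtype_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "subtype_model")) stop("file does not hold a subtype_model")
  model
}

#' Write subtype predictions as TSV
#'
#' @param pred a [predict.subtype_model()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  df <- data.frame(patient_id = names(pred$labels),
                   predicted_subtype = unname(pred$labels),
                   pred$prob, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
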