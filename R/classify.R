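#' Classifier specification
#'
#' Describes one of the four classifier families under a uniform
#' train/predict/score contract, named by the field convention
#' `ANN-nl-nu` (multi-layer perceptron with `nl` hidden layers of `nu`
#' units) and `PCA-nv-MSVM` (projection onto `nv` principal components
#' followed by a multiclass SVM).
#'
#' @param kind one of `"ann"`, `"msvm"`, `"rf"`, `"pca_msvm"`.
#' @param nl,nu hidden-layer count and units per layer (ann; defaults 3 and
#'   50).
#' @param n_trees tree count (rf; default 100).
#' @param nv retained principal components (pca_msvm).
#' @param standardize centre/scale features before training (default
#'   `FALSE`; raw voltages are used unless asked otherwise).
#' @param seed integer seed for stochastic trainers (ann initialisation and
#'   validation slice, rf bootstrap); msvm is deterministic and ignores it.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("ann", "msvm", "rf", "pca_msvm"),
                            nl = 3L, nu = 50L, n_trees = 100L, nv = 3L,
                            standardize = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  nl <- as.integer(nl); nu <- as.integer(nu)
  n_trees <- as.integer(n_trees); nv <- as.integer(nv)
  if (kind == "ann" && (nl < 1L || nu < 1L))
    stop_("ann requires nl >= 1 and nu >= 1")
  if (kind == "rf" && n_trees < 1L) stop_("rf requires n_trees >= 1")
  if (kind == "pca_msvm" && nv < 1L) stop_("pca_msvm requires nv >= 1")
  structure(list(kind = kind, nl = nl, nu = nu, n_trees = n_trees, nv = nv,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Display name of a classifier spec (`ANN-3-50`, `PCA-3-MSVM`, ...)
#' @param spec a `classifier_spec`.
#' @export
spec_label <- function(spec) {
  switch(spec$kind,
         ann = sprintf("ANN-%d-%d", spec$nl, spec$nu),
         msvm = "MSVM",
         rf = "RF",
         pca_msvm = sprintf("PCA-%d-MSVM", spec$nv))
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (seed=%d%s)\n", spec_label(x), x$seed,
              if (x$standardize) ", standardized" else ""))
  invisible(x)
}

#' Fit a principal-component projection on training features
#'
#' Centres on the training mean (no scaling, no whitening) and retains the
#' leading `nv` components. The returned map is applied unchanged to test
#' data — it is never refit outside the training set.
#'
#' @param train_features numeric matrix (trials x features).
#' @param nv components to keep; at most `min(n_features, n_train - 1)`
#'   informative directions exist.
#' @return list with `project(x)` (function), `rotation`, `center`, and
#'   `scores` (projected training features).
#' @export
pca_project <- function(train_features, nv) {
  nv <- as.integer(nv)
  if (nv < 1L) stop_("nv must be >= 1")
  rank_cap <- min(dim(train_features))
  if (nv > rank_cap)
    stop_(sprintf("nv = %d exceeds the feasible rank %d", nv, rank_cap))
  pc <- stats::prcomp(train_features, center = TRUE, scale. = FALSE)
  if (nv > ncol(pc$rotation))
    stop_(sprintf("nv = %d exceeds the %d available components",
                  nv, ncol(pc$rotation)))
  rotation <- pc$rotation[, seq_len(nv), drop = FALSE]
  center <- pc$center
  project <- function(x) sweep(x, 2L, center) %*% rotation
  list(project = project, rotation = rotation, center = center,
       scores = pc$x[, seq_len(nv), drop = FALSE])
}

#' Train a classifier on an e-nose dataset
#'
#' Dispatches a [classifier_spec()]:
#' \describe{
#'   \item{ann}{fully connected network, `nl` hidden tanh layers of `nu`
#'     units, softmax over the class inventory, cross-entropy loss, Adam,
#'     early stopping on a stratified 15\% slice of the training pool with
#'     best-weight restoration. Stochastic across seeds.}
#'   \item{msvm}{one-vs-one linear-kernel SVM ensemble with majority voting
#'     (via \pkg{e1071}); deterministic — refits with different seeds give
#'     identical models.}
#'   \item{rf}{random forest of `n_trees` trees, Gini splits, bootstrap
#'     sampling (via \pkg{randomForest}); stochastic across seeds.}
#'   \item{pca_msvm}{[pca_project()] onto `nv` components fitted on the
#'     training data, then the msvm in the reduced space; deterministic.}
#' }
#'
#' @param spec a [classifier_spec()].
#' @param train training `enose_dataset` with >= 2 classes present and >= 1
#'   trial in every present class.
#' @param seed optional override of `spec$seed`.
#' @return a `fitted_model` with a [predict][predict.fitted_model] method.
#' @export
enose_train <- function(spec, train, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "enose_dataset"))
  seed <- as.integer(seed %||% spec$seed)
  cc <- class_counts(train)
  present <- names(cc)[cc > 0L]
  if (length(present) < 2L)
    stop_("training requires at least 2 classes with trials")
  empty <- setdiff(train$classes, present)
  if (length(empty))
    stop_("class with no training trials: ", paste(empty, collapse = ", "))
  x <- train$features
  scaling <- NULL
  if (spec$standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
    scaling <- list(mu = mu, sd = sdv)
  }
  y_idx <- as.integer(train$labels)
  C <- length(train$classes)
  fit <- switch(spec$kind,
    ann = mlp_fit(x, y_idx, C, rep(spec$nu, spec$nl), seed = seed),
    msvm = e1071::svm(x, factor(train$labels, levels = train$classes),
                      kernel = "linear", scale = FALSE, probability = FALSE),
    rf = with_seed(seed,
      randomForest::randomForest(x, factor(train$labels,
                                           levels = train$classes),
                                 ntree = spec$n_trees)),
    pca_msvm = {
      proj <- pca_project(x, spec$nv)
      svm_fit <- e1071::svm(proj$scores,
                            factor(train$labels, levels = train$classes),
                            kernel = "linear", scale = FALSE)
      list(proj = proj, svm = svm_fit)
    })
  structure(list(spec = spec, fit = fit, classes = train$classes,
                 n_features = ncol(train$features), scaling = scaling,
                 seed = seed),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s, %d classes, %d features\n",
              spec_label(x$spec), length(x$classes), x$n_features))
  invisible(x)
}

#' Predict class labels (and probabilities where available)
#'
#' @param object a `fitted_model`.
#' @param newdata an `enose_dataset` or numeric feature matrix with the
#'   training feature length.
#' @param type `"class"` for labels, `"prob"` for the per-class probability
#'   matrix (ann only; other families predict hard labels).
#' @param ... unused.
#' @return factor of predicted labels, or a probability matrix.
#' @export
predict.fitted_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "enose_dataset")) newdata$features
       else as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop_(sprintf("newdata has %d features; model was trained on %d",
                  ncol(x), object$n_features))
  if (!is.null(object$scaling))
    x <- sweep(sweep(x, 2L, object$scaling$mu), 2L, object$scaling$sd, `/`)
  if (object$spec$kind == "ann") {
    prob <- mlp_predict_prob(object$fit, x)
    colnames(prob) <- object$classes
    if (type == "prob") return(prob)
    # argmax with ties broken toward the lower class index
    return(factor(object$classes[max.col(prob, ties.method = "first")],
                  levels = object$classes))
  }
  if (type == "prob")
    stop_("probability outputs are only available for ann models")
  pred <- switch(object$spec$kind,
    msvm = stats::predict(object$fit, x),
    rf = stats::predict(object$fit, x),
    pca_msvm = stats::predict(object$fit$svm, object$fit$proj$project(x)))
  factor(as.character(pred), levels = object$classes)
}

#' Evaluate a fitted model on held-out trials
#'
#' Computes the accuracy (percent of correctly classified test trials) and
#' the full true-by-predicted confusion matrix over the class inventory.
#'
#' @param model a `fitted_model`.
#' @param test a non-empty `enose_dataset` with matching feature length.
#' @return an `eval_report`: `accuracy` (percent), `confusion` (C x C count
#'   matrix), `predicted`, and `prob` (ann only).
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "fitted_model"), inherits(test, "enose_dataset"))
  if (n_trials(test) == 0L) stop_("test set is empty")
  pred <- predict(model, test)
  confusion <- table(true = factor(test$labels, levels = model$classes),
                     predicted = pred)
  accuracy <- 100 * sum(diag(confusion)) / sum(confusion)
  prob <- if (model$spec$kind == "ann") predict(model, test, type = "prob")
          else NULL
  structure(list(accuracy = accuracy, confusion = unclass(confusion),
                 predicted = pred, prob = prob,
                 spec = model$spec),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s accuracy %.2f%% (%d/%d correct)\n",
              spec_label(x$spec), x$accuracy,
              sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Serialize an eval report to JSON
#' @param report an `eval_report`.
#' @param path optional output file; if omitted the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(classifier = spec_label(report$spec),
                  accuracy = report$accuracy,
                  confusion = report$confusion)
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
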