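#' Fit a probabilistic base classifier on PC scores
#'
#' The two base learners wrapped by the AdaSampling procedure:
#'
#' * `"svm"` -- an RBF-kernel support vector machine trained one-against-one
#'   for multi-class problems, with per-pair Platt sigmoid calibration
#'   (`P = 1 / (1 + exp(A f(x) + B))`, `A`, `B` fit by maximum likelihood)
#'   combined into K-class probabilities by pairwise coupling, as
#'   implemented in libsvm via \pkg{e1071}. The RBF width defaults to
#'   `gamma = 1 / (ncol(x) * var(x))` and cost to 1.
#' * `"rf"` -- a random forest of `ntree` trees (100 by default), each grown
#'   on a bootstrap sample with `floor(sqrt(ncol(x)))` candidate features
#'   per split; class probabilities are the fraction of trees voting for
#'   each class, so they are multiples of `1/ntree`.
#'
#' Training data may contain only a subset of the full cell-type set (this
#' happens when a resample drops a class); `class_order` records the full
#' set so that [predict.base_classifier()] can pad absent classes with
#' probability zero and always return K columns in a fixed order.
#'
#' @param x Numeric matrix of PC scores (cells x components).
#' @param y Factor of cell-type labels aligned to `x` rows.
#' @param kind `"svm"` or `"rf"`.
#' @param ntree Number of trees for the forest.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses the default
#'   above.
#' @param class_order Full cell-type set; defaults to `levels(y)`.
#' @return An object of class `"base_classifier"`.
#' @export
fit_classifier <- function(x, y, kind = c("svm", "rf"), ntree = 100,
                           cost = 1, gamma = NULL,
                           class_order = levels(y)) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    stop("training labels contain a single class; the resampler must ",
         "supply at least two classes", call. = FALSE)
  }
  if (!all(levels(y) %in% class_order)) {
    stop("training labels outside the declared class order", call. = FALSE)
  }
  if (kind == "svm") {
    counts <- table(y)
    if (any(counts < 2)) {
      stop("class(es) ", paste(names(counts)[counts < 2], collapse = ", "),
           " have fewer than 2 training cells; Platt calibration needs ",
           "at least 2 per class -- the sampler must guarantee minimum ",
           "class counts", call. = FALSE)
    }
    if (is.null(gamma)) gamma <- 1 / (ncol(x) * var(as.vector(x)))
    fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                      probability = TRUE, scale = FALSE)
  } else {
    stopifnot(ntree >= 1)
    fit <- randomForest::randomForest(x, y, ntree = ntree)
  }
  structure(list(kind = kind, fit = fit, class_order = class_order,
                 trained_classes = levels(y), n_features = ncol(x),
                 training_size = nrow(x)),
            class = "base_classifier")
}

#' Predict class probabilities from a fitted base classifier
#'
#' @param object A `"base_classifier"` fit.
#' @param newdata Scores matrix with the same number of components as the
#'   training data.
#' @param ... Unused.
#' @return Row-stochastic matrix `nrow(newdata)` x K over
#'   `object$class_order`; classes absent from the training subset get
#'   probability 0.
#' @export
predict.base_classifier <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; model was trained on ",
         object$n_features, call. = FALSE)
  }
  if (object$kind == "svm") {
    pr <- attr(predict(object$fit, newdata, probability = TRUE),
               "probabilities")
  } else {
    pr <- predict(object$fit, newdata, type = "prob")
  }
  out <- matrix(0, nrow(newdata), length(object$class_order),
                dimnames = list(rownames(newdata), object$class_order))
  out[, colnames(pr)] <- pr
  out
}

#' @export
print.base_classifier <- function(x, ...) {
  cat("Base classifier (", x$kind, "): trained on ", x$training_size,
      " cells x ", x$n_features, " PCs, ", length(x$trained_classes), " of ",
      length(x$class_order), " classes present\n", sep = "")
  invisible(x)
}
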