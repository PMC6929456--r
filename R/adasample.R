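#' Per-cell mislabelling probability from class probabilities
#'
#' Given a classifier's row-stochastic class-probability matrix and the
#' current annotation, the mislabelling probability of cell i annotated as
#' type k is `eps_i = 1 - P(yhat_i = k | x_i)`: one minus the probability
#' mass the classifier puts on the cell's own label.
#'
#' @param probs Row-stochastic cells x K matrix with class names as column
#'   names.
#' @param y Factor (or character) of current labels aligned to `probs` rows.
#' @return Numeric vector of mislabelling probabilities in `[0, 1]`.
#' @export
estimate_epsilon <- function(probs, y) {
  y <- as.character(y)
  stopifnot(nrow(probs) == length(y))
  j <- match(y, colnames(probs))
  if (anyNA(j)) {
    stop("label(s) not among probability columns: ",
         paste(unique(y[is.na(j)]), collapse = ", "), call. = FALSE)
  }
  eps <- 1 - probs[cbind(seq_along(y), j)]
  pmin(pmax(eps, 0), 1)
}

#' Draw a weighted, class-stratified training resample
#'
#' Each cell's chance of entering the next training set is proportional to
#' `1 - eps_i` within its annotated class: cells that look mislabelled are
#' progressively excluded from training. Sampling is stratified -- class k
#' with `N_k` members contributes exactly `N_k` draws with replacement -- so
#' no class can vanish from the training set. A class whose weights are all
#' zero falls back to uniform weights with a warning; if a class would end
#' up represented by a single distinct cell, the highest-weight other cell
#' is forced in so that downstream Platt calibration stays feasible.
#'
#' @param y Factor of current labels.
#' @param eps Mislabelling probabilities aligned to `y` (0 = certainly
#'   correct). `eps = 0` everywhere gives a plain per-class bootstrap.
#' @return Integer vector of sampled cell indices (a multiset), grouped by
#'   class.
#' @export
weighted_resample <- function(y, eps = rep(0, length(y))) {
  y <- as.factor(y)
  stopifnot(length(eps) == length(y), all(eps >= 0), all(eps <= 1))
  w <- 1 - eps
  unlist(lapply(levels(y), function(k) {
    idx <- which(y == k)
    wk <- w[idx]
    if (all(wk <= 0)) {
      warning("all cells of class '", k, "' have mislabelling probability ",
              "1; falling back to uniform weights", call. = FALSE)
      wk <- rep(1, length(idx))
    }
    s <- idx[sample.int(length(idx), length(idx), replace = TRUE, prob = wk)]
    if (length(unique(s)) < 2 && sum(wk > 0) >= 2) {
      alt <- idx[order(wk, decreasing = TRUE)]
      alt <- alt[alt != s[1] & w[alt] > 0][1]
      s[length(s)] <- alt
    }
    s
  }), use.names = FALSE)
}

#' Iterative mislabelling-probability estimation (multi-class AdaSampling)
#'
#' The core adaptive-resampling loop. Iteration 1 trains the base
#' classifier on a uniform class-stratified bootstrap of the annotated
#' data (every cell equally likely within its class); each subsequent
#' iteration trains on a [weighted_resample()] driven by the previous
#' iteration's mislabelling probabilities. After every fit the classifier
#' predicts all N cells and the mislabelling probabilities are recomputed
#' with [estimate_epsilon()], so successive training sets are drawn from
#' progressively cleaner label distributions. Three iterations are the
#' default.
#'
#' @param scores Cells x components PC-score matrix.
#' @param y Factor of initial labels (K >= 2, each class with >= 4 cells
#'   recommended).
#' @param classifier `"svm"` or `"rf"`.
#' @param iters Number of iterations L.
#' @param ntree Trees per forest when `classifier = "rf"`.
#' @return List with `epsilon` (final mislabelling probabilities, one per
#'   cell), `probs` (class-probability matrix from the final iteration) and
#'   `iters`.
#' @export
adasample <- function(scores, y, classifier = c("svm", "rf"), iters = 3,
                      ntree = 100) {
  classifier <- match.arg(classifier)
  y <- as.factor(y)
  stopifnot(iters >= 1, nrow(scores) == length(y), nlevels(y) >= 2)
  eps <- rep(0, length(y))
  probs <- NULL
  for (l in seq_len(iters)) {
    idx <- weighted_resample(y, eps)
    model <- fit_classifier(scores[idx, , drop = FALSE], y[idx],
                            kind = classifier, ntree = ntree,
                            class_order = levels(y))
    probs <- predict(model, scores)
    eps <- estimate_epsilon(probs, y)
  }
  list(epsilon = stats::setNames(eps, rownames(scores)), probs = probs,
       iters = iters)
}
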