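#' Per-class mean classification accuracy
#'
#' The unweighted mean over cell types of the within-type fraction of
#' correctly labelled cells:
#' `(1/K) * sum_k (1/N_k) * sum_{truth_i = k} 1(pred_i = truth_i)`.
#' K and the class sizes `N_k` come from the truth vector, so every type
#' counts equally regardless of how many cells it holds -- a 100-cell type
#' fully wrong costs as much as a 1000-cell type fully wrong. Predicted
#' labels outside the truth's type set simply count as incorrect.
#'
#' @param pred Predicted/corrected labels.
#' @param truth Reference labels, aligned to `pred`; every type present in
#'   `truth` must be non-empty (it is, by construction).
#' @return Mean accuracy in `[0, 1]`.
#' @seealso [adjusted_rand_index()] for a class-size-adjusted alternative.
#' @export
mean_accuracy <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth have different lengths", call. = FALSE)
  }
  classes <- unique(truth)
  mean(vapply(classes, function(k) {
    mean(pred[truth == k] == k)
  }, numeric(1)))
}

#' Adjusted Rand index between two labellings (pair-count form)
#'
#' Agreement between two partitions of the same N cells, corrected for
#' chance, computed from the four pair categories over all N(N-1)/2 cell
#' pairs: `a` pairs co-labelled in both lists, `b` co-labelled only in the
#' first, `c` co-labelled only in the second, `d` separated in both. Then
#'
#' `ARI = 2(ad - bc) / ((a + b)(b + d) + (a + c)(c + d))`.
#'
#' The pair counts are accumulated from the contingency table of the two
#' labellings, which is exact and O(K^2) rather than O(N^2). Degenerate
#' denominators follow common practice: identical degenerate partitions
#' (`b = c = 0`) score 1, any other zero denominator scores 0. Label
#' *names* never matter, only the induced partitions.
#'
#' @param a_labels,b_labels Two label vectors over the same N >= 2 cells.
#' @return ARI in `[-1, 1]`; 1 iff the partitions are identical, ~0 for
#'   independent labellings.
#' @export
adjusted_rand_index <- function(a_labels, b_labels) {
  if (length(a_labels) != length(b_labels)) {
    stop("label vectors have different lengths", call. = FALSE)
  }
  n <- length(a_labels)
  if (n < 2) stop("need at least 2 cells to form a pair", call. = FALSE)
  tab <- table(as.character(a_labels), as.character(b_labels))
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2)) - a
  cc <- sum(choose(colSums(tab), 2)) - a
  d <- choose(n, 2) - a - b - cc
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) {
    return(if (b == 0 && cc == 0) 1 else 0)
  }
  2 * (a * d - b * cc) / denom
}

#' Evaluation report for a corrected annotation
#'
#' @param pred Predicted/corrected labels.
#' @param truth Reference labels.
#' @return List with `mean_accuracy`, `ari`, `per_class_accuracy` (named by
#'   truth type) and the `confusion` table (truth rows x predicted
#'   columns; row sums are the class sizes).
#' @export
evaluate_labels <- function(pred, truth) {
  predc <- as.character(pred)
  truthc <- as.character(truth)
  classes <- unique(truthc)
  per_class <- vapply(classes, function(k) mean(predc[truthc == k] == k),
                      numeric(1))
  list(
    mean_accuracy = mean(per_class),
    ari = adjusted_rand_index(pred, truth),
    per_class_accuracy = per_class,
    confusion = table(truth = truthc, predicted = predc)
  )
}

#' Benchmark label correction over a noise grid
#'
#' For every combination of noise rate, base classifier and repeat: inject
#' cyclic label-flip noise into the truth, run [relabel()] on the
#' expression matrix with the noisy labels, and record baseline (noisy vs
#' truth) and corrected (relabelled vs truth) mean accuracy and ARI.
#'
#' @param expression Cells x genes matrix in raw units.
#' @param truth True/reference labels.
#' @param rho Vector of mislabelling rates (default 0.1 to 0.5).
#' @param classifiers Base classifiers to benchmark.
#' @param repeats Independent noise/correction repetitions per cell of the
#'   grid (default 10).
#' @param ... Further arguments to [relabel()] (e.g. `ensemble`, `iters`).
#' @return Long-format data frame with one row per (rho, classifier,
#'   repeat): baseline and corrected mean accuracy and ARI, and the number
#'   of cells the correction changed.
#' @export
benchmark_noise <- function(expression, truth, rho = seq(0.1, 0.5, by = 0.1),
                            classifiers = "svm", repeats = 10, ...) {
  grid <- expand.grid(rep = seq_len(repeats), classifier = classifiers,
                      rho = rho, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    noisy <- inject_label_noise(truth, g$rho)
    fit <- relabel(expression, noisy$labels, classifier = g$classifier,
                   keep_models = FALSE, ...)
    data.frame(
      rho = g$rho, classifier = g$classifier, rep = g$rep,
      baseline_accuracy = mean_accuracy(noisy$labels, truth),
      corrected_accuracy = mean_accuracy(fitted(fit), truth),
      baseline_ari = adjusted_rand_index(noisy$labels, truth),
      corrected_ari = adjusted_rand_index(fitted(fit), truth),
      n_changed = sum(fit$changed),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
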