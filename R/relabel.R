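#' Correct a cell-type annotation by adaptive resampling
#'
#' The main fitting function. Starting from a cells x genes expression
#' matrix and an initial (possibly partly wrong) cell-type annotation, it
#'
#' 1. removes genes with more than `zero_fraction_cutoff` zeros across
#'    cells and applies the log2(x+1) transform (each step can be
#'    switched off);
#' 2. reduces the matrix to principal-component scores, keeping the number
#'    of components that captures at least `variance_threshold` of the
#'    variance, clamped to `[pc_floor, pc_ceiling]` ([reduce_dims()]);
#' 3. runs `iters` rounds of AdaSampling ([adasample()]) to estimate each
#'    cell's mislabelling probability `eps_i`;
#' 4. draws `ensemble` final training sets weighted by `1 - eps_i`, fits
#'    one base classifier per set, and averages their class-probability
#'    matrices;
#' 5. reassigns every cell to the class with the highest ensemble
#'    probability. Ties keep the initial label when it is among the tied
#'    classes, otherwise the earliest class in first-appearance order
#'    wins. With `min_prob > 0`, cells whose top ensemble probability
#'    falls below it keep their initial label.
#'
#' Randomness (resampling, forest growth, SVM probability calibration) is
#' drawn from R's RNG, so `set.seed()` before the call makes the fit fully
#' reproducible.
#'
#' @param x Non-negative cells x genes matrix with cell ids as row names,
#'   or anything coercible to one.
#' @param labels Initial annotation: factor or character of length
#'   `nrow(x)`, or a named vector matched against `rownames(x)`. At least
#'   two cell types, each with at least 4 cells.
#' @param classifier Base classifier, `"svm"` (default) or `"rf"`.
#' @param iters AdaSampling iterations L (default 3).
#' @param ensemble Number of final models averaged (default 10); 1 gives
#'   the single-model variant.
#' @param filter,log2_transform Toggle the preprocessing steps.
#' @param zero_fraction_cutoff Gene-filter threshold (default 0.8).
#' @param variance_threshold,pc_floor,pc_ceiling PC-selection rule
#'   parameters (defaults 0.7, 10, 20).
#' @param ntree Trees per forest when `classifier = "rf"` (default 100).
#' @param min_prob Optional confidence floor for relabelling (default 0:
#'   pure argmax, every cell reassigned).
#' @param keep_models Keep the fitted ensemble members so the fit can
#'   [predict()] on new cells (default `TRUE`).
#' @return An object of class `"relabel"`; see Details. Key elements:
#'   `labels` (corrected factor), `initial`, `probabilities` (cells x K
#'   ensemble average), `epsilon`, `changed` (logical), `reduction`.
#' @examples
#' set.seed(1)
#' sim <- simulate_cells(n_types = 3, cells_per_type = 50, n_genes = 400)
#' noisy <- inject_label_noise(sim$labels, rho = 0.2)
#' fit <- relabel(sim$expression, noisy$labels, ensemble = 5)
#' mean_accuracy(fitted(fit), sim$labels)
#' @export
relabel <- function(x, labels,
                    classifier = c("svm", "rf"),
                    iters = 3, ensemble = 10,
                    filter = TRUE, log2_transform = TRUE,
                    zero_fraction_cutoff = 0.8,
                    variance_threshold = 0.7, pc_floor = 10L,
                    pc_ceiling = 20L,
                    ntree = 100, min_prob = 0,
                    keep_models = TRUE) {
  classifier <- match.arg(classifier)
  stopifnot(iters >= 1, ensemble >= 1, min_prob >= 0, min_prob <= 1)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("cell", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("gene", seq_len(ncol(x)))
  if (!is.null(names(labels)) && !identical(names(labels), rownames(x))) {
    if (!setequal(names(labels), rownames(x))) {
      stop("label names do not match expression matrix cell ids",
           call. = FALSE)
    }
    labels <- labels[rownames(x)]
  }
  if (length(labels) != nrow(x)) {
    stop("got ", length(labels), " labels for ", nrow(x), " cells",
         call. = FALSE)
  }
  y <- factor(as.character(labels), levels = unique(as.character(labels)))
  if (nlevels(y) < 2) stop("need at least two cell types", call. = FALSE)
  small <- table(y) < 4
  if (any(small)) {
    stop("cell type(s) with fewer than 4 cells: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  }

  if (filter) x <- filter_genes(x, zero_fraction_cutoff)
  if (log2_transform) x <- log_transform(x)
  red <- reduce_dims(x, variance_threshold, pc_floor, pc_ceiling)
  scores <- red$scores

  ada <- adasample(scores, y, classifier = classifier, iters = iters,
                   ntree = ntree)

  probs <- matrix(0, nrow(scores), nlevels(y),
                  dimnames = list(rownames(x), levels(y)))
  models <- vector("list", ensemble)
  for (b in seq_len(ensemble)) {
    idx <- weighted_resample(y, ada$epsilon)
    model <- fit_classifier(scores[idx, , drop = FALSE], y[idx],
                            kind = classifier, ntree = ntree,
                            class_order = levels(y))
    probs <- probs + predict(model, scores)
    if (keep_models) models[[b]] <- model
  }
  probs <- probs / ensemble

  corrected <- argmax_labels(probs, y)
  if (min_prob > 0) {
    low <- apply(probs, 1, max) < min_prob
    corrected[low] <- y[low]
  }

  structure(list(
    labels = stats::setNames(corrected, rownames(x)),
    initial = stats::setNames(y, rownames(x)),
    probabilities = probs,
    epsilon = ada$epsilon,
    changed = stats::setNames(corrected != y, rownames(x)),
    reduction = red,
    genes = colnames(x),
    log2_transform = log2_transform,
    classifier = classifier, iters = iters, ensemble = ensemble,
    ntree = ntree, min_prob = min_prob,
    models = if (keep_models) models,
    call = match.call()
  ), class = "relabel")
}

# row argmax with conservative tie handling: keep the current label when it
# ties for the maximum, otherwise take the earliest class in level order
argmax_labels <- function(probs, y) {
  lev <- colnames(probs)
  out <- character(nrow(probs))
  yc <- as.character(y)
  for (i in seq_len(nrow(probs))) {
    p <- probs[i, ]
    top <- which(p >= max(p) - 1e-12)
    out[i] <- if (match(yc[i], lev) %in% top) yc[i] else lev[top[1]]
  }
  factor(out, levels = lev)
}

#' @export
print.relabel <- function(x, ...) {
  cat("Post hoc cell-type label correction\n")
  cat("  ", length(x$labels), " cells, ", nlevels(x$initial),
      " cell types, ", x$reduction$npcs, " PCs\n", sep = "")
  cat("  base classifier: ", x$classifier, " (", x$iters,
      " AdaSampling iterations, ensemble of ", x$ensemble, ")\n", sep = "")
  cat("  relabelled ", sum(x$changed), " of ", length(x$labels), " cells (",
      sprintf("%.1f%%", 100 * mean(x$changed)), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.relabel <- function(object, ...) {
  tab <- table(initial = object$initial, corrected = object$labels)
  structure(list(
    fit = object,
    transitions = tab,
    n_changed = sum(object$changed),
    epsilon_summary = summary(object$epsilon),
    mean_max_prob = mean(apply(object$probabilities, 1, max))
  ), class = "summary.relabel")
}

#' @export
print.summary.relabel <- function(x, ...) {
  print(x$fit)
  cat("\nMislabelling probabilities (eps):\n")
  print(x$epsilon_summary)
  cat(sprintf("\nMean top ensemble probability: %.3f\n", x$mean_max_prob))
  cat("\nInitial -> corrected label transitions:\n")
  print(x$transitions)
  invisible(x)
}

#' Corrected labels of a relabel fit
#' @param object A [relabel()] fit.
#' @param ... Unused.
#' @return Factor of corrected labels, named by cell id.
#' @export
fitted.relabel <- function(object, ...) object$labels

#' Result table of a relabel fit
#'
#' One row per cell in input order: `cell_id`, `original_label`,
#' `predicted_label`, `changed`, `max_probability`, then one `prob_<type>`
#' column per cell type.
#'
#' @param x A [relabel()] fit.
#' @param ... Unused.
#' @export
as.data.frame.relabel <- function(x, ...) {
  df <- data.frame(
    cell_id = names(x$labels),
    original_label = as.character(x$initial),
    predicted_label = as.character(x$labels),
    changed = unname(x$changed),
    max_probability = unname(apply(x$probabilities, 1, max)),
    stringsAsFactors = FALSE
  )
  pr <- as.data.frame(x$probabilities)
  names(pr) <- paste0("prob_", names(pr))
  cbind(df, pr, row.names = NULL)
}

#' Classify new cells with a fitted relabel ensemble
#'
#' Projects new cells into the fit's PC space (after restricting to the
#' genes the fit retained) and averages the stored ensemble's class
#' probabilities.
#'
#' @param object A [relabel()] fit with `keep_models = TRUE`.
#' @param newdata Cells x genes matrix in the same raw units as the
#'   training input; gene set must cover the fit's retained genes.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... Unused.
#' @export
predict.relabel <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$models)) {
    stop("fit was built with keep_models = FALSE; refit to predict on new ",
         "cells", call. = FALSE)
  }
  newdata <- as.matrix(newdata)
  if (!all(object$genes %in% colnames(newdata))) {
    stop("newdata is missing ", sum(!object$genes %in% colnames(newdata)),
         " of the genes used in the fit", call. = FALSE)
  }
  m <- newdata[, object$genes, drop = FALSE]
  if (isTRUE(object$log2_transform)) m <- log2(m + 1)
  scores <- predict(object$reduction, m)
  probs <- Reduce(`+`, lapply(object$models, predict, newdata = scores))
  probs <- probs / length(object$models)
  if (type == "prob") return(probs)
  factor(colnames(probs)[max.col(probs, ties.method = "first")],
         levels = colnames(probs))
}

#' Plot a relabel fit in PC space
#'
#' Scatter of the first two principal components, coloured by corrected
#' cell type; relabelled cells are ringed in black.
#'
#' @param x A [relabel()] fit.
#' @param ... Passed to [plot()].
#' @export
plot.relabel <- function(x, ...) {
  s <- x$reduction$scores
  pal <- hcl.colors(nlevels(x$labels), "Dark 3")
  col <- pal[as.integer(x$labels)]
  plot(s[, 1], s[, 2], col = col, pch = 16,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$reduction$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$reduction$explained[2]), ...)
  if (any(x$changed)) {
    points(s[x$changed, 1], s[x$changed, 2], pch = 1, cex = 1.8)
  }
  legend("topright", legend = levels(x$labels), col = pal, pch = 16,
         bty = "n", cex = 0.8)
  invisible(x)
}
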