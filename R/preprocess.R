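#' Log-transform an expression matrix
#'
#' Replaces every value v by log2(v + 1), the variance-stabilising transform
#' conventionally applied to FPKM-scale single-cell matrices before PCA.
#' The matrix `"unit"` attribute is updated to record the transform; calling
#' it again on an already-transformed matrix is an error unless `force`.
#'
#' @param x Non-negative cells x genes matrix.
#' @param force Transform even when the unit tag says it already happened.
#' @return The transformed matrix, unit tag suffixed with `"log2(.+1)"`.
#' @export
log_transform <- function(x, force = FALSE) {
  unit <- attr(x, "unit")
  if (!force && !is.null(unit) && grepl("log", unit, ignore.case = TRUE)) {
    stop("matrix unit tag '", unit, "' indicates it is already ",
         "log-transformed; use force = TRUE to transform anyway",
         call. = FALSE)
  }
  if (any(x < 0)) {
    stop("log_transform requires non-negative values", call. = FALSE)
  }
  out <- log2(x + 1)
  attr(out, "unit") <- paste0("log2(", if (is.null(unit)) "x" else unit, "+1)")
  out
}

#' Remove genes dominated by zeros
#'
#' Drops genes whose fraction of zero-valued cells is strictly greater than
#' `cutoff`. A zero here is an expression value of exactly 0 -- FPKM-style
#' matrices encode non-detection as 0, not NA -- so the default 0.8 removes
#' genes undetected in more than 80% of cells. A gene zero in exactly
#' `cutoff` of cells is retained (strict inequality). Cell set and relative
#' gene order are unchanged; the operation is idempotent.
#'
#' @param x Cells x genes matrix.
#' @param cutoff Zero-fraction threshold in (0, 1].
#' @return The matrix restricted to retained genes.
#' @export
filter_genes <- function(x, cutoff = 0.8) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0, cutoff <= 1)
  zero_frac <- colMeans(x == 0)
  keep <- zero_frac <= cutoff
  if (!any(keep)) {
    stop("all ", ncol(x), " genes exceed the ", cutoff,
         " zero-fraction cutoff; lower the cutoff or skip filtering",
         call. = FALSE)
  }
  out <- x[, keep, drop = FALSE]
  attr(out, "unit") <- attr(x, "unit")
  out
}

#' Choose the number of principal components to retain
#'
#' Implements the clamped cumulative-variance rule: `d` is the smallest
#' number of leading components whose cumulative explained-variance ratio
#' reaches at least `threshold` (70% by default), and the retained count is
#' `d` clamped to `[floor, ceiling]` (10 and 20 by default):
#' `floor` when `d < floor`, `d` when `floor <= d <= ceiling`, `ceiling`
#' when `d > ceiling`. If the cumulative ratio never reaches the threshold,
#' `d` is the full spectrum length before clamping.
#'
#' @param explained Non-increasing vector of per-component explained-variance
#'   fractions.
#' @param threshold Cumulative variance target, in (0, 1].
#' @param floor,ceiling Clamp bounds, `floor <= ceiling`.
#' @return Integer count of components to retain.
#' @export
select_num_pcs <- function(explained, threshold = 0.7, floor = 10L,
                           ceiling = 20L) {
  stopifnot(threshold > 0, threshold <= 1, floor >= 1, floor <= ceiling)
  if (any(explained < -1e-9) || any(explained > 1 + 1e-9)) {
    stop("explained-variance ratios must lie in [0, 1]", call. = FALSE)
  }
  # small tolerance so spectra constructed to cross exactly at d are not
  # missed to floating-point rounding
  d <- match(TRUE, cumsum(explained) >= threshold - 1e-9)
  if (is.na(d)) d <- length(explained)
  as.integer(min(max(d, floor), ceiling))
}

#' Reduce an expression matrix to principal-component scores
#'
#' Runs PCA on the column-centred (not unit-scaled) matrix and keeps the
#' number of components chosen by [select_num_pcs()]. Each component's sign
#' is fixed by forcing its largest-magnitude gene loading to be positive, so
#' scores are reproducible across linear-algebra backends. If the matrix
#' admits fewer components than `pc_floor`, all available components are
#' kept with a warning.
#'
#' @param x Log-transformed, gene-filtered cells x genes matrix with at
#'   least 3 cells.
#' @param variance_threshold,pc_floor,pc_ceiling Passed to
#'   [select_num_pcs()].
#' @return An object of class `"reduced_dims"`: list with `scores`
#'   (cells x npcs), `rotation`, `center`, `explained` (all components),
#'   `d` (unclamped crossing point) and `npcs`.
#' @export
reduce_dims <- function(x, variance_threshold = 0.7, pc_floor = 10L,
                        pc_ceiling = 20L) {
  if (nrow(x) < 3) stop("need at least 3 cells for PCA", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  explained <- vars / sum(vars)
  d <- match(TRUE, cumsum(explained) >= variance_threshold - 1e-9)
  if (is.na(d)) d <- length(explained)
  npcs <- select_num_pcs(explained, variance_threshold, pc_floor, pc_ceiling)
  if (npcs > length(explained)) {
    warning("only ", length(explained), " components available; keeping ",
            "them all", call. = FALSE)
    npcs <- length(explained)
  }
  # deterministic sign: largest-magnitude loading of each component positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    v[which.max(abs(v))] < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  structure(list(
    scores = pc$x[, seq_len(npcs), drop = FALSE],
    rotation = pc$rotation[, seq_len(npcs), drop = FALSE],
    center = pc$center,
    sdev = pc$sdev,
    explained = explained,
    d = as.integer(d),
    npcs = as.integer(npcs)
  ), class = "reduced_dims")
}

#' @export
print.reduced_dims <- function(x, ...) {
  cat("Reduced expression matrix: ", nrow(x$scores), " cells x ", x$npcs,
      " PCs\n", sep = "")
  cat(sprintf(
    "Cumulative variance threshold crossed at d = %d; retained %d PCs (%.1f%% of variance)\n",
    x$d, x$npcs, 100 * sum(x$explained[seq_len(x$npcs)])))
  invisible(x)
}

#' Project new cells into an existing reduced space
#'
#' @param object A `"reduced_dims"` object.
#' @param newdata Cells x genes matrix over the same genes (same order) used
#'   to build the reduction.
#' @param ... Unused.
#' @return Scores matrix `nrow(newdata)` x `npcs`.
#' @export
predict.reduced_dims <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$center)) {
    stop("newdata has ", ncol(newdata), " genes; reduction was built on ",
         length(object$center), call. = FALSE)
  }
  scale(newdata, center = object$center, scale = FALSE) %*% object$rotation
}
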