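#' Simulate a group-structured single-cell expression matrix
#'
#' Generates a count matrix with K cell types from a gamma / log-normal /
#' negative-binomial hierarchy, the statistical silhouette of standard
#' scRNA-seq group simulators:
#'
#' * per-gene baseline mean `lambda_g ~ Gamma(mean_shape, mean_rate)`;
#' * for each (type, gene) pair, with probability `de_prob` the gene is
#'   differentially expressed in that type and receives a multiplicative
#'   log-normal fold change `exp(N(0, de_logfc_scale))`;
#' * per-cell library-size factor `exp(N(0, library_size_sigma))`;
#' * counts `~ NB(mu = lambda_g * DE factor * library factor,
#'   size = 1/dispersion)`, whose intrinsic zeros stand in for dropout;
#' * counts are rescaled per cell to counts-per-million, an FPKM-like unit
#'   under uniform 1 kb pseudo-lengths.
#'
#' Defaults give 100 cells in each of 5 types and a 10% per-type
#' differential-expression probability.
#'
#' @param n_types Number of cell types K (>= 2 for downstream correction;
#'   1 is allowed for null-model checks).
#' @param cells_per_type Cells simulated per type (default 100).
#' @param n_genes Genes per cell (default 10000).
#' @param de_prob Probability a gene is differentially expressed in a given
#'   type (default 0.1).
#' @param de_logfc_scale SD of the log fold change of DE genes (default 1).
#' @param dispersion Negative-binomial dispersion; counts have
#'   `size = 1/dispersion` (default 0.5).
#' @param library_size_sigma SD of the per-cell log library factor
#'   (default 0.2).
#' @param mean_shape,mean_rate Gamma parameters of the baseline gene means
#'   (defaults 0.6 and 0.3).
#' @return List with `expression` (cells x genes matrix, unit tag
#'   `"simulated"`), `labels` (factor of true types, named by cell id),
#'   `de_genes` (K x genes logical matrix of DE assignments) and
#'   `fold_changes` (K x genes matrix of multiplicative factors).
#' @export
simulate_cells <- function(n_types = 5, cells_per_type = 100,
                           n_genes = 10000, de_prob = 0.1,
                           de_logfc_scale = 1, dispersion = 0.5,
                           library_size_sigma = 0.2,
                           mean_shape = 0.6, mean_rate = 0.3) {
  stopifnot(n_types >= 1, cells_per_type >= 1, n_genes >= 1,
            de_prob > 0, de_prob < 1, de_logfc_scale > 0, dispersion > 0,
            library_size_sigma >= 0)
  K <- n_types
  n <- K * cells_per_type
  base <- rgamma(n_genes, shape = mean_shape, rate = mean_rate)
  de <- matrix(runif(K * n_genes) < de_prob, K, n_genes)
  fc <- matrix(1, K, n_genes)
  fc[de] <- exp(rnorm(sum(de), 0, de_logfc_scale))
  lib <- exp(rnorm(n, 0, library_size_sigma))
  type <- rep(seq_len(K), each = cells_per_type)
  mu <- (fc[type, , drop = FALSE] * rep(base, each = n)) * lib
  counts <- matrix(rnbinom(n * n_genes, mu = mu, size = 1 / dispersion),
                   n, n_genes)
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  expr <- counts / tot * 1e6
  dimnames(expr) <- list(paste0("cell", seq_len(n)),
                         paste0("gene", seq_len(n_genes)))
  attr(expr, "unit") <- "simulated"
  labels <- factor(paste0("type", type), levels = paste0("type", seq_len(K)))
  names(labels) <- rownames(expr)
  list(expression = expr, labels = labels, de_genes = de, fold_changes = fc)
}

#' Flip a fixed fraction of each cell type to the next type
#'
#' The benchmark noise model: within every class k, exactly
#' `floor(rho * N_k)` cells chosen uniformly without replacement have their
#' label flipped to the cyclically next class (class K wraps to class 1) in
#' the level order of `truth`. The flip count is exact rather than
#' Bernoulli, so the baseline per-class accuracy is deterministically
#' `1 - floor(rho * N_k) / N_k` (equal to `1 - rho` whenever `rho * N_k`
#' is integral). A flipped label never equals the true one.
#'
#' @param truth Factor of true labels (K >= 2).
#' @param rho Mislabelling fraction in `[0, 0.5]`.
#' @return List with `labels` (noisy factor, same levels and names as
#'   `truth`) and `flipped` (logical mask of altered cells).
#' @export
inject_label_noise <- function(truth, rho) {
  truth <- as.factor(truth)
  stopifnot(rho >= 0, rho <= 0.5, nlevels(truth) >= 2)
  lev <- levels(truth)
  K <- length(lev)
  noisy <- truth
  flipped <- logical(length(truth))
  for (k in seq_len(K)) {
    idx <- which(truth == lev[k])
    nf <- floor(rho * length(idx))
    if (nf > 0) {
      sel <- idx[sample.int(length(idx), nf)]
      noisy[sel] <- lev[k %% K + 1]
      flipped[sel] <- TRUE
    }
  }
  if (!any(flipped) && rho > 0) {
    warning("rho = ", rho, " flips no cells at these class sizes; labels ",
            "returned unchanged", call. = FALSE)
  }
  names(flipped) <- names(truth)
  list(labels = noisy, flipped = flipped)
}
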