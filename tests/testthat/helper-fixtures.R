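# fixtures and independent oracles shared across tests

# K well-separated Gaussian blobs in `dim` dimensions; class centres sit on
# scaled coordinate axes so pairwise distances are `sep`
make_blobs <- function(n_per = 50, K = 3, dim = 10, sep = 10, sd = 1) {
  centers <- matrix(0, K, dim)
  for (k in seq_len(K)) centers[k, k] <- sep / sqrt(2)
  x <- do.call(rbind, lapply(seq_len(K), function(k) {
    matrix(rnorm(n_per * dim, sd = sd), n_per, dim,
           dimnames = list(NULL, paste0("f", seq_len(dim)))) +
      rep(centers[k, ], each = n_per)
  }))
  rownames(x) <- paste0("cell", seq_len(K * n_per))
  y <- factor(rep(paste0("c", seq_len(K)), each = n_per),
              levels = paste0("c", seq_len(K)))
  names(y) <- rownames(x)
  list(x = x, y = y)
}

# a tiny raw expression matrix with ids, for io round trips
tiny_expr <- function(n = 4, m = 6) {
  set.seed(99)
  x <- matrix(round(runif(n * m, 0, 50), 3), n, m,
              dimnames = list(paste0("cell", seq_len(n)),
                              paste0("g", seq_len(m))))
  attr(x, "unit") <- "FPKM"
  x
}

# brute-force mean accuracy: explicit loop over classes (independent of the
# vectorised implementation)
brute_mean_accuracy <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  classes <- unique(truth)
  total <- 0
  for (k in classes) {
    idx <- which(truth == k)
    hits <- 0
    for (i in idx) if (pred[i] == k) hits <- hits + 1
    total <- total + hits / length(idx)
  }
  total / length(classes)
}

# brute-force ARI: explicit double loop over all cell pairs, counting the
# four pair categories and applying the pair-count formula
brute_ari <- function(a_labels, b_labels) {
  a_labels <- as.character(a_labels); b_labels <- as.character(b_labels)
  n <- length(a_labels)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same1 <- a_labels[i] == a_labels[j]
      same2 <- b_labels[i] == b_labels[j]
      if (same1 && same2) a <- a + 1
      else if (same1) b <- b + 1
      else if (same2) cc <- cc + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(if (b == 0 && cc == 0) 1 else 0)
  2 * (a * d - b * cc) / denom
}
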