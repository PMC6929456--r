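test_that("simulator emits a valid labelled matrix with DE structure", {
  set.seed(41)
  sim <- simulate_cells(n_types = 5, cells_per_type = 20, n_genes = 2000)
  expect_equal(dim(sim$expression), c(100, 2000))
  expect_true(all(sim$expression >= 0))
  expect_identical(attr(sim$expression, "unit"), "simulated")
  expect_equal(as.vector(table(sim$labels)), rep(20, 5))
  expect_identical(names(sim$labels), rownames(sim$expression))
  # DE gene count per type follows the binomial oracle:
  # n_genes * de_prob +- 3 * sqrt(n_genes * p * (1 - p))
  p <- 0.1
  bound <- 3 * sqrt(2000 * p * (1 - p))
  expect_true(all(abs(rowSums(sim$de_genes) - 2000 * p) < bound))
  # non-DE (type, gene) pairs keep fold change exactly 1
  expect_true(all(sim$fold_changes[!sim$de_genes] == 1))
})

test_that("single-type simulation has no group structure on PC1", {
  set.seed(42)
  sim <- simulate_cells(n_types = 1, cells_per_type = 60, n_genes = 500)
  x <- log_transform(filter_genes(sim$expression))
  red <- reduce_dims(x, pc_floor = 1L, pc_ceiling = 5L)
  # permutation test: PC1 shift between two random halves is unremarkable
  half <- sample(rep(c(TRUE, FALSE), 30))
  obs <- abs(mean(red$scores[half, 1]) - mean(red$scores[!half, 1]))
  null <- replicate(500, {
    h <- sample(half)
    abs(mean(red$scores[h, 1]) - mean(red$scores[!h, 1]))
  })
  expect_gt(mean(null >= obs), 0.01)
})

test_that("between-type separation grows from the no-signal limit", {
  # statistic: mean |difference of type-wise mean log expression| over
  # expressed genes, relative to the same contrast between two random
  # halves of one type (the pure-noise reference; the sqrt(2) corrects for
  # the halved group size). Near the de_prob -> 0 limit the ratio is ~1;
  # with substantial DE it must clearly exceed it.
  set.seed(43)
  ratio_for <- function(de_prob) {
    sim <- simulate_cells(n_types = 2, cells_per_type = 60, n_genes = 800,
                          de_prob = de_prob)
    lx <- log2(sim$expression + 1)
    lx <- lx[, colMeans(lx) > 1]
    g1 <- sim$labels == "type1"
    between <- mean(abs(colMeans(lx[g1, ]) - colMeans(lx[!g1, ])))
    h <- rep(c(TRUE, FALSE), length.out = sum(g1))
    within <- mean(abs(colMeans(lx[which(g1)[h], ]) -
                         colMeans(lx[which(g1)[!h], ]))) / sqrt(2)
    between / within
  }
  expect_lt(ratio_for(0.002), 1.3)
  expect_gt(ratio_for(0.3), 1.8)
})

test_that("simulated matrices pass preprocessing with most genes intact", {
  set.seed(44)
  sim <- simulate_cells(n_types = 3, cells_per_type = 40, n_genes = 1000)
  kept <- filter_genes(sim$expression, 0.8)
  expect_gte(ncol(kept) / 1000, 0.5)
})

test_that("label flipping is exact, cyclic, and never a self-map", {
  for (K in c(3, 5, 7, 9)) {
    for (rho in seq(0.1, 0.5, by = 0.1)) {
      set.seed(100 * K + round(10 * rho))
      truth <- factor(rep(paste0("t", seq_len(K)), each = 100),
                      levels = paste0("t", seq_len(K)))
      noisy <- inject_label_noise(truth, rho)
      nf <- floor(rho * 100)
      for (k in seq_len(K)) {
        in_k <- truth == paste0("t", k)
        flipped_k <- noisy$flipped & in_k
        expect_equal(sum(flipped_k), nf)
        # all flips go to the cyclically next type
        expect_true(all(noisy$labels[flipped_k] == paste0("t", k %% K + 1)))
        expect_true(all(noisy$labels[in_k & !noisy$flipped] == paste0("t", k)))
      }
      expect_true(all(noisy$labels[noisy$flipped] != truth[noisy$flipped]))
      # baseline mean accuracy is deterministically 1 - rho here
      expect_equal(mean_accuracy(noisy$labels, truth), 1 - rho)
    }
  }
})

test_that("flip edge cases: rho = 0 and sub-single-flip rates", {
  truth <- factor(rep(c("a", "b"), each = 9))
  out <- inject_label_noise(truth, 0)
  expect_identical(out$labels, truth)
  expect_false(any(out$flipped))
  expect_warning(out2 <- inject_label_noise(truth, 0.05), "flips no cells")
  expect_identical(out2$labels, truth)
})

test_that("baseline ARI decreases strictly with the noise rate", {
  set.seed(46)
  truth <- factor(rep(paste0("t", 1:5), each = 100))
  aris <- vapply(seq(0.1, 0.5, by = 0.1), function(rho) {
    adjusted_rand_index(inject_label_noise(truth, rho)$labels, truth)
  }, numeric(1))
  expect_true(all(diff(aris) < 0))
})
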