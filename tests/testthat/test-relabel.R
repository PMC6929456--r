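# small desk-scale simulation reused by several blocks
fit_small <- function(seed, rho = 0.2, classifier = "svm", ...) {
  set.seed(seed)
  sim <- simulate_cells(n_types = 3, cells_per_type = 40, n_genes = 600)
  noisy <- inject_label_noise(sim$labels, rho)
  fit <- relabel(sim$expression, noisy$labels, classifier = classifier,
                 ensemble = 5, ...)
  list(sim = sim, noisy = noisy, fit = fit)
}

test_that("the fit corrects most planted flips on separable simulations", {
  r <- fit_small(61)
  restored <- r$fit$labels[r$noisy$flipped] == r$sim$labels[r$noisy$flipped]
  expect_gt(mean(restored), 0.5)
  expect_gt(mean_accuracy(fitted(r$fit), r$sim$labels),
            mean_accuracy(r$noisy$labels, r$sim$labels))
})

test_that("the fit object is coherent", {
  r <- fit_small(62, classifier = "rf", ntree = 60)
  fit <- r$fit
  expect_s3_class(fit, "relabel")
  expect_identical(levels(fit$labels), levels(fit$initial))
  expect_identical(unname(fit$changed),
                   unname(fit$labels != fit$initial))
  expect_equal(rowSums(fit$probabilities), rep(1, length(fit$labels)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(fit$epsilon >= 0 & fit$epsilon <= 1))
  expect_true(fit$reduction$npcs >= 10 && fit$reduction$npcs <= 20)
  # corrected labels are the row argmax (up to the conservative tie rule)
  amax <- colnames(fit$probabilities)[max.col(fit$probabilities,
                                              ties.method = "first")]
  ties <- abs(apply(fit$probabilities, 1, max) -
                fit$probabilities[cbind(seq_along(amax),
                                        as.integer(fit$initial))]) < 1e-12
  expect_identical(as.character(fit$labels)[!ties], amax[!ties])
  expect_output(print(fit), "Post hoc")
  expect_output(print(summary(fit)), "transitions")
  df <- as.data.frame(fit)
  expect_equal(nrow(df), length(fit$labels))
})

test_that("ensemble of one reduces to the single-model variant", {
  set.seed(63)
  sim <- simulate_cells(n_types = 3, cells_per_type = 30, n_genes = 400)
  noisy <- inject_label_noise(sim$labels, 0.2)
  fit <- relabel(sim$expression, noisy$labels, ensemble = 1)
  expect_equal(rowSums(fit$probabilities), rep(1, 90), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_s3_class(fit$labels, "factor")
})

test_that("relabel is bit-reproducible end to end under a fixed seed", {
  set.seed(64)
  sim <- simulate_cells(n_types = 3, cells_per_type = 30, n_genes = 400)
  noisy <- inject_label_noise(sim$labels, 0.2)
  for (kind in c("svm", "rf")) {
    set.seed(123)
    f1 <- relabel(sim$expression, noisy$labels, classifier = kind,
                  ensemble = 3, keep_models = FALSE)
    set.seed(123)
    f2 <- relabel(sim$expression, noisy$labels, classifier = kind,
                  ensemble = 3, keep_models = FALSE)
    expect_identical(f1$labels, f2$labels)
    expect_identical(f1$probabilities, f2$probabilities)
    expect_identical(f1$epsilon, f2$epsilon)
  }
})

test_that("correction quality is invariant under class renaming", {
  set.seed(65)
  sim <- simulate_cells(n_types = 3, cells_per_type = 30, n_genes = 400)
  noisy <- inject_label_noise(sim$labels, 0.2)
  ren <- c(type1 = "beta", type2 = "alpha", type3 = "omega")
  y2 <- factor(ren[as.character(noisy$labels)], levels = unname(ren))
  names(y2) <- names(noisy$labels)
  set.seed(9)
  f1 <- relabel(sim$expression, noisy$labels, ensemble = 3,
                keep_models = FALSE)
  set.seed(9)
  f2 <- relabel(sim$expression, y2, ensemble = 3, keep_models = FALSE)
  expect_identical(unname(ren[as.character(f1$labels)]),
                   as.character(f2$labels))
  expect_equal(f1$epsilon, f2$epsilon, tolerance = 1e-12)
})

test_that("named labels are aligned to matrix rows; misalignment errors", {
  set.seed(66)
  sim <- simulate_cells(n_types = 2, cells_per_type = 20, n_genes = 200)
  shuffled <- sample(sim$labels)
  set.seed(1); f1 <- relabel(sim$expression, sim$labels, ensemble = 2,
                             iters = 1, keep_models = FALSE)
  set.seed(1); f2 <- relabel(sim$expression, shuffled, ensemble = 2,
                             iters = 1, keep_models = FALSE)
  expect_identical(f1$initial, f2$initial)
  bad <- sim$labels
  names(bad) <- paste0("other", seq_along(bad))
  expect_error(relabel(sim$expression, bad), "cell ids")
  expect_error(relabel(sim$expression, unname(sim$labels)[-1]), "labels")
  expect_error(relabel(sim$expression, rep("a", nrow(sim$expression))),
               "two cell types")
})

test_that("min_prob keeps the initial label for unconfident cells", {
  r <- fit_small(67, min_prob = 1)   # unreachable confidence: nothing moves
  expect_false(any(r$fit$changed))
})

test_that("a kept-model fit predicts its own training cells consistently", {
  r <- fit_small(68, keep_models = TRUE)
  pred <- predict(r$fit, r$sim$expression, type = "class")
  agree <- mean(pred == r$fit$labels)
  expect_gt(agree, 0.95)
  pr <- predict(r$fit, r$sim$expression, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6,
               ignore_attr = TRUE)
})
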