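# small shared fixtures: a quick reference table and a synthetic
# regression problem (built once; reused across blocks)
small_cfg <- cell_config(0.7, 15, N = 100, n = 20)
small_tab <- abc_reference_table(abc_priors(), R = 150, config = small_cfg,
                                 seed = 321)

synth <- local({
  set.seed(99)
  R <- 400; d <- 6
  X <- matrix(rnorm(R * d), R, d,
              dimnames = list(NULL, paste0("s", 1:d)))
  Y <- cbind(a = X[, 1] + 0.5 * X[, 2] + rnorm(R, sd = 0.3),
             b = X[, 2] - X[, 3] + rnorm(R, sd = 0.3))
  list(X = X, Y = Y)
})

test_that("reference tables have the documented shape and reproducibility", {
  tab <- abc_reference_table(abc_priors(), R = 10, config = small_cfg,
                             seed = 7)
  expect_s3_class(tab, "abc_reftable")
  expect_equal(dim(tab), c(10L, 13L))
  expect_identical(colnames(tab)[1:2], c("p", "theta"))
  expect_true(all(tab$p > 0.5 & tab$p < 0.8))
  expect_true(all(tab$theta > 10 & tab$theta < 20))
  tab2 <- abc_reference_table(abc_priors(), R = 10, config = small_cfg,
                              seed = 7)
  expect_identical(tab, tab2)
  # rows are reproducible in isolation: a 3-row table is the head of a
  # 10-row table built from the same seed
  tab3 <- abc_reference_table(abc_priors(), R = 3, config = small_cfg,
                              seed = 7)
  expect_equal(tab3$S, tab$S[1:3])
})

test_that("table marginals show the conditioning bias on p but not on theta", {
  expect_gt(stats::ks.test(small_tab$theta, "punif", 10, 20)$p.value, 0.01)
  # survival conditioning biases p upward: realized p stochastically
  # larger than its uniform prior (one-sided: ecdf below the uniform CDF)
  u <- stats::punif(small_tab$p, 0.5, 0.8)
  expect_lt(stats::ks.test(u, "punif", alternative = "less")$p.value,
            0.05)
  expect_gt(mean(u), 0.5)
})

test_that("rejection ABC reduces to the prior sample and to exact matching", {
  obs <- as.numeric(small_tab[3, summary_columns(small_tab)])
  fit1 <- abc_fit(small_tab, obs, method = "rejection",
                  accept_fraction = 1)
  expect_true(all(abs(weights(fit1) - 1 / nrow(small_tab)) < 1e-12))
  fit2 <- abc_fit(small_tab, obs, method = "rejection",
                  accept_fraction = 1 / nrow(small_tab))
  expect_equal(weights(fit2)[3], 1)
  expect_error(abc_fit(small_tab[0, ], obs, method = "rejection"),
               "empty")
})

test_that("forest weights are a proper distribution and degenerate correctly", {
  R <- nrow(synth$X)
  f1 <- bd_forest(synth$X, synth$Y[, 1], num_trees = 1, min_leaf = R,
                  seed = 5)
  w <- forest_weights(f1, rnorm(ncol(synth$X)))
  expect_true(all(abs(w - 1 / R) < 1e-12))     # single all-root tree
  fr <- bd_forest(synth$X, synth$Y, num_trees = 60, seed = 6)
  for (k in 1:5) {
    w <- forest_weights(fr, rnorm(ncol(synth$X)))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(forest_weights(fr, rnorm(3)), "covariates")
  expect_error(bd_forest(synth$X, rep(1, R), num_trees = 5), "degenerate")
})

test_that("out-of-bag error decreases with ensemble size", {
  fr <- bd_forest(synth$X, synth$Y[, 1], num_trees = 200, seed = 8)
  expect_gt(oob_error(fr, 1), oob_error(fr, 200))
  expect_gt(oob_error(fr, 5), oob_error(fr, 200))
})

test_that("univariate forest agrees with an independent implementation", {
  # ranger as external cross-check of OOB behaviour, never the implementation
  fr <- bd_forest(synth$X, synth$Y[, 1], num_trees = 200, seed = 9)
  ours <- oob_predict(fr)[, 1]
  rf <- ranger::ranger(y ~ ., data = data.frame(synth$X, y = synth$Y[, 1]),
                       num.trees = 200, min.node.size = 5, seed = 1)
  theirs <- rf$predictions
  ok <- !is.na(ours)
  expect_gt(cor(ours[ok], theirs[ok]), 0.9)
})

test_that("permutation importance finds signal and ignores noise", {
  fr <- bd_forest(synth$X, synth$Y, num_trees = 120, seed = 10)
  imp <- forest_importance(fr, seed = 11)
  expect_setequal(names(imp), paste0("s", 1:6))
  expect_true(all(c("s1", "s2", "s3") %in% names(imp)[1:3]))
  # pure-noise columns change OOB error by ~0
  expect_lt(max(abs(imp[c("s4", "s5", "s6")])), 0.1 * max(imp))
  # stability across seeds
  fr2 <- bd_forest(synth$X, synth$Y, num_trees = 120, seed = 20)
  imp2 <- forest_importance(fr2, seed = 21)
  expect_gt(cor(imp[paste0("s", 1:6)], imp2[paste0("s", 1:6)],
                method = "spearman"), 0.7)
})

test_that("posterior summaries behave like weighted empirical quantities", {
  x <- c(5, 1, 3, 2, 4)
  w <- rep(0.2, 5)
  expect_equal(unname(weighted_quantile(x, w, 0)), 1)
  expect_equal(unname(weighted_quantile(x, w, 1)), 5)
  probs <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(unname(weighted_quantile(x, w, probs)),
               unname(quantile(x, probs, type = 1)))
  # zero-weight support is excluded
  expect_equal(unname(weighted_quantile(c(0, x), c(0, w), 0)), 1)
})

test_that("ABC fits recover parameters and report coherent posteriors", {
  obs <- simulate_cell_dataset(cell_config(0.7, 12, N = 100, n = 20),
                               seed = 404)
  drf <- abc_fit(small_tab, obs, method = "drf", num_trees = 100,
                 seed = 12)
  expect_s3_class(drf, "bd_abc")
  expect_equal(sum(weights(drf)), 1, tolerance = 1e-12)
  cm <- coef(drf)
  expect_true(cm[["theta"]] > 10 && cm[["theta"]] < 20)
  sm <- summary(drf)
  expect_true(sm$table["theta", "lower"] <= sm$table["theta", "median"])
  expect_true(sm$table["theta", "median"] <= sm$table["theta", "upper"])
  # rf marginal broadly comparable to the drf marginal
  rf <- abc_fit(small_tab, obs, method = "rf", param = "theta",
                num_trees = 100, seed = 13)
  expect_lt(abs(coef(rf)[["theta"]] - cm[["theta"]]), 3)
  qq <- posterior_qq(rf, drf, "theta")
  expect_true(all(diff(qq$q1) >= 0) && all(diff(qq$q2) >= 0))
  expect_error(abc_fit(small_tab, obs[-1]), "11 values")
  expect_error(variable_importance(abc_fit(small_tab, obs,
                                           method = "rejection")),
               "forest")
})

test_that("posterior densities and plots are produced without error", {
  obs <- as.numeric(small_tab[5, summary_columns(small_tab)])
  fit <- abc_fit(small_tab, obs, method = "drf", num_trees = 50, seed = 14)
  d <- posterior_density(fit, "theta")
  expect_s3_class(d, "density")
  kd <- posterior_joint_density(fit, n = 20, resample = 500, seed = 15)
  expect_equal(dim(kd$z), c(20L, 20L))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
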