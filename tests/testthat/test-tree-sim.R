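test_that("complete-tree simulation satisfies the structural invariants", {
  set.seed(3)
  for (k in 1:50) {
    tr <- simulate_complete_tree(bd_params(1, 0.6), t = 1.5)
    nd <- tr$nodes
    # binary splits: every split node has exactly two children
    kids <- tabulate(nd$parent[!is.na(nd$parent)], nbins = nrow(nd))
    expect_true(all(kids[nd$reason == "split"] == 2))
    expect_true(all(kids[nd$reason != "split"] == 0))
    # child birth equals parent split time
    ch <- which(!is.na(nd$parent))
    expect_equal(nd$birth[ch], nd$end[nd$parent[ch]])
    expect_true(all(nd$birth >= 0 & nd$end <= 1.5))
    # accounting: terminal nodes = splits + founders
    expect_equal(sum(nd$reason != "split"), sum(nd$reason == "split") + 1L)
  }
})

test_that("extant-leaf counts of pure-birth trees follow the Yule law", {
  set.seed(5)
  reps <- 5000
  counts <- vapply(seq_len(reps), function(i) {
    n_extant(simulate_complete_tree(bd_params(1), t = 1))
  }, integer(1))
  expect_gt(chisq_gof(tabulate(counts, 15), dyule(1:15, 1, 1), n = reps), 0.01)
})

test_that("first event time of a single lineage is exponential(lambda + mu)", {
  set.seed(9)
  first <- replicate(3000, {
    tr <- simulate_complete_tree(bd_params(1, 2), t = 8)
    tr$nodes$end[1]
  })
  first <- first[first < 8]     # censoring mass e^{-24}, negligible
  ks <- stats::ks.test(first, stats::pexp, rate = 3)
  expect_gt(ks$p.value, 0.01)
})

test_that("pruning preserves extant leaves and yields an ultrametric tree", {
  set.seed(21)
  for (k in 1:300) {
    tr <- simulate_complete_tree(bd_params(1, 0.7), t = 1)
    rec <- prune_to_reconstructed(tr)
    if (is.null(rec)) {
      expect_identical(n_extant(tr), 0L)
    } else {
      expect_equal(n_extant(rec), n_extant(tr))
      leaves <- rec$nodes[rec$nodes$reason == "observed", ]
      expect_true(all(leaves$end == 1))   # exact, times carried not re-derived
      # sampled leaf labels survive pruning
      orig <- tr$nodes$label[tr$nodes$reason == "observed"]
      expect_setequal(leaves$label, orig)
    }
  }
})

test_that("pruning a pure-birth tree only relabels: split times are unchanged", {
  set.seed(2)
  tr <- simulate_complete_tree(bd_params(1.2), t = 1.5)
  rec <- prune_to_reconstructed(tr)
  expect_equal(split_times_of(rec), split_times_of(tr))
  expect_equal(nrow(rec$nodes), nrow(tr$nodes))
})

test_that("pruning rejects reconstructed input and maps extinction to NULL", {
  rec <- simulate_reconstructed_tree(4, 1, bd_params(1), seed = 1)
  expect_error(prune_to_reconstructed(rec), "complete")
  set.seed(8)
  repeat {   # find an extinct tree (mu >> lambda makes this quick)
    tr <- simulate_complete_tree(bd_params(0.5, 3), t = 5)
    if (n_extant(tr) == 0) break
  }
  expect_null(prune_to_reconstructed(tr))
})

test_that("Yule split-time sampler has the stated transform and law", {
  # transform endpoints
  lam <- 1; t <- 1
  expect_equal(log(exp(lam * t) * 0 + 1) / lam, 0)
  expect_equal(log(exp(lam * t) * 1 + 0) / lam, t)
  s <- yule_split_times(200, t = 1, lambda = 1, seed = 4)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
  set.seed(13)
  draws <- yule_split_times(10001, t = 1, lambda = 1)
  ks <- stats::ks.test(draws, yule_split_cdf, t = 1, lam = 1)
  expect_gt(ks$p.value, 0.01)
  expect_error(yule_split_times(1, 1, 1), ">= 2")
})

test_that("reconstructed split CDF has exact endpoints and the Yule reduction", {
  p <- bd_params(1, 0.5)
  expect_equal(bd_split_cdf(0, 1, p), 0)
  expect_equal(bd_split_cdf(1, 1, p), 1)
  u <- seq(0, 1, by = 0.01)
  g <- bd_split_cdf(u, 1, bd_params(2))
  expect_equal(g, yule_split_cdf(u, 1, 2), tolerance = 1e-12)
  expect_true(all(diff(bd_split_cdf(u, 1, p)) > 0))
  expect_error(bd_split_cdf(1.5, 1, p), "\\[0, t\\]")
})

test_that("differencing the split CDF recovers the stated density", {
  p <- bd_params(1, 0.5); t <- 1
  u <- seq(0.05, 0.95, by = 0.05)
  h <- 1e-4
  dens_num <- (bd_split_cdf(u + h, t, p) - bd_split_cdf(u - h, t, p)) /
    (2 * h)
  ba_t <- bd_beta_alpha(t, p)
  ba <- bd_beta_alpha(t - u, p)
  dens <- p$lambda * (1 - ba$alpha) * (1 - ba$beta) / ba_t$beta
  expect_equal(dens_num, dens, tolerance = 1e-6)
})

test_that("quantile function inverts the split CDF", {
  p <- bd_params(1.3, 0.9)
  pr <- seq(0, 1, by = 0.05)
  u <- bd_split_quantile(pr, 2, p)
  expect_equal(bd_split_cdf(u, 2, p), pr, tolerance = 1e-10)
})

test_that("direct reconstructed-tree sampler has the required shape and laws", {
  p <- bd_params(1, 0.5)
  tr <- simulate_reconstructed_tree(7, 1, p, seed = 2)
  nd <- tr$nodes
  expect_equal(sum(nd$reason == "split"), 6L)
  expect_equal(sum(nd$reason == "observed"), 7L)
  expect_true(all(nd$end[nd$reason == "observed"] == 1))
  # mu = 0: split-time law indistinguishable from the Yule transform sampler
  set.seed(31)
  a <- as.vector(replicate(2500, split_times_of(
    simulate_reconstructed_tree(3, 1, bd_params(1)))))
  b <- as.vector(replicate(2500, yule_split_times(3, 1, 1)))
  expect_gt(suppressWarnings(stats::ks.test(a, b))$p.value, 0.01)
})

test_that("smallest split time follows the minimum-order-statistic law", {
  p <- bd_params(1, 0.5); t <- 1; n <- 5
  set.seed(17)
  mins <- replicate(4000, min(split_times_of(
    simulate_reconstructed_tree(n, t, p))))
  cdf_min <- function(x) 1 - (1 - bd_split_cdf(x, t, p))^(n - 1)
  ks <- stats::ks.test(mins, cdf_min)
  expect_gt(ks$p.value, 0.01)
})

test_that("rejection-conditioned complete trees match the direct sampler", {
  # the naive rejection oracle, retained in tests only
  set.seed(23)
  p <- bd_params(1, 0.5); t <- 1; n <- 3
  rej <- rejection_conditioned_splits(p, t, n, 1500)
  dir <- t(replicate(1500, split_times_of(
    simulate_reconstructed_tree(n, t, p))))
  for (j in 1:(n - 1)) {
    expect_gt(suppressWarnings(stats::ks.test(rej[, j],
                                              dir[, j]))$p.value, 0.01)
  }
})
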