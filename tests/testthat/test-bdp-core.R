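test_that("Yule pmf matches its closed form at forced points", {
  expect_equal(dyule(1, t = 0, lambda = 1), 1)
  # e^{-lambda t} = 1/2 forces a geometric(1/2) law
  expect_equal(dyule(1:10, t = log(2), lambda = 1), 2^-(1:10))
  # r = 1 start reduces the negative binomial to the geometric
  expect_equal(dyule(1:20, t = 0.7, lambda = 1.3, z0 = 1),
               dyule(1:20, t = 0.7, lambda = 1.3))
  # no splits in any of r lines
  expect_equal(dyule(3, t = 2, lambda = 0.4, z0 = 3), exp(-3 * 0.4 * 2))
  expect_equal(dyule(2, t = 1, lambda = 1, z0 = 3), 0)
})

test_that("negative binomial start equals the brute-force convolution of geometrics", {
  # two independent lines: P(Z = n | r = 2) by exhaustive summation
  t <- 1; lam <- 1
  geo <- function(k) exp(-lam * t) * (1 - exp(-lam * t))^(k - 1)
  conv4 <- sum(vapply(1:3, function(k) geo(k) * geo(4 - k), numeric(1)))
  expect_equal(dyule(4, t, lam, z0 = 2), conv4, tolerance = 1e-12)
})

test_that("Yule pmf mean, variance and normalization agree with the geometric law", {
  for (pars in list(c(1, 1), c(0.5, 2), c(2, 0.6))) {
    t <- pars[1]; lam <- pars[2]
    nmax <- bdp_truncation(t, bd_params(lam), 1e-14)
    n <- seq_len(max(nmax, 50))
    p <- dyule(n, t, lam)
    tail_mass <- (1 - exp(-lam * t))^max(n)
    expect_equal(sum(p) + tail_mass, 1, tolerance = 1e-12)
    m <- exp(lam * t)
    expect_equal(sum(n * p), m, tolerance = 1e-9)
    expect_equal(sum(n^2 * p) - m^2, m * (m - 1), tolerance = 1e-7)
  }
})

test_that("Yule pmf matches event-driven simulation frequencies", {
  set.seed(4242)
  reps <- 30000
  z <- bdtree:::cpp_bd_final_sizes(1, 0, 1, 1, reps)
  p3 <- dyule(3, 1, 1)
  se <- sqrt(p3 * (1 - p3) / reps)
  expect_lt(abs(mean(z == 3) - p3), 3 * se)
  expect_gt(chisq_gof(tabulate(z, 15), dyule(1:15, 1, 1), n = reps), 0.01)
})

test_that("beta/alpha satisfy their defining identities", {
  ba0 <- bd_beta_alpha(0, bd_params(2, 1))
  expect_identical(ba0$beta, 0); expect_identical(ba0$alpha, 0)
  ba <- bd_beta_alpha(1, bd_params(1, 1))
  expect_equal(ba$beta, 0.5); expect_equal(ba$alpha, 0.5)
  # mu = 0: beta = 1 - e^{-lambda t}, alpha = 0
  expect_equal(bd_beta_alpha(1.4, bd_params(0.8))$beta,
               1 - exp(-0.8 * 1.4), tolerance = 1e-12)
  expect_identical(bd_beta_alpha(1.4, bd_params(0.8))$alpha, 0)
  # alpha = (mu/lambda) beta in the noncritical case
  ba <- bd_beta_alpha(2, bd_params(1.5, 0.4))
  expect_equal(ba$alpha, 0.4 / 1.5 * ba$beta)
  # derivative identity d beta/dt = lambda (1 - alpha)(1 - beta)
  p <- bd_params(1, 0.5); h <- 1e-6
  num <- (bd_beta_alpha(1 + h, p)$beta - bd_beta_alpha(1 - h, p)$beta) /
    (2 * h)
  ba <- bd_beta_alpha(1, p)
  expect_equal(num, p$lambda * (1 - ba$alpha) * (1 - ba$beta),
               tolerance = 1e-6)
})

test_that("beta/alpha are continuous across the critical case", {
  t <- 1.3
  crit <- bd_beta_alpha(t, bd_params(1, 1))$beta
  for (eps in c(1e-8, -1e-8, 1e-9, -1e-9)) {
    near <- bd_beta_alpha(t, bd_params(1, 1 + eps))$beta
    expect_equal(near, crit, tolerance = 1e-6)
  }
})

test_that("BDP size law has the stated mass at 0, normalization and mean", {
  p <- bd_params(1, 0.5)
  ba <- bd_beta_alpha(1, p)
  expect_equal(dbdp(0, 1, p), ba$alpha)
  m <- 0:bdp_truncation(1, p, 1e-16)
  pm <- dbdp(m, 1, p)
  expect_equal(sum(pm), 1, tolerance = 1e-12)
  expect_equal(sum(m * pm), exp((1 - 0.5) * 1), tolerance = 1e-9)
  # mu = 0 reduces to the Yule law with no extinction mass
  expect_equal(dbdp(1:10, 0.8, bd_params(1.2)), dyule(1:10, 0.8, 1.2))
  expect_equal(dbdp(0, 0.8, bd_params(1.2)), 0)
})

test_that("long-horizon extinction mass approaches min(1, mu/lambda)", {
  expect_equal(dbdp(0, 60, bd_params(1, 2)), 1, tolerance = 1e-6)
  expect_equal(dbdp(0, 60, bd_params(2, 1)), 0.5, tolerance = 1e-6)
})

test_that("BDP law matches event-driven simulation in total variation", {
  set.seed(7)
  reps <- 30000
  z <- bdtree:::cpp_bd_final_sizes(1, 0.5, 1, 1, reps)
  emp <- tabulate(z + 1, 31) / reps
  thr <- dbdp(0:30, 1, bd_params(1, 0.5))
  expect_lt(0.5 * sum(abs(emp - thr)) + 0.5 * (1 - sum(thr)), 0.02)
})

test_that("extinction probability matches the closed form and the long-run p10", {
  expect_equal(extinction_prob(bd_params(1, 2)), 1)
  expect_equal(extinction_prob(bd_params(1, 1)), 1)
  expect_equal(extinction_prob(bd_params(2, 1)), 0.5)
  expect_equal(extinction_prob(bd_params(2, 1), z0 = 3), 0.125)
  # limit of p10(t)^2 for two founders
  expect_equal(extinction_prob(bd_params(1, 0.5), z0 = 2),
               dbdp(0, 40, bd_params(1, 0.5))^2, tolerance = 1e-3)
})

test_that("time-inhomogeneous Yule law is a time change of the homogeneous one", {
  expect_equal(dyule_inhom(1:12, 1, function(u) rep(0.9, length(u))),
               dyule(1:12, 1, 0.9), tolerance = 1e-9)
  # rate 2u on [0,1] integrates to 1
  expect_equal(dyule_inhom(1:12, 1, function(u) 2 * u),
               dyule(1:12, 1, 1), tolerance = 1e-9)
  expect_error(dyule_inhom(1, 1, function(u) u - 0.5), "nonnegative")
})

test_that("inhomogeneous Yule pmf matches a thinning-based simulation", {
  set.seed(11)
  reps <- 20000
  rate_fn <- function(u) 1 + sin(u)
  z <- bdtree:::cpp_inhom_yule_sizes(rate_fn, 2, 2, reps)
  pr <- dyule_inhom(1:40, 2, rate_fn)
  for (k in c(1, 2, 3, 5)) {
    se <- sqrt(pr[k] * (1 - pr[k]) / reps)
    expect_lt(abs(mean(z == k) - pr[k]), 3 * se)
  }
})

test_that("domain errors are raised on invalid inputs", {
  expect_error(dyule(0, 1, 1), ">= 1")
  expect_error(dyule(1, 1, -1), "> 0")
  expect_error(dyule(1, 1, 1, z0 = 0), ">= 1")
  expect_error(dbdp(-1, 1, bd_params(1)), ">= 0")
  expect_error(extinction_prob(bd_params(1), z0 = 0), ">= 1")
  expect_error(bd_params(0, 1), "> 0")
  expect_error(bd_params(1, -0.1), ">= 0")
})
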