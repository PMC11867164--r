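# Shared test oracles: goodness-of-fit helpers, closed-form CDFs and the
# naive rejection-conditioned tree sampler kept purely as an independent
# reference for the direct order-statistic sampler.

# chi-square GOF p-value of observed counts against probabilities,
# pooling cells so every expected count is >= 5; `n` is the full sample
# size (so the implicit tail cell gets n - sum(obs_counts) observations)
chisq_gof <- function(obs_counts, probs, n = sum(obs_counts)) {
  stopifnot(length(obs_counts) == length(probs))
  keep_tail <- 1 - sum(probs)
  obs <- c(obs_counts, n - sum(obs_counts))
  pr <- c(probs, keep_tail)
  if (pr[length(pr)] <= 0) { obs <- obs[-length(obs)]; pr <- pr[-length(pr)] }
  # pool smallest-expectation cells from the right
  ord <- order(pr * n)
  while (length(pr) > 2 && min(pr * n) < 5) {
    i <- which.min(pr * n)
    j <- if (i == length(pr)) i - 1L else i + 1L
    pr[j] <- pr[j] + pr[i]; obs[j] <- obs[j] + obs[i]
    pr <- pr[-i]; obs <- obs[-i]
  }
  stat <- sum((obs - n * pr)^2 / (n * pr))
  stats::pchisq(stat, df = length(pr) - 1, lower.tail = FALSE)
}

# closed-form CDF of the Yule conditional split-time density
# g(u) = lam e^{-lam(t-u)} / (1 - e^{-lam t})
yule_split_cdf <- function(u, t, lam) {
  expm1(lam * u) / expm1(lam * t)
}

split_times_of <- function(tree) {
  sort(tree$nodes$end[tree$nodes$reason == "split"])
}

# naive rejection sampler: complete trees conditioned on n extant at t,
# pruned to reconstructed, returning a matrix of sorted split times
rejection_conditioned_splits <- function(params, t, n, reps) {
  out <- matrix(NA_real_, reps, n - 1)
  got <- 0L
  while (got < reps) {
    tr <- simulate_complete_tree(params, t)
    if (n_extant(tr) == n) {
      got <- got + 1L
      out[got, ] <- split_times_of(prune_to_reconstructed(tr))
    }
  }
  out
}

# manual 3-leaf ultrametric tree with chosen split times, for mutation
# accounting tests
three_leaf_tree <- function(u1, u2, t) {
  bdtree:::build_tree_from_splits(c(u1, u2), t)
}
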