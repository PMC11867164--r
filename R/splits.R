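#' Conditional split times of a Yule tree
#'
#' Given that a Yule process started from one lineage has `n` lineages at
#' time `t`, the `n - 1` split times are distributed as the increasing
#' order statistics of `n - 1` i.i.d. draws from the density
#' \deqn{g(u) = \frac{\lambda e^{-\lambda(t - u)}}{1 - e^{-\lambda t}},
#'   \quad 0 < u < t.}
#' Draws are produced by the explicit transform
#' \eqn{S = \lambda^{-1}\log(e^{\lambda t}V + 1 - V)} of uniforms `V`.
#'
#' @param n Number of tips, integer `>= 2`.
#' @param t Time horizon, `> 0`.
#' @param lambda Split rate, `> 0`.
#' @param seed Optional integer seed.
#' @return Strictly increasing vector of `n - 1` split times in `(0, t)`.
#' @examples
#' yule_split_times(5, t = 1, lambda = 1, seed = 1)
#' @export
yule_split_times <- function(n, t, lambda, seed = NULL) {
  if (length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (t <= 0 || lambda <= 0) {
    stop("`t` and `lambda` must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  v <- runif(n - 1)
  sort(log(exp(lambda * t) * v + (1 - v)) / lambda)
}

#' Distribution function of a reconstructed-tree split time
#'
#' For a linear BDP observed at time `t`, each of the `n - 1` split times
#' of the reconstructed tree is an i.i.d. draw (before ordering) from the
#' distribution with CDF
#' \deqn{G(u) = 1 - \beta(t - u)/\beta(t), \quad 0 \le u \le t,}
#' whose density is proportional to
#' \eqn{\lambda(1 - \alpha(t-u))(1 - \beta(t-u))}. With `mu = 0` this
#' reduces to the Yule split-time law of [yule_split_times()].
#'
#' @param u Time(s) in `[0, t]`. Vectorized.
#' @param t Time horizon, `> 0`.
#' @param params A [bd_params()] object.
#' @return `G(u)`, nondecreasing with `G(0) = 0`, `G(t) = 1`.
#' @examples
#' bd_split_cdf(c(0, 0.5, 1), t = 1, params = bd_params(1, 0.5))
#' @export
bd_split_cdf <- function(u, t, params) {
  params <- as_bd_params(params)
  if (any(u < 0) || any(u > t)) {
    stop("`u` must lie in [0, t]", call. = FALSE)
  }
  1 - bd_beta_alpha(t - u, params)$beta / bd_beta_alpha(t, params)$beta
}

#' Quantile function of a reconstructed-tree split time
#'
#' Closed-form inverse of [bd_split_cdf()], used for probability-integral
#' -transform sampling: solving \eqn{\beta(s) = (1 - p)\beta(t)} for `s`
#' gives \eqn{u = t - s}.
#'
#' @param p Probability(-ies) in `[0, 1]`.
#' @param t Time horizon, `> 0`.
#' @param params A [bd_params()] object.
#' @return Split time(s) in `[0, t]`.
#' @export
bd_split_quantile <- function(p, t, params) {
  params <- as_bd_params(params)
  if (any(p < 0) || any(p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  lambda <- params$lambda; mu <- params$mu
  b <- (1 - p) * bd_beta_alpha(t, params)$beta
  d <- lambda - mu
  if (abs(d) < .bd_critical_tol * lambda) {
    s <- b / (lambda * (1 - b))
  } else {
    s <- log((lambda - b * mu) / (lambda * (1 - b))) / d
  }
  pmin(pmax(t - s, 0), t)      # clamp float fuzz at the endpoints
}

#' Simulate a reconstructed birth-death tree directly
#'
#' Samples the ultrametric reconstructed tree of a linear BDP conditioned
#' to have `n` extant lineages at time `t`, without simulating (and
#' rejecting) complete trees. The `n - 1` split times are inverse-CDF
#' transforms of uniforms through [bd_split_cdf()], sorted; at each split
#' time a uniformly chosen current lineage bifurcates.
#'
#' @param n Number of tips, integer `>= 2`.
#' @param t Time horizon, `> 0`.
#' @param params A [bd_params()] object.
#' @param seed Optional integer seed.
#' @return A `timed_tree` of flavor `"reconstructed"` with `n` leaves at
#'   depth exactly `t` and the stem retained from time 0.
#' @examples
#' tr <- simulate_reconstructed_tree(5, t = 1, params = bd_params(1, 0.5),
#'                                   seed = 1)
#' n_extant(tr)
#' @export
simulate_reconstructed_tree <- function(n, t, params, seed = NULL) {
  params <- as_bd_params(params)
  if (length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (t <= 0) stop("`t` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- sort(bd_split_quantile(runif(n - 1), t, params))
  # float-resolution ties have probability zero; nudge and warn if seen
  while (any(dup <- duplicated(u))) {
    warning("tied split times at float resolution; perturbing by one ulp")
    u[dup] <- u[dup] * (1 + .Machine$double.eps)
    u <- sort(u)
  }
  build_tree_from_splits(u, t)
}

# Grow the node table forward given ordered split times: at each split a
# uniformly chosen current lineage bifurcates (new lineages labelled in
# creation order).
build_tree_from_splits <- function(u, t) {
  n <- length(u) + 1L
  ntot <- 2L * n - 1L
  parent <- rep(NA_integer_, ntot)
  birth <- numeric(ntot)
  end <- numeric(ntot)
  reason <- character(ntot)
  lineages <- 1L
  nxt <- 2L
  for (ui in u) {
    k <- lineages[sample.int(length(lineages), 1L)]
    end[k] <- ui
    reason[k] <- "split"
    parent[nxt] <- k; parent[nxt + 1L] <- k
    birth[nxt] <- ui; birth[nxt + 1L] <- ui
    lineages <- c(setdiff(lineages, k), nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  end[lineages] <- t
  reason[lineages] <- "observed"
  nodes <- data.frame(id = seq_len(ntot), parent = parent, birth = birth,
                      end = end, reason = reason,
                      label = species_labels(parent),
                      stringsAsFactors = FALSE)
  new_timed_tree(nodes, t, "reconstructed")
}
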