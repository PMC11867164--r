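#' Population-size distribution of the Yule (pure-birth) process
#'
#' Probability that a Yule process with per-capita split rate `lambda`,
#' started from `z0` independent founder lineages, has `n` individuals at
#' time `t`. For `z0 = 1` this is the geometric law
#' \deqn{P(Z(t) = n) = e^{-\lambda t}(1 - e^{-\lambda t})^{n-1},}
#' with mean \eqn{e^{\lambda t}}; for `z0 = r > 1` it is the negative
#' binomial
#' \deqn{P(Z(t) = n) = \binom{n-1}{r-1} e^{-r\lambda t}
#'   (1 - e^{-\lambda t})^{n-r}, \quad n \ge r.}
#'
#' @param n Population size(s), integer `>= 1`. Vectorized.
#' @param t Time, `>= 0`.
#' @param lambda Per-capita split rate, `> 0`.
#' @param z0 Initial number of lineages, integer `>= 1`.
#' @param log Return log-probabilities?
#' @return Probabilities; `0` for `n < z0`.
#' @examples
#' dyule(1:5, t = 1, lambda = 1)
#' sum(dyule(3:60, t = 1, lambda = 1, z0 = 3))   # ~1
#' @export
dyule <- function(n, t, lambda, z0 = 1, log = FALSE) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single finite number >= 0", call. = FALSE)
  }
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0) {
    stop("`lambda` must be a single finite number > 0", call. = FALSE)
  }
  if (length(z0) != 1L || z0 < 1 || z0 != round(z0)) {
    stop("`z0` must be a single integer >= 1", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop("`n` must be integers >= 1", call. = FALSE)
  }
  r <- z0
  lp <- ifelse(n < r, -Inf,
               lchoose(n - 1, r - 1) - r * lambda * t +
                 (n - r) * log1p(-exp(-lambda * t)))
  # 0 * log(0) at t = 0, n = r: define as 0 (point mass at n = r)
  lp[t == 0 & n == r] <- 0
  if (log) lp else exp(lp)
}

#' Population-size distribution of a time-inhomogeneous Yule process
#'
#' A pure-birth process whose per-capita split rate at time `u` is
#' `rate_fn(u)` is a deterministic time-change of the unit-rate Yule
#' process: the size at `t` is geometric with success probability
#' \eqn{e^{-\rho(t)}}, where \eqn{\rho(t) = \int_0^t \lambda(u)\,du}
#' (computed here by adaptive quadrature).
#'
#' @param n Population size(s), integer `>= 1`.
#' @param t Time, `>= 0`.
#' @param rate_fn Vectorized nonnegative rate function of time.
#' @param abs_tol Absolute quadrature tolerance for \eqn{\rho(t)}.
#' @return Probabilities \eqn{P(Z(t) = n \mid Z(0) = 1)}.
#' @examples
#' dyule_inhom(1:4, t = 1, rate_fn = function(u) 2 * u)  # rho = 1
#' @export
dyule_inhom <- function(n, t, rate_fn, abs_tol = 1e-10) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single finite number >= 0", call. = FALSE)
  }
  grid <- seq(0, t, length.out = 101L)
  vals <- rate_fn(grid)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("`rate_fn` must be nonnegative and finite on [0, t]", call. = FALSE)
  }
  rho <- if (t == 0) 0 else {
    stats::integrate(rate_fn, 0, t, abs.tol = abs_tol,
                     subdivisions = 500L)$value
  }
  if (any(n < 1) || any(n != round(n))) {
    stop("`n` must be integers >= 1", call. = FALSE)
  }
  lp <- -rho + (n - 1) * log1p(-exp(-rho))
  lp[rho == 0 & n == 1] <- 0
  exp(lp)
}

#' Population-size distribution of a linear birth-death process
#'
#' Probability that a linear BDP started from a single individual has `m`
#' individuals at time `t`:
#' \deqn{p_{10}(t) = \alpha(t), \qquad
#'   p_{1m}(t) = (1 - \alpha(t))(1 - \beta(t))\beta(t)^{m-1}, \; m \ge 1,}
#' with \eqn{\alpha, \beta} from [bd_beta_alpha()]. The mean is
#' \eqn{e^{(\lambda - \mu)t}} and \eqn{p_{10}(t) \to \min\{1, \mu/\lambda\}}
#' as \eqn{t \to \infty}.
#'
#' @param m Population size(s), integer `>= 0`. Vectorized.
#' @param t Time, `> 0` (at `t = 0` the law degenerates to a point mass
#'   at 1, which is returned).
#' @param params A [bd_params()] object.
#' @param log Return log-probabilities?
#' @return Probabilities.
#' @examples
#' dbdp(0:5, t = 1, params = bd_params(1, 0.5))
#' @export
dbdp <- function(m, t, params, log = FALSE) {
  params <- as_bd_params(params)
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single finite number >= 0", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("`m` must be integers >= 0", call. = FALSE)
  }
  ba <- bd_beta_alpha(t, params)
  beta <- ba$beta; alpha <- ba$alpha
  if (t == 0) {
    lp <- ifelse(m == 1, 0, -Inf)
    return(if (log) lp else exp(lp))
  }
  lp <- ifelse(m == 0, log(alpha),
               log1p(-alpha) + log1p(-beta) + (m - 1) * log(beta))
  # Yule case: beta^0 at m = 1 with log(beta) finite is fine, but
  # mu = 0 gives alpha = 0 -> log(0) = -Inf for m = 0, as it should.
  lp[m == 1 & beta == 0] <- log1p(-alpha)
  if (log) lp else exp(lp)
}

#' Upper truncation point for the BDP/Yule size distribution
#'
#' Smallest `m` such that the geometric tail mass beyond `m` is below
#' `tail_tol`, computed in closed form from the geometric tail
#' \eqn{(1-\alpha)\beta^{m}}.
#'
#' @param t Time.
#' @param params A [bd_params()] object.
#' @param tail_tol Tail mass tolerance.
#' @return Integer truncation point.
#' @export
bdp_truncation <- function(t, params, tail_tol = 1e-12) {
  params <- as_bd_params(params)
  ba <- bd_beta_alpha(t, params)
  beta <- ba$beta
  if (beta == 0) return(1L)
  # tail beyond m (sizes > m): (1 - alpha) * beta^m
  m <- ceiling((log(tail_tol) - log1p(-ba$alpha)) / log(beta))
  as.integer(max(1, m))
}
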