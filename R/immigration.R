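#' Expected number of families of a given size under Poisson immigration
#'
#' Families arrive as a homogeneous Poisson process of rate `theta` and
#' each grows as an independent linear BDP from a single individual. By
#' the Poisson marking theorem the number \eqn{C_j(t)} of families of
#' size `j` at time `t` is Poisson with mean
#' \deqn{E C_j(t) = \theta \int_0^t p_{1j}(t - u)\,du
#'   = \frac{\theta}{\lambda}\frac{\beta(t)^j}{j}, \quad j \ge 1.}
#' For `j = 0` the mean \eqn{\theta t + (\theta/\lambda)\log(1 - \beta(t))}
#' is the expected number of families that have arrived and died out by
#' `t` (a cumulative count, so it grows with `t`).
#'
#' @param j Family size(s), integer `>= 0`. Vectorized.
#' @param theta Immigration rate, `> 0`.
#' @param params A [bd_params()] object for the family growth.
#' @param t Time horizon, `>= 0`.
#' @param method `"closed"` for the explicit formula, `"quadrature"` to
#'   integrate \eqn{\theta p_{1j}(t-u)} numerically (cross-check path).
#' @return Expected counts.
#' @examples
#' expected_family_count(1:5, theta = 2, params = bd_params(1, 0.5), t = 1)
#' @export
expected_family_count <- function(j, theta, params, t,
                                  method = c("closed", "quadrature")) {
  method <- match.arg(method)
  params <- as_bd_params(params)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (any(j < 0) || any(j != round(j))) {
    stop("`j` must be integers >= 0", call. = FALSE)
  }
  if (method == "quadrature") {
    return(vapply(j, function(jj) {
      f <- function(v) vapply(v, function(vv) dbdp(jj, vv, params),
                              numeric(1))
      theta * stats::integrate(f, 0, t, rel.tol = 1e-9)$value
    }, numeric(1)))
  }
  beta <- bd_beta_alpha(t, params)$beta
  kappa <- theta / params$lambda
  out <- numeric(length(j))
  pos <- j >= 1
  out[pos] <- kappa * beta^j[pos] / j[pos]
  out[!pos] <- theta * t + kappa * log1p(-beta)
  out
}

#' Simulate family sizes under Poisson immigration
#'
#' Direct marked-Poisson simulation: arrivals on `(0, t)` from a Poisson
#' process of rate `theta`, each family then evolving as an independent
#' event-driven linear BDP from size 1.
#'
#' @param theta Immigration rate, `> 0`.
#' @param params A [bd_params()] object.
#' @param t Time horizon.
#' @param reps Number of independent replicates.
#' @param seed Optional integer seed.
#' @return A list of length `reps`; each element is the integer vector of
#'   family sizes at `t` (extinct families appear as `0`). Use
#'   [family_counts()] to tabulate.
#' @examples
#' sims <- simulate_family_process(1, bd_params(1, 0.5), t = 1,
#'                                 reps = 3, seed = 1)
#' @export
simulate_family_process <- function(theta, params, t, reps = 1, seed = NULL) {
  params <- as_bd_params(params)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cpp_family_sizes_reps(theta, params$lambda, params$mu, t,
                        as.integer(reps))
}

#' Tabulate family sizes into counts, population size and family number
#'
#' @param sizes Integer vector of family sizes (zeros = extinct families).
#' @return A list with `counts` (vector `C_j` for `j = 1..max`), `Z`
#'   (total individuals \eqn{\sum j C_j}) and `F` (families alive
#'   \eqn{\sum C_j}).
#' @export
family_counts <- function(sizes) {
  sizes <- sizes[sizes > 0]
  counts <- if (length(sizes)) tabulate(sizes) else integer(0)
  list(counts = counts,
       Z = sum(sizes),
       F = length(sizes))
}

#' Population-size distribution under Poisson immigration
#'
#' The total population size \eqn{Z(t) = \sum_j j C_j(t)} of the
#' immigration model is negative binomial:
#' \deqn{P(Z(t) = j) = \binom{j + \theta/\lambda - 1}{j}
#'   (1 - \beta(t))^{\theta/\lambda} \beta(t)^j,}
#' with mean \eqn{\theta(e^{(\lambda-\mu)t} - 1)/(\lambda - \mu)}
#' (\eqn{\theta t} when \eqn{\lambda = \mu}).
#'
#' @param j Population size(s), integer `>= 0`. Vectorized.
#' @param theta Immigration rate, `> 0`.
#' @param params A [bd_params()] object.
#' @param t Time horizon.
#' @return Probabilities.
#' @examples
#' dbdi(0:5, theta = 2, params = bd_params(1, 0.5), t = 1)
#' @export
dbdi <- function(j, theta, params, t) {
  params <- as_bd_params(params)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (any(j < 0) || any(j != round(j))) {
    stop("`j` must be integers >= 0", call. = FALSE)
  }
  beta <- bd_beta_alpha(t, params)$beta
  dnbinom(j, size = theta / params$lambda, prob = 1 - beta)
}

#' Ewens sampling formula
#'
#' Probability of the family-size configuration
#' \eqn{(c_1, \dots, c_n)} (with \eqn{c_j} families of size `j` and
#' \eqn{\sum_j j c_j = n}) conditional on total population size `n` in
#' the immigration model, which depends on the rates only through the
#' concentration \eqn{\kappa = \theta/\lambda}:
#' \deqn{P(c_1,\dots,c_n) = \frac{n!}{\kappa_{(n)}}
#'   \prod_{j=1}^n \left(\frac{\kappa}{j}\right)^{c_j} \frac{1}{c_j!},}
#' where \eqn{\kappa_{(n)} = \kappa(\kappa+1)\cdots(\kappa+n-1)}.
#'
#' @param c Integer vector of multiplicities `c_1, ..., c_n` (trailing
#'   zeros may be omitted).
#' @param kappa Concentration parameter \eqn{\theta/\lambda > 0}.
#' @param log Return the log-probability?
#' @return The probability of the configuration.
#' @examples
#' dewens(c(2), kappa = 1)        # two singletons, n = 2
#' dewens(c(0, 1), kappa = 1)     # one pair, n = 2
#' @export
dewens <- function(c, kappa, log = FALSE) {
  if (kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  if (any(c < 0) || any(c != round(c))) {
    stop("`c` must be nonnegative integers", call. = FALSE)
  }
  n <- sum(seq_along(c) * c)
  if (n < 1) stop("`c` must describe a partition of some n >= 1",
                  call. = FALSE)
  j <- which(c > 0)
  lp <- lfactorial(n) - (lgamma(kappa + n) - lgamma(kappa)) +
    sum(c[j] * (log(kappa) - log(j)) - lfactorial(c[j]))
  if (log) lp else exp(lp)
}

#' Enumerate all partitions of n as multiplicity vectors
#'
#' Returns every configuration \eqn{(c_1, \dots, c_n)} with
#' \eqn{\sum_j j c_j = n}; used e.g. to verify that [dewens()] sums to 1.
#'
#' @param n Positive integer.
#' @return A list of integer vectors of length `n`.
#' @examples
#' length(partition_multiplicities(6))   # 11 partitions
#' @export
partition_multiplicities <- function(n) {
  stopifnot(n >= 1, n == round(n))
  out <- list()
  rec <- function(remaining, maxpart, acc) {
    if (remaining == 0) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (p in seq_len(min(remaining, maxpart))) {
      acc2 <- acc
      acc2[p] <- acc2[p] + 1L
      rec(remaining - p, p, acc2)
    }
  }
  rec(n, n, integer(n))
  out
}
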