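#' Birth-death process parameters
#'
#' Bundle the per-capita birth rate \eqn{\lambda > 0} and death rate
#' \eqn{\mu \ge 0} of a linear (per-capita) birth-death process. With
#' `mu = 0` the process is the Yule (pure-birth) process.
#'
#' @param lambda Per-capita birth rate (events per unit time), `> 0`.
#' @param mu Per-capita death rate, `>= 0`. Default `0` (Yule process).
#' @return An object of class `bd_params`, a list with elements `lambda`
#'   and `mu`.
#' @examples
#' bd_params(1, 0.5)
#' @export
bd_params <- function(lambda, mu = 0) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("`mu` must be a single finite number >= 0", call. = FALSE)
  }
  structure(list(lambda = lambda, mu = mu), class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("Linear birth-death parameters: lambda = %g, mu = %g%s\n",
              x$lambda, x$mu,
              if (x$mu == 0) " (Yule process)" else ""))
  invisible(x)
}

as_bd_params <- function(params) {
  if (inherits(params, "bd_params")) return(params)
  if (is.numeric(params) && length(params) == 2L) {
    return(bd_params(params[[1]], params[[2]]))
  }
  stop("`params` must be a bd_params object or a numeric c(lambda, mu)",
       call. = FALSE)
}

# Relative |lambda - mu| below which the critical closed form is used;
# eq for beta has a removable singularity at lambda == mu and the direct
# formula cancels catastrophically nearby.
.bd_critical_tol <- 1e-8

#' Geometric parameter and extinction probability of a linear BDP
#'
#' Computes the two functions that parameterize the population-size law of
#' a linear birth-death process started from one individual:
#' \deqn{\beta(t) = \frac{\lambda(e^{(\lambda-\mu)t} - 1)}
#'   {\lambda e^{(\lambda-\mu)t} - \mu}, \qquad
#'   \alpha(t) = \frac{\mu}{\lambda}\beta(t),}
#' with the continuous limit \eqn{\beta(t) = \alpha(t) = \lambda t /
#' (1 + \lambda t)} in the critical case \eqn{\lambda = \mu}.
#' \eqn{\alpha(t)} is the probability of extinction by time `t`;
#' \eqn{\beta(t)} is the geometric parameter of the size distribution
#' conditional on survival, and satisfies
#' \eqn{\beta'(t) = \lambda(1 - \alpha(t))(1 - \beta(t))}.
#'
#' @param t Time(s), `>= 0`. Vectorized.
#' @param params A [bd_params()] object (or `c(lambda, mu)`).
#' @return A list with numeric vectors `beta` and `alpha`, both in
#'   `[0, 1)`.
#' @examples
#' bd_beta_alpha(1, bd_params(1, 0.5))
#' @export
bd_beta_alpha <- function(t, params) {
  params <- as_bd_params(params)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  lambda <- params$lambda
  mu <- params$mu
  d <- lambda - mu
  if (abs(d) < .bd_critical_tol * lambda) {
    beta <- lambda * t / (1 + lambda * t)
    return(list(beta = beta, alpha = beta))
  }
  if (d > 0) {
    # multiply through by e^{-dt} so large t cannot overflow
    em <- exp(-d * t)
    beta <- (1 - em) / (1 - (mu / lambda) * em)
  } else {
    e <- expm1(d * t)            # in (-1, 0], accurate for small |d t|
    beta <- lambda * e / (lambda * e + d)
  }
  list(beta = beta, alpha = (mu / lambda) * beta)
}

#' Eventual extinction probability of a linear BDP
#'
#' Starting from `z0` individuals each founding an independent line, the
#' population dies out with probability \eqn{\min\{1, (\mu/\lambda)^{z_0}\}}.
#'
#' @param params A [bd_params()] object.
#' @param z0 Initial number of individuals, integer `>= 1`.
#' @return The probability of eventual extinction.
#' @examples
#' extinction_prob(bd_params(2, 1))      # 0.5
#' @export
extinction_prob <- function(params, z0 = 1) {
  params <- as_bd_params(params)
  if (length(z0) != 1L || z0 < 1 || z0 != round(z0)) {
    stop("`z0` must be a single integer >= 1", call. = FALSE)
  }
  min(1, (params$mu / params$lambda)^z0)
}
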