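# Fisher's multiple-sampling problem under the Yule-with-immigration
# model, time scaled so the per-capita split rate is 1. Individuals are
# counted at their birth/arrival instants, the only mapping under which
# the species count in (0, t1] is Poisson(theta * t1) and the formulas
# below close. (The replicate-population scenario, with E V2 ~ theta log n,
# is not simulated here.)

#' Mean number of families observed in a time window
#'
#' `F(a, b)` counts the families (species) with at least one individual
#' appearing — by immigrant arrival or by birth — in the window
#' `(a, b]`: exactly the species detected when the specimens collected
#' over `(a, b]` are classified. Under unit-rate Yule growth with
#' Poisson(`theta`) immigration, marking each family by whether it
#' appears in the window makes `F(a, b)` Poisson with mean
#' \deqn{\theta \log(e^b - e^a + 1).}
#' For `a > 0` this mixes families founded before `a` that keep
#' producing offspring with families founded inside the window; the
#' function is restricted to `a > 0` (at `a = 0` the count reduces to
#' plain arrivals, mean `theta * b`).
#'
#' @param a,b Window bounds, `0 < a <= b`.
#' @param theta Immigration rate, `> 0`.
#' @return The Poisson mean of `F(a, b)`.
#' @examples
#' overlap_mean(1, 2, theta = 1)
#' @export
overlap_mean <- function(a, b, theta) {
  if (any(a <= 0) || any(b < a)) {
    stop("need 0 < a <= b", call. = FALSE)
  }
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  theta * log(exp(b) - exp(a) + 1)
}

#' Covariance of overlap counts in disjoint windows
#'
#' For `0 <= a < b <= c < d`,
#' \deqn{\mathrm{Cov}(F(a,b), F(c,d)) = \theta \log\frac{(e^b - e^a + 1)
#'   (e^d - e^c + 1)}{e^d - e^c + e^b - e^a + 1}.}
#'
#' @param a,b,c,d Window bounds with `0 <= a < b <= c < d`.
#' @param theta Immigration rate, `> 0`.
#' @return The covariance.
#' @examples
#' overlap_cov(0.5, 1, 1, 1.5, theta = 2)
#' @export
overlap_cov <- function(a, b, c, d, theta) {
  if (!(a >= 0 && a < b && b <= c && c < d)) {
    stop("need 0 <= a < b <= c < d", call. = FALSE)
  }
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  A <- exp(b) - exp(a)
  B <- exp(d) - exp(c)
  theta * log((A + 1) * (B + 1) / (A + B + 1))
}

#' Expected sample variance of species counts in consecutive samples
#'
#' Let `F1`, `F2` be the numbers of species (families) observed in the
#' consecutive windows `(0, t1]` and `(t1, t2]` of a unit-rate
#' Yule-with-immigration process, and `V2 = (F1 - F2)^2 / 2` their sample
#' variance. Then
#' \deqn{E V_2 = \tfrac12\left\{\theta\log\frac{e^{2t_2}e^{-t_1}}
#'   {e^{t_2} - e^{t_1} + 1} + \theta^2\log^2\frac{e^{t_1}}
#'   {e^{t_2} - e^{t_1} + 1}\right\}.}
#'
#' @param t1,t2 Sampling times, `0 < t1 < t2`.
#' @param theta Immigration rate, `> 0`.
#' @return The expected sample variance.
#' @examples
#' ev2_mean_times(1, 2, theta = 1)
#' @export
ev2_mean_times <- function(t1, t2, theta) {
  if (!(t1 > 0 && t2 > t1)) stop("need 0 < t1 < t2", call. = FALSE)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  D <- exp(t2) - exp(t1) + 1
  0.5 * (theta * log(exp(2 * t2 - t1) / D) + theta^2 * log(exp(t1) / D)^2)
}

#' Expected sample variance for given consecutive sample sizes
#'
#' The discrete version of [ev2_mean_times()]: sampling times are chosen
#' by [choose_times()] so the expected specimen counts are `n1` and
#' `n1 + n2`, giving
#' \deqn{E V_2 = \tfrac12\left\{\theta\log\frac{(n_1+n_2+\theta)^2}
#'   {(n_1+\theta)(n_2+\theta)} + \theta^2\log^2\frac{n_1+\theta}
#'   {n_2+\theta}\right\},}
#' which for equal sizes `n1 = n2 = n` reduces to
#' \eqn{\theta\log\{(2n+\theta)/(n+\theta)\}} and so to
#' \eqn{\theta\log 2} in large samples.
#'
#' @param n1,n2 Expected sample sizes, `> 0`.
#' @param theta Immigration rate, `> 0`.
#' @return The expected sample variance.
#' @examples
#' ev2_mean_sizes(50, 50, theta = 3)
#' 3 * log((100 + 3) / (50 + 3))          # equal-size reduction
#' @export
ev2_mean_sizes <- function(n1, n2, theta) {
  if (n1 <= 0 || n2 <= 0) stop("`n1`, `n2` must be > 0", call. = FALSE)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  0.5 * (theta * log((n1 + n2 + theta)^2 / ((n1 + theta) * (n2 + theta))) +
           theta^2 * log((n1 + theta) / (n2 + theta))^2)
}

#' Sampling times matching expected specimen counts
#'
#' Inverts the mean population size \eqn{E Z(t) = \theta(e^t - 1)} of the
#' unit-rate Yule-with-immigration model so that the expected number of
#' specimens at `t1` is `n1` and at `t2` is `n1 + n2`:
#' \deqn{t_1 = \log\frac{n_1+\theta}{\theta}, \qquad
#'   t_2 = \log\frac{n_1+n_2+\theta}{\theta}.}
#'
#' @param n1,n2 Sample sizes, `> 0`.
#' @param theta Immigration rate, `> 0`.
#' @return Named numeric vector `c(t1, t2)`.
#' @examples
#' choose_times(50, 50, theta = 3)
#' @export
choose_times <- function(n1, n2, theta) {
  if (n1 <= 0 || n2 <= 0) stop("`n1`, `n2` must be > 0", call. = FALSE)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  c(t1 = log((n1 + theta) / theta), t2 = log((n1 + n2 + theta) / theta))
}

#' Monte-Carlo estimate of Fisher's two-sample variance
#'
#' Simulates the unit-rate Yule-with-immigration process to `t2` (from
#' [choose_times()]); `F1` counts distinct families with at least one
#' individual appearing (arrival or birth) in `(0, t1]` and `F2` the
#' same for `(t1, t2]`. Returns the Monte-Carlo mean of
#' `V2 = (F1 - F2)^2 / 2` with its standard error.
#'
#' @param n1,n2 Sample sizes, `> 0`.
#' @param theta Immigration rate, `> 0`.
#' @param reps Number of replicates, `>= 1`.
#' @param seed Optional integer seed.
#' @return List with `mean`, `se`, `F1`, `F2` (per-replicate counts) and
#'   the times used.
#' @examples
#' simulate_two_sample_v2(50, 50, theta = 3, reps = 1000, seed = 1)$mean
#' @export
simulate_two_sample_v2 <- function(n1, n2, theta, reps, seed = NULL) {
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  tt <- choose_times(n1, n2, theta)
  if (!is.null(seed)) set.seed(seed)
  windows <- rbind(c(0, tt[["t1"]]), c(tt[["t1"]], tt[["t2"]]))
  cnt <- cpp_yule_imm_window_counts(theta, 1, tt[["t2"]], windows,
                                    c(0L, 0L), as.integer(reps))
  v2 <- 0.5 * (cnt[, 1] - cnt[, 2])^2
  list(mean = mean(v2), se = sd(v2) / sqrt(reps),
       F1 = cnt[, 1], F2 = cnt[, 2], t1 = tt[["t1"]], t2 = tt[["t2"]])
}

#' Monte-Carlo window counts F(a, b)
#'
#' Simulates the unit-rate Yule-with-immigration process and counts, per
#' replicate, the families with at least one individual appearing in
#' each requested window `(a, b]` (see [overlap_mean()]).
#'
#' @param windows Two-column matrix of window bounds (one row per
#'   window).
#' @param theta Immigration rate, `> 0`.
#' @param reps Number of replicates.
#' @param seed Optional integer seed.
#' @return Integer matrix `reps x nrow(windows)` of counts.
#' @examples
#' counts <- simulate_overlap_counts(rbind(c(1, 2)), theta = 1,
#'                                   reps = 500, seed = 1)
#' mean(counts)          # compare overlap_mean(1, 2, 1)
#' @export
simulate_overlap_counts <- function(windows, theta, reps, seed = NULL) {
  windows <- rbind(windows)
  if (any(windows[, 1] <= 0) || any(windows[, 2] < windows[, 1])) {
    stop("each window needs 0 < a <= b", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cpp_yule_imm_window_counts(theta, 1, max(windows[, 2]), windows,
                             rep(0L, nrow(windows)), as.integer(reps))
}
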