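#' Configuration for the birth-death cell-population simulator
#'
#' Cells age independently for an exponential time with parameter
#' `event_rate`; at the event the cell divides with probability `p`,
#' otherwise it dies. The population is grown from one founder cell
#' until it first reaches `N` concurrent cells (runs that die out are
#' discarded and restarted); `n` cells are then sampled uniformly
#' without replacement and neutral mutations are laid on the sampled
#' ancestral tree under an infinite-sites model of rate `theta`.
#'
#' @param p Division probability, in `(0, 1)`.
#' @param theta Mutation rate (mutations per unit branch time, or per
#'   division when `mutation_model = "division"`), `>= 0`.
#' @param N Target population size, `>= 2`.
#' @param n Sample size, `2 <= n <= N`. The sample size is a free design
#'   knob of the model; the default 100 keeps sampled-tree sizes modest.
#' @param event_rate Cell event rate \eqn{\lambda} (default 1: time is
#'   measured in expected cell lifetimes).
#' @param mutation_model `"time"` (Poisson(`theta` x branch duration),
#'   default) or `"division"` (Poisson(`theta` x divisions on branch)).
#' @param include_stem Keep the stem branch (founder to sample MRCA), so
#'   truncal mutations can arise? Default `TRUE`.
#' @param max_attempts Cap on growth restarts before failing.
#' @return An object of class `cell_config`.
#' @examples
#' cell_config(p = 0.722, theta = 11.07)
#' @export
cell_config <- function(p, theta, N = 1000, n = 100, event_rate = 1,
                        mutation_model = c("time", "division"),
                        include_stem = TRUE, max_attempts = 10000) {
  if (!(p > 0 && p < 1)) stop("`p` must be in (0, 1)", call. = FALSE)
  if (theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  if (N < 2 || N != round(N)) stop("`N` must be an integer >= 2",
                                   call. = FALSE)
  if (n < 2 || n > N || n != round(n)) {
    stop("`n` must be an integer with 2 <= n <= N", call. = FALSE)
  }
  if (event_rate <= 0) stop("`event_rate` must be > 0", call. = FALSE)
  structure(list(p = p, theta = theta, N = as.integer(N), n = as.integer(n),
                 event_rate = event_rate,
                 mutation_model = match.arg(mutation_model),
                 include_stem = isTRUE(include_stem),
                 max_attempts = as.integer(max_attempts)),
            class = "cell_config")
}

#' @export
print.cell_config <- function(x, ...) {
  cat(sprintf(
    "Cell-population model: p = %g, theta = %g, N = %d, n = %d (rate %g)\n",
    x$p, x$theta, x$N, x$n, x$event_rate))
  invisible(x)
}

#' Grow a cell population to its target size
#'
#' Event-driven growth of the equivalent linear BDP with birth rate
#' `p * event_rate` and death rate `(1 - p) * event_rate`, from one
#' founder. Runs that go extinct before reaching `N` cells are discarded
#' and the simulation restarts; the expected number of attempts is the
#' reciprocal survival probability `p / (2p - 1)`. The population is
#' frozen at the instant the `N`-th concurrent cell appears.
#'
#' @param config A [cell_config()] object.
#' @param seed Optional integer seed.
#' @return A complete `timed_tree` with exactly `N` extant leaves;
#'   attribute `"attempts"` records the number of growth attempts.
#' @examples
#' pop <- grow_cell_population(cell_config(0.9, 1, N = 50, n = 10), seed = 1)
#' n_extant(pop)
#' @export
grow_cell_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cell_config"))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_grow_to_n(config$p * config$event_rate,
                       (1 - config$p) * config$event_rate,
                       config$N, config$max_attempts)
  if (!is.null(res$failed)) {
    stop(sprintf(
      "population failed to reach N = %d within %d attempts (p = %g)",
      config$N, config$max_attempts, config$p), call. = FALSE)
  }
  tree <- cpp_tree_to_timed(res, res$t_final, "complete")
  attr(tree, "attempts") <- res$attempts
  tree
}

#' Ancestral tree of a random sample of cells
#'
#' Draws `n` extant cells uniformly without replacement and prunes the
#' population tree to their ancestry, suppressing unary nodes. The stem
#' branch from the founder (time 0) to the sample MRCA is retained so
#' truncal mutations are representable. Each branch also records the
#' number of cell divisions it spans (column `divisions`), for the
#' per-division mutation clock.
#'
#' @param population A complete `timed_tree` from
#'   [grow_cell_population()].
#' @param n Sample size, `<= ` number of extant cells.
#' @param seed Optional integer seed.
#' @return A reconstructed `timed_tree` with `n` leaves (2n - 1 nodes).
#' @export
sample_cell_tree <- function(population, n, seed = NULL) {
  stopifnot(inherits(population, "timed_tree"))
  extant <- which(population$nodes$reason == "observed")
  if (n > length(extant)) {
    stop("`n` exceeds the number of extant cells", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  take <- extant[sample.int(length(extant), n)]
  out <- prune_ancestry(population, take)
  # divisions spanned by each retained branch: division events with time
  # in (branch birth, branch end] along the lineage path, i.e. the
  # suppressed unary splits plus the division terminating the branch
  # (none for branches ending in a sampled cell)
  nd <- population$nodes
  retained_orig <- retained_ids(population, take)
  is_ret <- logical(nrow(nd)); is_ret[retained_orig] <- TRUE
  divs <- integer(length(retained_orig))
  for (k in seq_along(retained_orig)) {
    o <- retained_orig[k]
    cnt <- if (nd$reason[o] == "split") 1L else 0L
    j <- nd$parent[o]
    while (!is.na(j) && !is_ret[j]) {
      cnt <- cnt + 1L
      j <- nd$parent[j]
    }
    divs[k] <- cnt
  }
  out$nodes$divisions <- divs
  out
}

# original-node ids retained after pruning to `take` (same rule as
# prune_ancestry)
retained_ids <- function(tree, take) {
  nd <- tree$nodes
  keep <- mark_ancestry(nd$parent, take)
  is_target <- logical(nrow(nd)); is_target[take] <- TRUE
  kc <- tabulate(nd$parent[keep & !is.na(nd$parent)], nbins = nrow(nd))
  kc[!keep] <- 0L
  which(keep & (is_target | kc == 2L))
}

#' Drop infinite-sites mutations on a sampled ancestral tree
#'
#' Each branch receives a Poisson number of mutations with mean
#' `theta` times its duration (or times its division count under the
#' per-division clock); every mutation is carried by all sampled cells
#' descending from the branch. Mutations on the stem are carried by all
#' `n` cells (truncal).
#'
#' @param tree A reconstructed `timed_tree` from [sample_cell_tree()]
#'   (or any reconstructed tree).
#' @param theta Mutation rate, `>= 0`.
#' @param seed Optional integer seed.
#' @param mutation_model `"time"` or `"division"`.
#' @param include_stem Lay mutations on the stem (root) branch?
#' @return A list with `f` (the site frequency spectrum, `f[j]` =
#'   mutations carried by exactly `j` sampled cells, `j = 1..n`), `S`
#'   (total mutations) and `truncal` (`f[n]`).
#' @export
drop_mutations <- function(tree, theta, seed = NULL,
                           mutation_model = c("time", "division"),
                           include_stem = TRUE) {
  stopifnot(inherits(tree, "timed_tree"))
  mutation_model <- match.arg(mutation_model)
  if (theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nd <- tree$nodes
  n <- sum(nd$reason == "observed")
  ndesc <- descendant_counts(nd)
  expo <- if (mutation_model == "time") {
    nd$end - nd$birth
  } else {
    if (is.null(nd$divisions)) {
      stop("per-division clock needs the `divisions` column from ",
           "sample_cell_tree()", call. = FALSE)
    }
    nd$divisions
  }
  if (!include_stem) expo[is.na(nd$parent)] <- 0
  muts <- rpois(nrow(nd), theta * expo)
  f <- integer(n)
  agg <- tapply(muts, ndesc, sum)
  f[as.integer(names(agg))] <- as.integer(agg)
  list(f = f, S = sum(f), truncal = f[n])
}

# observed-leaf count below (and including) each node
descendant_counts <- function(nd) {
  ndesc <- integer(nrow(nd))
  ndesc[nd$reason == "observed"] <- 1L
  for (k in rev(seq_len(nrow(nd)))) {     # parents precede children
    p <- nd$parent[k]
    if (!is.na(p)) ndesc[p] <- ndesc[p] + ndesc[k]
  }
  ndesc
}

#' Bin a site frequency spectrum into summary statistics
#'
#' Computes the proportions `b_1, ..., b_10` of the `S` mutations whose
#' sample frequency `j/n` falls in `(0, 0.1], (0.1, 0.2], ..., (0.9, 1]`,
#' and returns the 11-dimensional summary used for inference: `S`,
#' `b_1..b_9` (`b_10` is redundant given the rest) and the truncal count
#' `f_n`.
#'
#' @param sfs Either the list returned by [drop_mutations()] or an
#'   integer vector `f` of length `n`.
#' @param n Sample size (required when `sfs` is a bare vector).
#' @return Named numeric vector `c(S, b1, ..., b9, truncal)`.
#' @examples
#' summarize_sfs(c(4, 0, 0, 0, 2, 0, 0, 0, 0, 4), n = 10)
#' @export
summarize_sfs <- function(sfs, n = NULL) {
  if (is.list(sfs)) {
    f <- sfs$f
    n <- length(f)
  } else {
    f <- sfs
    if (is.null(n)) n <- length(f)
    if (length(f) != n) stop("`f` must have length n", call. = FALSE)
  }
  if (any(f < 0) || any(f != round(f))) {
    stop("`f` must be nonnegative integers", call. = FALSE)
  }
  S <- sum(f)
  b <- numeric(10)
  if (S > 0) {
    j <- seq_len(n)
    bin <- ((10L * j) + n - 1L) %/% n      # = ceiling(10 j / n), exact
    agg <- tapply(f, bin, sum)
    b[as.integer(names(agg))] <- agg / S
  }
  setNames(c(S, b[1:9], f[n]),
           c("S", paste0("b", 1:9), "truncal"))
}

#' Simulate one dataset of the cell model
#'
#' Runs the full pipeline grow -> sample -> mutate -> summarize and is
#' deterministic given `seed`.
#'
#' @param config A [cell_config()] object.
#' @param seed Optional integer seed.
#' @return Named summary vector `c(S, b1..b9, truncal)` with attribute
#'   `"attempts"` (growth restarts used).
#' @examples
#' simulate_cell_dataset(cell_config(0.9, 2, N = 50, n = 10), seed = 1)
#' @export
simulate_cell_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cell_config"))
  if (!is.null(seed)) set.seed(seed)
  pop <- grow_cell_population(config)
  tr <- sample_cell_tree(pop, config$n)
  sfs <- drop_mutations(tr, config$theta,
                        mutation_model = config$mutation_model,
                        include_stem = config$include_stem)
  out <- summarize_sfs(sfs)
  attr(out, "attempts") <- attr(pop, "attempts")
  out
}
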