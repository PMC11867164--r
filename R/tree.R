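#' Timed birth-death trees
#'
#' A `timed_tree` stores a rooted binary timed tree as a node table. Each
#' node is one lineage segment with a `birth` and `end` time and an
#' `end_reason` (`"split"`, `"death"` or `"observed"`). Children of a
#' split are born at the parent's split time; times run from the root at
#' time 0 to the observation time `t`. A `reconstructed` tree is
#' ultrametric: every leaf ends at `t` with reason `"observed"`.
#'
#' @param nodes Data frame with columns `id`, `parent` (`NA` for a root),
#'   `birth`, `end`, `reason`, `label`.
#' @param t Observation time (time horizon).
#' @param flavor `"complete"` or `"reconstructed"`.
#' @return An object of class `timed_tree`.
#' @keywords internal
new_timed_tree <- function(nodes, t, flavor) {
  stopifnot(is.data.frame(nodes), flavor %in% c("complete", "reconstructed"))
  structure(list(nodes = nodes, t = t, flavor = flavor),
            class = "timed_tree")
}

reason_labels <- c("split", "death", "observed")

#' @export
print.timed_tree <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("Timed %s birth-death tree: %d nodes, %d extant leaves, t = %g\n",
              x$flavor, nrow(nd), sum(nd$reason == "observed"), x$t))
  if (!is.null(attr(x, "attempts"))) {
    cat(sprintf("  growth attempts: %d\n", attr(x, "attempts")))
  }
  invisible(x)
}

#' Number of extant (observed) leaves of a timed tree
#' @param tree A `timed_tree`.
#' @return Integer count of lineages observed at the horizon.
#' @export
n_extant <- function(tree) {
  stopifnot(inherits(tree, "timed_tree"))
  sum(tree$nodes$reason == "observed")
}

#' Total branch length of a timed tree
#' @param tree A `timed_tree`.
#' @return Sum of all branch durations (including the root/stem branch).
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "timed_tree"))
  sum(tree$nodes$end - tree$nodes$birth)
}

cpp_tree_to_timed <- function(res, t, flavor = "complete") {
  reason <- reason_labels[res$reason]
  n <- length(res$parent)
  nodes <- data.frame(id = seq_len(n), parent = res$parent,
                      birth = res$birth, end = res$end,
                      reason = reason,
                      label = species_labels(res$parent),
                      stringsAsFactors = FALSE)
  new_timed_tree(nodes, t, flavor)
}

# Species labels in order of creation: each founder starts a species; at
# a split the first-created child continues the parent's species and the
# second is the next new species (so in a 2-tip tree the tips are "1"
# and "2"). Children always follow their parent and come in consecutive
# pairs, first child first.
species_labels <- function(parent) {
  n <- length(parent)
  lab <- character(n)
  sp <- 0L
  k <- 1L
  while (k <= n && is.na(parent[k])) {   # founders
    sp <- sp + 1L
    lab[k] <- as.character(sp)
    k <- k + 1L
  }
  while (k <= n) {                        # child pairs
    lab[k] <- lab[parent[k]]
    sp <- sp + 1L
    lab[k + 1L] <- as.character(sp)
    k <- k + 2L
  }
  lab
}

#' Simulate a complete linear birth-death tree
#'
#' Event-driven (Gillespie) simulation of a complete timed tree. With `n`
#' extant lineages the next event occurs after an exponential waiting
#' time with rate \eqn{n(\lambda + \mu)}; a uniformly chosen extant
#' lineage then splits with probability \eqn{\lambda/(\lambda+\mu)} or
#' dies otherwise. All lineages, extinct or not, are retained.
#'
#' @param params A [bd_params()] object.
#' @param t Time horizon, `> 0`.
#' @param z0 Number of founder lineages at time 0 (a forest if `> 1`).
#' @param seed Optional integer seed.
#' @return A `timed_tree` of flavor `"complete"`. An extinct tree (zero
#'   extant leaves) is a valid result.
#' @examples
#' tr <- simulate_complete_tree(bd_params(1, 0.5), t = 2, seed = 1)
#' n_extant(tr)
#' @export
simulate_complete_tree <- function(params, t, z0 = 1, seed = NULL) {
  params <- as_bd_params(params)
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("`t` must be a single finite number > 0", call. = FALSE)
  }
  if (z0 < 1 || z0 != round(z0)) {
    stop("`z0` must be an integer >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_sim_bd_tree(params$lambda, params$mu, t, as.integer(z0))
  cpp_tree_to_timed(res, t, "complete")
}

# Mark, for every node, whether it has a descendant in `target_ids`
# (inclusive); returns a logical keep vector over node rows.
mark_ancestry <- function(parent, target_ids) {
  keep <- logical(length(parent))
  for (i in target_ids) {
    j <- i
    while (!is.na(j) && !keep[j]) {
      keep[j] <- TRUE
      j <- parent[j]
    }
  }
  keep
}

# Prune a complete tree to the ancestry of the given extant leaf ids,
# suppressing unary nodes by concatenating branch durations. The stem
# (time 0 to the first retained split) is kept, so the root branch of the
# result starts at 0.
prune_ancestry <- function(tree, leaf_ids) {
  nd <- tree$nodes
  if (length(leaf_ids) == 0L) return(NULL)
  keep <- mark_ancestry(nd$parent, leaf_ids)
  is_target <- logical(nrow(nd)); is_target[leaf_ids] <- TRUE
  kc <- tabulate(nd$parent[keep & !is.na(nd$parent)], nbins = nrow(nd))
  kc[!keep] <- 0L
  retained <- keep & (is_target | kc == 2L)
  rid <- which(retained)
  newid <- integer(nrow(nd)); newid[rid] <- seq_along(rid)
  # retained parent: nearest retained proper ancestor
  rparent <- rep(NA_integer_, length(rid))
  for (k in seq_along(rid)) {
    j <- nd$parent[rid[k]]
    while (!is.na(j) && !retained[j]) j <- nd$parent[j]
    if (!is.na(j)) rparent[k] <- newid[j]
  }
  # birth of a retained node = end time of its retained parent (this is
  # what concatenates durations across suppressed unary nodes); 0 for the
  # retained root, which keeps the stem
  birth <- nd$end[rid][rparent]
  birth[is.na(rparent)] <- 0
  out <- data.frame(id = seq_along(rid), parent = rparent,
                    birth = birth, end = nd$end[rid],
                    reason = ifelse(is_target[rid], "observed", "split"),
                    label = nd$label[rid], stringsAsFactors = FALSE)
  new_timed_tree(out, tree$t, "reconstructed")
}

#' Prune a complete tree to the reconstructed tree of extant lineages
#'
#' Removes every lineage with no descendant observed at the horizon and
#' suppresses the resulting unary nodes by concatenating branch
#' durations. The result is the ultrametric reconstructed tree whose
#' leaves are exactly the extant lineages; the stem from time 0 to the
#' first surviving split is retained as the root branch.
#'
#' @param tree A `timed_tree` of flavor `"complete"`.
#' @return A `timed_tree` of flavor `"reconstructed"`, or `NULL` when the
#'   tree is extinct.
#' @examples
#' tr <- simulate_complete_tree(bd_params(1, 0.5), t = 2, seed = 1)
#' rec <- prune_to_reconstructed(tr)
#' @export
prune_to_reconstructed <- function(tree) {
  stopifnot(inherits(tree, "timed_tree"))
  if (tree$flavor != "complete") {
    stop("`tree` is already reconstructed; pruning requires a complete tree",
         call. = FALSE)
  }
  prune_ancestry(tree, which(tree$nodes$reason == "observed"))
}

#' @export
plot.timed_tree <- function(x, ...) {
  phy <- as.phylo(x)
  ape::plot.phylo(phy, root.edge = TRUE, ...)
  invisible(x)
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Convert a timed tree to an ape "phylo" object
#'
#' Split nodes become internal vertices; non-split nodes become tips.
#' Branch lengths are lineage durations; the root lineage's duration is
#' stored as the `root.edge` (the stem).
#'
#' @param x A `timed_tree` with at least one split and a single root.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.timed_tree <- function(x, ...) {
  nd <- x$nodes
  roots <- which(is.na(nd$parent))
  if (length(roots) != 1L) {
    stop("only single-root trees can be converted to phylo", call. = FALSE)
  }
  is_split <- nd$reason == "split"
  if (!any(is_split)) {
    stop("tree has no splits; cannot represent a single lineage as phylo",
         call. = FALSE)
  }
  tips <- which(!is_split)
  ints <- which(is_split)
  # root lineage must end in a split for a rooted binary phylo
  if (!is_split[roots]) {
    stop("root lineage has no split; cannot convert to phylo", call. = FALSE)
  }
  ints <- c(roots, setdiff(ints, roots))     # root vertex first
  ntip <- length(tips)
  vert <- integer(nrow(nd))
  vert[tips] <- seq_len(ntip)
  vert[ints] <- ntip + seq_along(ints)
  nonroot <- which(!is.na(nd$parent))
  edge <- cbind(vert[nd$parent[nonroot]], vert[nonroot])
  len <- nd$end[nonroot] - nd$birth[nonroot]
  phy <- list(edge = edge, edge.length = len,
              tip.label = nd$label[tips], Nnode = length(ints),
              root.edge = nd$end[roots] - nd$birth[roots])
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy)
}
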