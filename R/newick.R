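#' Write a timed tree to a Newick file
#'
#' Serializes via [as.phylo.timed_tree()] and [ape::write.tree()]:
#' standard single-line Newick, branch lengths in model time units,
#' semicolon-terminated, with the stem written as the root edge.
#'
#' @param tree A `timed_tree` with at least one split.
#' @param path Output file path.
#' @return The path, invisibly.
#' @examples
#' tr <- simulate_reconstructed_tree(4, 1, bd_params(1), seed = 1)
#' f <- tempfile(fileext = ".nwk")
#' write_newick(tr, f)
#' readLines(f)
#' @export
write_newick <- function(tree, path) {
  phy <- as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick file as a timed tree
#'
#' Reads a rooted, strictly binary Newick tree with mandatory branch
#' lengths and reconstructs absolute times with the root lineage starting
#' at time 0 (any root edge becomes the stem). Tips whose depth equals
#' the maximum depth (within `tol`) are marked `"observed"`, the others
#' `"death"`.
#'
#' @param path Path to a Newick file.
#' @param tol Relative tolerance for classifying tips as extant.
#' @return A `timed_tree`.
#' @export
read_newick <- function(path, tol = 1e-8) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length)) {
    stop("branch lengths are mandatory in this Newick dialect", call. = FALSE)
  }
  tab <- tabulate(phy$edge[, 1], nbins = ape::Ntip(phy) + phy$Nnode)
  bad <- which(tab[-seq_len(ape::Ntip(phy))] != 2)
  if (length(bad)) {
    stop("non-binary node(s) in Newick input: internal vertex ",
         paste(bad + ape::Ntip(phy), collapse = ", "), call. = FALSE)
  }
  from_phylo(phy)
}

# Build the timed_tree node table from a rooted binary phylo: each edge
# becomes a lineage segment; the root vertex gains a stem lineage of
# length root.edge (0 if absent) starting at time 0.
from_phylo <- function(phy, tol = 1e-8) {
  ntip <- ape::Ntip(phy)
  nvert <- ntip + phy$Nnode
  root_vert <- ntip + 1L
  stem <- if (is.null(phy$root.edge)) 0 else phy$root.edge
  # depth of each vertex below the root vertex
  depth <- numeric(nvert)
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    depth[ord$edge[k, 2]] <- depth[ord$edge[k, 1]] + ord$edge.length[k]
  }
  depth <- depth + stem
  # node per vertex: lineage ending at that vertex
  parent_vert <- rep(NA_integer_, nvert)
  parent_vert[phy$edge[, 2]] <- phy$edge[, 1]
  ids <- c(root_vert, setdiff(seq_len(nvert), root_vert))
  newid <- integer(nvert); newid[ids] <- seq_len(nvert)
  tmax <- max(depth[seq_len(ntip)])
  birth <- ifelse(is.na(parent_vert), 0, depth[parent_vert])
  is_tip <- seq_len(nvert) <= ntip
  reason <- ifelse(!is_tip, "split",
                   ifelse(abs(depth - tmax) <= tol * max(tmax, 1),
                          "observed", "death"))
  label <- ifelse(is_tip, phy$tip.label, NA_character_)
  nodes <- data.frame(id = newid, parent = newid[parent_vert],
                      birth = birth, end = depth, reason = reason,
                      label = label, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  flavor <- if (all(nodes$reason != "death")) "reconstructed" else "complete"
  new_timed_tree(nodes, tmax, flavor)
}
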