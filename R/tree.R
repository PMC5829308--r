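#' Simulate a rooted binary phylogeny for synthetic communities
#'
#' Generates a pure-birth (Yule) topology by sequential random splitting,
#' with independent exponential branch lengths. The result is a rooted,
#' binary `ape::phylo` tree whose tips are labelled `OTU_0001`,
#' `OTU_0002`, ... in tip order, suitable for Faith's PD and UniFrac
#' computations on simulated OTU tables.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed; the same seed always yields the same tree.
#' @param branch_rate rate of the exponential branch-length distribution;
#'   mean branch length is `1 / branch_rate`.
#' @return a rooted binary `phylo` object with `n_taxa` tips, all branch
#'   lengths strictly positive.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, branch_rate = 1) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 2)
    stop("`n_taxa` must be a single integer >= 2", call. = FALSE)
  n_taxa <- as.integer(n_taxa)
  with_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$edge.length <- rexp(nrow(tree$edge), rate = branch_rate) + 1e-6
    tree$tip.label <- sprintf("OTU_%04d", seq_len(n_taxa))
    tree
  })
}

# Branch decomposition of a rooted tree: for every edge, the set of tips
# descending from it, as a tips x edges 0/1 incidence matrix. This single
# structure drives Faith's PD (presence of any descendant) and weighted
# UniFrac (total descendant abundance), so both metrics share one
# postorder traversal.
branch_structure <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object",
                                     call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths",
                                      call. = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nedge <- nrow(tree$edge)
  # desc[v, t] == TRUE iff tip t descends from (or is) node v
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nedge)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  incidence <- t(desc[tree$edge[, 2L], , drop = FALSE]) * 1
  dimnames(incidence) <- list(tree$tip.label, NULL)
  parent <- integer(nnode); parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of <- integer(nnode); edge_of[tree$edge[, 2L]] <- seq_len(nedge)
  list(tip_labels = tree$tip.label, incidence = incidence,
       edge_length = tree$edge.length, parent = parent, edge_of = edge_of,
       child = tree$edge[, 2L], root = ntip + 1L, n_tip = ntip)
}

# Sum of branch lengths on the path from `node` up to the root.
root_path_length <- function(bs, node) {
  total <- 0
  while (node != bs$root && bs$parent[node] != 0L) {
    total <- total + bs$edge_length[bs$edge_of[node]]
    node <- bs$parent[node]
  }
  total
}
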