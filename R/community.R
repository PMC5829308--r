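#' Drop samples with too few reads
#'
#' Removes samples whose library size (row sum) is below `min_reads`.
#' Samples with exactly `min_reads` reads are retained.
#'
#' @param counts samples x OTUs non-negative count matrix with sample ids as
#'   row names.
#' @param min_reads minimum library size to retain a sample (default 20000).
#' @return the filtered count matrix, with attribute `"removed"` listing the
#'   ids of dropped samples.
#' @export
filter_samples <- function(counts, min_reads = 20000) {
  counts <- as_count_matrix(counts)
  keep <- rowSums(counts) >= min_reads
  if (!any(keep))
    stop("all samples fall below `min_reads` = ", min_reads, call. = FALSE)
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Rarefy counts to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, removing library-size effects
#' before diversity computations.
#'
#' @inheritParams filter_samples
#' @param depth target library size; must not exceed any sample's total.
#' @param seed integer seed; output is deterministic given the seed.
#' @return count matrix with every row summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  counts <- as_count_matrix(counts)
  depth <- as.integer(depth)
  lib <- rowSums(counts)
  if (any(lib < depth))
    stop("`depth` (", depth, ") exceeds library size of sample(s): ",
         paste(rownames(counts)[lib < depth], collapse = ", "), call. = FALSE)
  with_seed(seed, {
    out <- counts
    for (i in seq_len(nrow(counts))) {
      if (lib[i] == depth) next
      x <- counts[i, ]
      remaining <- lib[i]; to_draw <- depth
      for (j in seq_along(x)) {
        if (to_draw == 0L) { out[i, j:ncol(counts)] <- 0L; break }
        # conditional draw from the multivariate hypergeometric
        drawn <- rhyper(1, x[j], remaining - x[j], to_draw)
        out[i, j] <- drawn
        to_draw <- to_draw - drawn
        remaining <- remaining - x[j]
      }
    }
    out
  })
}

#' Median-of-ratios size factors and log transform
#'
#' Computes per-sample size factors by the median-of-ratios method over
#' OTUs observed in every sample, then returns `log2(count / s_i + 1)`.
#' This stabilises the count variance without discarding reads, as an
#' alternative to rarefaction.
#'
#' @inheritParams filter_samples
#' @return real-valued matrix of the same shape, with attribute
#'   `"size_factors"`.
#' @export
size_factor_transform <- function(counts) {
  counts <- as_count_matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  allpos <- colSums(counts > 0) == nrow(counts)
  if (!any(allpos))
    stop("no OTU has positive counts in every sample; ",
         "add pseudo-counts or use rarefaction", call. = FALSE)
  loggeo <- colMeans(log(counts[, allpos, drop = FALSE]))
  s <- apply(counts[, allpos, drop = FALSE], 1,
             function(x) exp(median(log(x) - loggeo)))
  out <- log2(sweep(counts, 1, s, "/") + 1)
  attr(out, "size_factors") <- s
  out
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the tree spanning a sample's taxa: with
#' `include_root = TRUE` (the default) every branch on a path from a
#' present tip to the root contributes; with `FALSE` only branches below
#' the most recent common ancestor of the present tips count.
#'
#' @param present character vector of OTU ids present in the sample (or a
#'   named numeric vector; positive entries are taken as present).
#' @param tree rooted `phylo` tree whose tip labels cover the OTU ids.
#' @param include_root include the path from the spanning subtree to the
#'   root (default `TRUE`).
#' @return phylogenetic diversity in branch-length units; 0 for an empty
#'   sample.
#' @export
faith_pd <- function(present, tree, include_root = TRUE) {
  if (is.numeric(present)) {
    if (is.null(names(present))) stop("numeric `present` must be named",
                                      call. = FALSE)
    present <- names(present)[present > 0]
  }
  bs <- if (is.list(tree) && !inherits(tree, "phylo")) tree
        else branch_structure(tree)
  if (length(present) == 0L) return(0)
  missing <- setdiff(present, bs$tip_labels)
  if (length(missing))
    stop("OTUs absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(present, bs$tip_labels)
  on_path <- colSums(bs$incidence[idx, , drop = FALSE]) > 0
  pd <- sum(bs$edge_length[on_path])
  if (!include_root) {
    mrca_node <- if (length(idx) == 1L) idx else {
      # MRCA = child end of the smallest-clade edge covering all present
      # tips; if no edge covers them the MRCA is the root itself
      cover <- colSums(bs$incidence[idx, , drop = FALSE]) == length(idx)
      if (any(cover)) {
        sizes <- colSums(bs$incidence)
        bs$child[which(cover)[which.min(sizes[cover])]]
      } else bs$root
    }
    pd <- pd - root_path_length(bs, mrca_node)
  }
  pd
}

#' Weighted UniFrac distance between two communities
#'
#' For each branch, the absolute difference of the total relative abundance
#' of its descendant tips is weighted by the branch length and summed.
#' The normalised variant divides by the same sum with `|.|` replaced by
#' `+`, bounding the distance in `[0, 1]`.
#'
#' @param p_a,p_b named non-negative relative-abundance vectors (each
#'   summing to 1) over tree tips.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param normalized divide by the total abundance-weighted branch length
#'   (default `TRUE`).
#' @return a single non-negative distance.
#' @export
weighted_unifrac <- function(p_a, p_b, tree, normalized = TRUE) {
  if (any(p_a < 0) || any(p_b < 0))
    stop("abundances must be non-negative", call. = FALSE)
  bs <- if (is.list(tree) && !inherits(tree, "phylo")) tree
        else branch_structure(tree)
  a <- expand_abundance(p_a, bs$tip_labels)
  b <- expand_abundance(p_b, bs$tip_labels)
  la <- as.vector(a %*% bs$incidence)
  lb <- as.vector(b %*% bs$incidence)
  raw <- sum(bs$edge_length * abs(la - lb))
  if (!normalized) return(raw)
  denom <- sum(bs$edge_length * (la + lb))
  if (denom == 0) return(0)
  raw / denom
}

expand_abundance <- function(p, tips) {
  if (is.null(names(p))) {
    if (length(p) != length(tips))
      stop("unnamed abundance vector must cover all tips", call. = FALSE)
    names(p) <- tips
  }
  missing <- setdiff(names(p)[p > 0], tips)
  if (length(missing))
    stop("OTUs absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- setNames(numeric(length(tips)), tips)
  out[names(p)] <- p
  matrix(out, nrow = 1)
}

#' All pairwise weighted UniFrac distances
#'
#' Computes per-sample branch loads in one pass (a samples x branches
#' matrix), then all pairwise distances as branch-length-weighted Manhattan
#' distances between load vectors, which is fast enough for hundreds of
#' samples.
#'
#' @param abundances samples x OTUs matrix of relative abundances (rows sum
#'   to 1); column names must be tree tip labels.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param normalized normalised weighted UniFrac (default `TRUE`).
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
pairwise_distances <- function(abundances, tree, normalized = TRUE) {
  abundances <- as.matrix(abundances)
  if (any(abundances < 0)) stop("abundances must be non-negative",
                                call. = FALSE)
  if (any(rowSums(abundances) == 0)) stop("empty samples present",
                                          call. = FALSE)
  bs <- if (is.list(tree) && !inherits(tree, "phylo")) tree
        else branch_structure(tree)
  missing <- setdiff(colnames(abundances), bs$tip_labels)
  if (length(missing))
    stop("OTUs absent from tree: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  loads <- abundances %*% bs$incidence[colnames(abundances), , drop = FALSE]
  wload <- sweep(loads, 2, bs$edge_length, "*")
  d <- as.matrix(dist(wload, method = "manhattan"))
  if (normalized) {
    r <- rowSums(wload)
    denom <- outer(r, r, "+")
    d <- ifelse(denom > 0, d / denom, 0)
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(abundances), rownames(abundances))
  d
}

#' Convert counts to relative abundances
#'
#' @inheritParams filter_samples
#' @return matrix with rows summing to 1. Real-valued (e.g. size-factor
#'   transformed) input is clamped at zero before scaling.
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  counts[counts < 0] <- 0
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("empty samples present", call. = FALSE)
  sweep(counts, 1, rs, "/")
}

as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stop("duplicated OTU ids", call. = FALSE)
  counts
}
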