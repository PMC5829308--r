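# Independent brute-force oracles. These deliberately avoid the package's
# branch_structure() machinery: descendant tip sets are found by naive
# recursion over the edge table, and paths by walking parent pointers.

# all tips descending from `node` (node itself if a tip)
oracle_desc_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_desc_tips, tree = tree))
}

# Faith's PD by exhaustive enumeration of the spanning branch set: an edge
# is on a root path iff any present tip descends from its child end.
oracle_pd <- function(present, tree) {
  if (length(present) == 0) return(0)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips_below <- oracle_desc_tips(tree, tree$edge[e, 2])
    if (any(present %in% tips_below)) total <- total + tree$edge.length[e]
  }
  total
}

# weighted UniFrac by per-branch enumeration
oracle_wunifrac <- function(p_a, p_b, tree, normalized = TRUE) {
  raw <- 0; denom <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips_below <- oracle_desc_tips(tree, tree$edge[e, 2])
    la <- sum(p_a[names(p_a) %in% tips_below])
    lb <- sum(p_b[names(p_b) %in% tips_below])
    raw <- raw + tree$edge.length[e] * abs(la - lb)
    denom <- denom + tree$edge.length[e] * (la + lb)
  }
  if (!normalized) raw else if (denom == 0) 0 else raw / denom
}

# BY step-up adjustment, written directly from the definition
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m * cm / i, 1)
    adj[o[i]] <- prev
  }
  adj
}

# random relative-abundance vector over a random subset of tips
random_community <- function(tree, min_taxa = 1) {
  tips <- tree$tip.label
  k <- sample(min_taxa:length(tips), 1)
  chosen <- sample(tips, k)
  p <- rgamma(k, 1)
  stats::setNames(p / sum(p), chosen)
}

# indicator data with known 3-factor structure (defaults: the generator's
# loading pattern)
gen_indicators <- function(n, L = default_loadings()) {
  f <- matrix(rnorm(n * 3), n, 3)
  noise <- matrix(rnorm(n * 7), n, 7) %*%
    diag(sqrt(pmax(1 - rowSums(L^2), 0)))
  X <- f %*% t(L) + noise
  colnames(X) <- rownames(L)
  list(Z = scale(X), f = f)
}

congruence <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# greedy column matching of estimated loadings to a truth matrix;
# returns the matched congruence per truth column
match_congruence <- function(est, truth) {
  C <- abs(crossprod(est, truth)) /
    outer(sqrt(colSums(est^2)), sqrt(colSums(truth^2)))
  out <- numeric(ncol(truth))
  for (r in seq_len(ncol(truth))) {
    idx <- which(C == max(C), arr.ind = TRUE)[1, ]
    out[idx[2]] <- C[idx[1], idx[2]]
    C[idx[1], ] <- -1; C[, idx[2]] <- -1
  }
  out
}

# One replicate of the null / recovery study: simulate a cohort on a fixed
# tree and return the p-values (and slope signs) of the PD regression, the
# windowed-dispersion regression per window fraction, and the PERMANOVA
# modernity term.
gradient_replicate <- function(cfg, tree, bs, rep_seed,
                               ws = seq(0.025, 0.10, length.out = 7),
                               n_perm = 199) {
  cfg$seed <- rep_seed
  md <- simulate_metadata(cfg)
  counts <- simulate_communities(tree, md$truth, cfg)
  f1 <- stats::setNames(md$truth$scores[, 1], rownames(md$truth$scores))
  rar <- rarefy(counts, min(rowSums(counts)),
                seed = migut:::substream_seed(rep_seed, "rarefy"))
  pres <- (rar > 0) * 1
  pd <- as.vector(((pres %*% bs$incidence[colnames(rar), ]) > 0) %*%
                    bs$edge_length)
  pd_fit <- ols_fit(pd, cbind(f = as.numeric(f1)))
  D <- pairwise_distances(relative_abundance(rar), bs)
  sw <- window_sensitivity(D, f1, ws, n_perm = n_perm,
                           seed = migut:::substream_seed(rep_seed,
                                                         "dispersion"))
  pm <- permanova(D, data.frame(f = as.numeric(f1)), "f", n_perm = n_perm,
                  seed = migut:::substream_seed(rep_seed, "permanova"))
  list(pd_p = pd_fit$coefficients["f", "p"],
       pd_slope = pd_fit$coefficients["f", "estimate"],
       disp_p = sw$p, disp_slope = sw$slope, disp_n_used = sw$n_used,
       disp_n_empty = sw$n_empty, perm_p = pm$p[1], n = length(f1))
}
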