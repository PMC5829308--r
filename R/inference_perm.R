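# Gower-centred inner-product matrix from a distance matrix:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n)
gower_center <- function(dist_mat) {
  D <- as.matrix(dist_mat)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric", call. = FALSE)
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A); gm <- mean(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
}

hat_matrix <- function(X) {
  qrx <- qr(X)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  tcrossprod(Q)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squares of a distance matrix across model
#' terms in the given (sequential) order, computing a pseudo-F per term and
#' a permutation p-value under free permutation of sample labels. Term
#' sums of squares come from projections of the Gower-centred
#' inner-product matrix, so Euclidean input distances reproduce classical
#' ANOVA exactly.
#'
#' @param dist_mat symmetric distance matrix.
#' @param data data frame of covariates aligned with `dist_mat` rows.
#' @param terms character vector of term labels, fitted sequentially in
#'   this order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return data frame of class `permanova_table` with one row per term
#'   plus `Residual` and `Total` rows: `term`, `df`, `ss`, `pseudo_f`,
#'   `r_squared`, `p`.
#' @export
permanova <- function(dist_mat, data, terms, n_perm = 999, seed = NULL) {
  G <- gower_center(dist_mat)
  n <- nrow(G)
  if (nrow(data) != n) stop("`data` rows do not match distances",
                            call. = FALSE)
  # sequential hat matrices: intercept, then cumulative term blocks
  hats <- vector("list", length(terms) + 1L)
  hats[[1]] <- matrix(1 / n, n, n)
  ranks <- integer(length(terms) + 1L); ranks[1] <- 1L
  for (j in seq_along(terms)) {
    d <- build_design(data, terms[seq_len(j)])
    X <- cbind(1, d$X)
    r <- qr(X)$rank
    if (r <= ranks[j])
      stop("term `", terms[j], "` adds no rank: collinear design",
           call. = FALSE)
    hats[[j + 1]] <- hat_matrix(X)
    ranks[j + 1] <- r
  }
  df_terms <- diff(ranks)
  ss_total <- sum(diag(G))
  seq_ss <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    diff(tr)
  }
  ss <- seq_ss(G)
  df_res <- n - ranks[length(ranks)]
  ss_res <- ss_total - sum(ss)
  fobs <- (ss / df_terms) / (ss_res / df_res)
  if (n_perm > 0) {
    exceed <- rep(0L, length(terms))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        ssp <- seq_ss(G[p, p])
        ssrp <- ss_total - sum(ssp)
        fp <- (ssp / df_terms) / (ssrp / df_res)
        exceed <- exceed + (fp >= fobs - 1e-12)
      }
    })
    pval <- (1 + exceed) / (1 + n_perm)
  } else pval <- rep(NA_real_, length(terms))
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    ss = c(ss, ss_res, ss_total),
    pseudo_f = c(fobs, NA, NA),
    r_squared = c(ss, ss_res, ss_total) / ss_total,
    p = c(pval, NA, NA), stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova_table", "data.frame")
  out
}

#' Partial distance-based redundancy analysis
#'
#' Constrained ordination of a distance matrix: the variance explained by
#' `condition` covariates is projected out of the Gower-centred matrix
#' first ("partialled out"), the remainder is decomposed into the part
#' explained by the (residualised) constraints and an unconstrained part,
#' and the constrained part is eigen-decomposed into ordination axes. The
#' joint significance of the constraints is assessed by permuting the
#' conditioned matrix, i.e. permutation under the reduced
#' (condition-only) model.
#'
#' @param dist_mat symmetric distance matrix.
#' @param constraints data frame (or matrix) of constraining covariates.
#' @param condition optional data frame of covariates to partial out.
#' @param n_perm permutations for the constraint test (default 999).
#' @param seed integer seed.
#' @return list of class `dbrda_result`: `eigenvalues` (constrained axes,
#'   non-increasing), `site_scores`, `biplot` (correlations of constraints
#'   with site scores), `inertia` (named components: total, conditioned,
#'   constrained, unconstrained), `pseudo_f`, `p`, `df`.
#' @export
partial_dbrda <- function(dist_mat, constraints, condition = NULL,
                          n_perm = 999, seed = NULL) {
  G <- gower_center(dist_mat)
  n <- nrow(G)
  Xc <- stats::model.matrix(~ ., data = as.data.frame(constraints))
  total_inertia <- sum(diag(G))
  if (!is.null(condition)) {
    Z <- stats::model.matrix(~ ., data = as.data.frame(condition))
    Hz <- hat_matrix(Z)
    rank_z <- qr(Z)$rank
  } else {
    Hz <- matrix(1 / n, n, n)
    rank_z <- 1L
  }
  Q <- diag(n) - Hz
  G1 <- Q %*% G %*% Q
  conditioned <- total_inertia - sum(diag(G1))
  Xr <- Q %*% Xc[, -1, drop = FALSE]
  qx <- qr(Xr)
  if (qx$rank < ncol(Xr))
    stop("constraints collinear with each other or the condition",
         call. = FALSE)
  H <- hat_matrix(Xr)
  q_df <- qx$rank
  constrained_part <- H %*% G1 %*% H
  ed <- eigen((constrained_part + t(constrained_part)) / 2, symmetric = TRUE)
  eig <- ed$values[seq_len(min(q_df, n))]
  pos <- which(ed$values > 1e-10)
  site <- ed$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ed$values[pos]), length(pos), length(pos))
  if (length(pos)) colnames(site) <- paste0("CAP", seq_along(pos))
  rownames(site) <- rownames(as.matrix(dist_mat))
  constrained <- sum(diag(constrained_part))
  unconstrained <- sum(diag(G1)) - constrained
  df_res <- n - rank_z - q_df
  fobs <- (constrained / q_df) / (unconstrained / df_res)
  pval <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        Gp <- G1[p, p]
        cp <- sum(H * Gp)  # tr(H Gp H) = tr(H Gp)
        fp <- (cp / q_df) / ((sum(diag(Gp)) - cp) / df_res)
        exceed <- exceed + (fp >= fobs - 1e-12)
      }
    })
    pval <- (1 + exceed) / (1 + n_perm)
  }
  biplot <- if (ncol(site) > 0)
    cor(Xc[, -1, drop = FALSE], site) else NULL
  structure(list(eigenvalues = eig, site_scores = site, biplot = biplot,
                 inertia = c(total = total_inertia,
                             conditioned = conditioned,
                             constrained = constrained,
                             unconstrained = unconstrained),
                 pseudo_f = fobs, p = pval,
                 df = c(constraints = q_df, residual = df_res),
                 n_perm = n_perm, seed = seed),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat("Partial distance-based RDA\n")
  cat("Inertia:\n"); print(round(x$inertia, 4))
  cat("Constrained eigenvalues:", paste(round(x$eigenvalues, 4),
                                        collapse = ", "), "\n")
  cat(sprintf("Constraint test: pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$p, x$n_perm))
  invisible(x)
}
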