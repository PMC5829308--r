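#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence: the Benjamini-Hochberg adjustment inflated by
#' `c(m) = sum(1/j, j = 1..m)`. Sorted p-values are scaled by
#' `m * c(m) / i`, made monotone from the largest rank downwards, capped
#' at 1, and returned in the original order. `NA`s are preserved and do
#' not count towards `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of adjusted p-values, same length and order.
#' @export
by_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  cm <- sum(1 / seq_len(m))
  o <- order(pv)
  scaled <- pv[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out[ok][o] <- pmin(adj, 1)
  out
}

#' Per-taxon correlation screen against the factor scores
#'
#' Pearson correlation of every OTU's (normalised) abundance with every
#' factor score, a t-test per correlation, and a joint
#' Benjamini-Yekutieli adjustment across all OTU x factor tests.
#' Zero-variance OTUs yield missing results rather than zeros.
#'
#' @param abundance samples x OTUs numeric matrix (normalised counts).
#' @param scores samples x factors numeric matrix of factor scores.
#' @param alpha significance level applied to adjusted p-values
#'   (default 0.05).
#' @return data frame of class `screen_result`, one row per OTU x factor:
#'   `otu`, `factor`, `r`, `t`, `p`, `p_adjusted`, `significant`, `sign`;
#'   attribute `"c_m"` is the BY inflation constant actually used.
#' @export
correlation_screen <- function(abundance, scores, alpha = 0.05) {
  abundance <- as.matrix(abundance)
  scores <- as.matrix(scores)
  n <- nrow(abundance)
  if (n != nrow(scores)) stop("sample mismatch", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("factor", seq_len(ncol(scores)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("OTU_", seq_len(ncol(abundance)))
  sd_a <- apply(abundance, 2, sd)
  # one cor() call does the whole grid; degenerate columns masked after
  suppressWarnings(R <- cor(abundance, scores))
  R[sd_a == 0, ] <- NA
  tstat <- R * sqrt(n - 2) / sqrt(pmax(1 - R^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), n - 2)
  out <- data.frame(
    otu = rep(colnames(abundance), times = ncol(scores)),
    factor = rep(colnames(scores), each = ncol(abundance)),
    r = as.vector(R), t = as.vector(tstat), p = as.vector(pval),
    stringsAsFactors = FALSE)
  out$p_adjusted <- by_adjust(out$p)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out$sign <- ifelse(is.na(out$r), NA, ifelse(out$r >= 0, "+", "-"))
  m_eff <- sum(!is.na(out$p))
  attr(out, "c_m") <- if (m_eff > 0) sum(1 / seq_len(m_eff)) else NA_real_
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", "data.frame")
  out
}
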