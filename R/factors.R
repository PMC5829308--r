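#' Standardize the seven lifestyle indicators
#'
#' Z-scores the five house-construction codes (treated as numeric) and the
#' two item-ownership proportions, dropping samples with any missing
#' indicator. This is the input to the latent-factor extraction.
#'
#' @param meta data frame holding the indicator columns.
#' @param indicator_cols names of the seven indicator columns; defaults to
#'   the generator's names (`wall`, `floor`, `water`, `latrine`,
#'   `electricity`, `sol_traditional`, `sol_market`).
#' @return numeric matrix (samples x 7) with column means 0 and sds 1, and
#'   attribute `"dropped"` listing rows removed for missingness.
#' @export
standardize_indicators <- function(meta,
                                   indicator_cols = c(
                                     "wall", "floor", "water", "latrine",
                                     "electricity", "sol_traditional",
                                     "sol_market")) {
  missing_cols <- setdiff(indicator_cols, names(meta))
  if (length(missing_cols))
    stop("missing indicator columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(as.data.frame(lapply(meta[indicator_cols], as.numeric)))
  rownames(X) <- rownames(meta) %||% meta$sample_id
  ok <- complete.cases(X)
  dropped <- rownames(X)[!ok]
  X <- X[ok, , drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance indicator(s): ",
         paste(indicator_cols[sds == 0], collapse = ", "), call. = FALSE)
  Z <- scale(X)
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  attr(Z, "dropped") <- dropped
  Z
}

#' Maximum number of extractable factors
#'
#' The largest `k` for which the likelihood-ratio test of a `k`-factor
#' model retains non-negative degrees of freedom,
#' `((p - k)^2 - (p + k)) / 2 >= 0`. For seven indicators this is three.
#'
#' @param p number of observed variables (>= 1).
#' @return integer, the largest admissible factor count (possibly 0).
#' @export
max_factors <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop("`p` must be a single integer >= 1", call. = FALSE)
  k <- 0L
  while (k + 1L < p && factor_df(p, k + 1L) >= 0) k <- k + 1L
  k
}

factor_df <- function(p, k) ((p - k)^2 - (p + k)) / 2

# Profile negative log-likelihood of the k-factor model as a function of
# the uniquenesses: with loadings concentrated out via the eigenstructure
# of Psi^{-1/2} R Psi^{-1/2}, only the p - k smallest eigenvalues remain.
fa_objective <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  ev <- eigen(R * outer(sc, sc), symmetric = TRUE, only.values = TRUE)$values
  p <- nrow(R)
  tail_ev <- pmax(ev[(k + 1):p], .Machine$double.eps)
  sum(tail_ev - log(tail_ev)) - (p - k)
}

fa_loadings_from_psi <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  ed <- eigen(R * outer(sc, sc), symmetric = TRUE)
  load <- ed$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ed$values[seq_len(k)] - 1, 0)), k, k)
  load * sqrt(psi)
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Fits the orthogonal `k`-factor model to the sample correlation matrix by
#' maximum likelihood, profiling the loadings out of the likelihood and
#' optimizing the uniquenesses under box constraints (avoiding Heywood
#' cases), then varimax-rotates the loadings (Kaiser normalization). The
#' fit is assessed with the Bartlett-corrected likelihood-ratio test
#' against an unconstrained correlation matrix. Per-sample scores are
#' regression (Thomson) scores.
#'
#' @param X standardized indicator matrix from [standardize_indicators()].
#' @param k number of factors, `1 <= k <= max_factors(ncol(X))`.
#' @param n_restarts extra random restarts of the optimizer (default 4).
#' @param rotate apply varimax rotation (default `TRUE`).
#' @return object of class `factor_solution`: list with `k`, `loadings`
#'   (p x k), `uniquenesses`, `scores` (n x k), `lrt_statistic`, `lrt_df`,
#'   `lrt_p`, `criterion` (profile discrepancy at the optimum), `rotation`.
#' @export
fit_factor_model <- function(X, k, n_restarts = 4, rotate = TRUE) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  kmax <- max_factors(p)
  if (k < 1 || k > kmax)
    stop("`k` must be between 1 and max_factors(p) = ", kmax, call. = FALSE)
  if (n <= p) stop("need more samples than indicators", call. = FALSE)
  R <- cor(X)
  lower <- 0.005; upper <- 1
  starts <- list((1 - 0.5 * k / p) / diag(solve(R)))
  for (r in seq_len(n_restarts))  # deterministic low-discrepancy restarts
    starts[[r + 1]] <- 0.1 + 0.8 * ((seq_len(p) * r * 0.381966) %% 1)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(st, lower), upper), fa_objective, R = R, k = k,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("factor model failed to converge", call. = FALSE)
  psi <- best$par
  load <- fa_loadings_from_psi(psi, R, k)
  rotation <- "none"
  if (rotate && k > 1) {
    load <- varimax(load, normalize = TRUE)$loadings[, , drop = FALSE]
    load <- load[, order(-colSums(load^2)), drop = FALSE]
    rotation <- "varimax"
  } else if (rotate) rotation <- "varimax"
  # sign convention: the largest-magnitude loading in each column positive
  for (j in seq_len(k))
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  dimnames(load) <- list(colnames(X), paste0("factor", seq_len(k)))
  names(psi) <- colnames(X)
  stat <- (n - 1 - (2 * p + 5) / 6 - 2 * k / 3) * best$value
  df <- factor_df(p, k)
  pval <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  sol <- structure(list(k = k, loadings = load, uniquenesses = psi,
                        rotation = rotation, lrt_statistic = stat,
                        lrt_df = df, lrt_p = pval, criterion = best$value,
                        correlation = R, n = n),
                   class = "factor_solution")
  sol$scores <- factor_scores(sol, X)
  sol
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("ML factor solution: k = %d (%s rotation)\n", x$k, x$rotation))
  cat("Loadings:\n"); print(round(x$loadings, 3))
  cat(sprintf("LRT: chi-sq = %.3f, df = %d, p = %.4g\n",
              x$lrt_statistic, as.integer(x$lrt_df), x$lrt_p))
  invisible(x)
}

#' Per-sample regression (Thomson) factor scores
#'
#' `f = X R^{-1} Lambda`, with `R` the sample correlation matrix the
#' solution was fitted to.
#'
#' @param solution a `factor_solution`.
#' @param X the standardized indicator matrix the model was fitted on.
#' @return n x k matrix of scores with (approximately) zero column means.
#' @export
factor_scores <- function(solution, X) {
  X <- as.matrix(X)
  R <- solution$correlation
  inv <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix", call. = FALSE))
  f <- X %*% inv %*% solution$loadings
  dimnames(f) <- list(rownames(X), colnames(solution$loadings))
  f
}

#' Choose the number of factors by sequential likelihood-ratio testing
#'
#' Fits k = 1, 2, ... factors and applies a sequential stopping rule based
#' on the likelihood-ratio fit test, never exceeding `max_factors(p)`. Two
#' rule directions are provided: `"stop_when_significant"` stops as soon as
#' the fit test rejects (p < `alpha`), while the conventional
#' `"stop_when_adequate"` stops as soon as the model fits adequately
#' (p >= `alpha`), so poorly fitting models are enlarged. See the package
#' vignette for why both are offered.
#'
#' @inheritParams fit_factor_model
#' @param alpha significance level of the fit test (default 0.05).
#' @param direction stopping-rule direction (see Details).
#' @return the selected `factor_solution`, with an extra element
#'   `selection_log`: data frame of (k, lrt_statistic, lrt_df, lrt_p).
#' @export
select_num_factors <- function(X, alpha = 0.05,
                               direction = c("stop_when_significant",
                                             "stop_when_adequate"),
                               n_restarts = 4) {
  direction <- match.arg(direction)
  p <- ncol(X)
  kmax <- max_factors(p)
  log_rows <- list(); sol <- NULL
  for (k in seq_len(kmax)) {
    sol <- fit_factor_model(X, k, n_restarts = n_restarts)
    log_rows[[k]] <- data.frame(k = k, lrt_statistic = sol$lrt_statistic,
                                lrt_df = sol$lrt_df, lrt_p = sol$lrt_p)
    stop_now <- if (direction == "stop_when_significant")
      isTRUE(sol$lrt_p < alpha) else isTRUE(sol$lrt_p >= alpha)
    if (stop_now) break
  }
  sol$selection_log <- do.call(rbind, log_rows)
  sol
}
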