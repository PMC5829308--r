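#' Ordinary least-squares fit with labelled terms
#'
#' QR-based least squares with classical standard errors, per-coefficient
#' t-tests, R-squared and the overall F-test. Refuses rank-deficient
#' designs, naming the aliased columns.
#'
#' @param y numeric response.
#' @param X numeric design matrix (no intercept column; one is added).
#' @param add_intercept add an intercept column (default `TRUE`).
#' @return object of class `linear_fit`: `coefficients` (matrix with
#'   columns estimate, se, t, p), `r_squared`, `f_statistic`, `f_df`,
#'   `f_p`, `df_residual`, `sigma2`, `rss`, plus the `design` and
#'   response used.
#' @export
ols_fit <- function(y, X, add_intercept = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept)
    X <- cbind(`(Intercept)` = rep(1, NROW(X)), X)
  n <- length(y)
  if (nrow(X) != n) stop("length(y) != nrow(X)", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (n <= qrx$rank) stop("need n > rank(design)", call. = FALSE)
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  df_res <- n - qrx$rank
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  names(se) <- colnames(X)[qrx$pivot]
  se <- se[colnames(X)]
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_res)
  tss <- sum((y - if (add_intercept) mean(y) else 0)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  k <- qrx$rank - add_intercept
  fstat <- if (k > 0 && rss > 0) ((tss - rss) / k) / sigma2 else NA_real_
  structure(list(
    coefficients = cbind(estimate = beta, se = se, t = tval, p = pval),
    r_squared = r2, f_statistic = fstat, f_df = c(k, df_res),
    f_p = if (is.na(fstat)) NA_real_ else pf(fstat, k, df_res,
                                             lower.tail = FALSE),
    df_residual = df_res, sigma2 = sigma2, rss = rss,
    design = X, y = y), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear model fit\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared = %.4f; F(%d, %d) = %.3f, p = %.4g\n",
              x$r_squared, x$f_df[1], x$f_df[2], x$f_statistic, x$f_p))
  invisible(x)
}

build_design <- function(data, terms) {
  mm <- stats::model.matrix(stats::reformulate(terms), data = data)
  assign <- attr(mm, "assign")
  labels <- attr(stats::terms(stats::reformulate(terms)), "term.labels")
  list(X = mm[, -1, drop = FALSE], assign = assign[-1], labels = labels)
}

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# a term is droppable when no retained higher-order term contains all of
# its variables (marginality)
droppable_terms <- function(terms) {
  vapply(terms, function(t) {
    tv <- term_vars(t)
    !any(vapply(setdiff(terms, t), function(o)
      all(tv %in% term_vars(o)), logical(1)))
  }, logical(1))
}

#' Backward model selection by nested F-tests
#'
#' Starting from the full model, repeatedly removes the least significant
#' droppable term (nested-model F-test p above `alpha_drop`), respecting
#' marginality: a main effect is never removed while one of its
#' interactions remains. The full elimination path is recorded.
#'
#' @param data data frame of covariates.
#' @param y numeric response, aligned with `data` rows.
#' @param terms character vector of term labels (interactions as `"a:b"`).
#' @param alpha_drop removal threshold for the nested F-test p-value
#'   (default 0.05).
#' @return list of class `model_selection`: `fit` (the final
#'   `linear_fit`), `terms` (retained labels), `path` (data frame logging
#'   every considered removal), and `data`.
#' @export
backward_select <- function(data, y, terms, alpha_drop = 0.05) {
  current <- terms
  path <- list()
  fit_terms <- function(tt) {
    if (length(tt) == 0)
      return(ols_fit(y, matrix(numeric(0), nrow = length(y), ncol = 0)))
    d <- build_design(data, tt)
    ols_fit(y, d$X)
  }
  fit <- fit_terms(current)
  step <- 0L
  repeat {
    if (length(current) == 0) break
    cand <- current[droppable_terms(current)]
    stats_tab <- lapply(cand, function(t) {
      reduced <- setdiff(current, t)
      rfit <- fit_terms(reduced)
      df_num <- rfit$df_residual - fit$df_residual
      fval <- ((rfit$rss - fit$rss) / df_num) / fit$sigma2
      data.frame(step = step, term = t, f = fval, df = df_num,
                 p = pf(fval, df_num, fit$df_residual, lower.tail = FALSE))
    })
    stats_tab <- do.call(rbind, stats_tab)
    path[[length(path) + 1L]] <- stats_tab
    worst <- which.max(stats_tab$p)
    if (stats_tab$p[worst] <= alpha_drop) break
    current <- setdiff(current, stats_tab$term[worst])
    fit <- fit_terms(current)
    step <- step + 1L
  }
  structure(list(fit = fit, terms = current,
                 path = if (length(path)) do.call(rbind, path)
                        else data.frame(),
                 data = data), class = "model_selection")
}

#' Interaction prediction profile
#'
#' For a fitted model containing `focal`, `moderator` and their
#' interaction, computes the predicted response line over the focal range
#' at each of `steps` moderator values from 0 to the maximum observed,
#' holding every other covariate at zero (its reference after
#' standardization). This is the family of prediction lines used to
#' visualise how the moderator amplifies the focal effect.
#'
#' @param fit a `linear_fit` whose design contains columns `focal`,
#'   `moderator`, and their interaction (`"focal:moderator"` in either
#'   order).
#' @param focal,moderator design column names.
#' @param steps number of moderator values (default 100).
#' @param moderator_max maximum moderator value; defaults to the maximum
#'   in the fitted design.
#' @param focal_range range of the focal variable for the line endpoints;
#'   defaults to its observed range.
#' @return data frame with one row per step: `step`, `moderator_value`,
#'   `intercept`, `slope`, `pred_at_min`, `pred_at_max`.
#' @export
prediction_profile <- function(fit, focal, moderator, steps = 100,
                               moderator_max = NULL, focal_range = NULL) {
  b <- fit$coefficients[, "estimate"]
  int_name <- if (paste(focal, moderator, sep = ":") %in% names(b))
    paste(focal, moderator, sep = ":")
  else if (paste(moderator, focal, sep = ":") %in% names(b))
    paste(moderator, focal, sep = ":")
  else stop("model has no ", focal, " x ", moderator, " interaction term",
            call. = FALSE)
  if (!all(c(focal, moderator) %in% names(b)))
    stop("focal or moderator main effect missing from fit", call. = FALSE)
  X <- fit$design
  moderator_max <- moderator_max %||% max(X[, moderator])
  focal_range <- focal_range %||% range(X[, focal])
  mvals <- seq(0, moderator_max, length.out = steps)
  b0 <- if ("(Intercept)" %in% names(b)) b[["(Intercept)"]] else 0
  intercept <- b0 + b[[moderator]] * mvals
  slope <- b[[focal]] + b[[int_name]] * mvals
  data.frame(step = seq_len(steps), moderator_value = mvals,
             intercept = intercept, slope = slope,
             pred_at_min = intercept + slope * focal_range[1],
             pred_at_max = intercept + slope * focal_range[2])
}
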