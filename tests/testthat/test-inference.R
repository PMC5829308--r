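test_that("OLS matches exact and normal-equation solutions", {
  x <- 1:10
  fit <- ols_fit(2 * x, cbind(x = x))
  expect_equal(unname(fit$coefficients["x", "estimate"]), 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(20:60, 1); k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n, k); y <- rnorm(n)
    fit <- ols_fit(y, X)
    Xi <- cbind(1, X)
    beta <- solve(crossprod(Xi), crossprod(Xi, y))  # normal equations
    expect_equal(unname(fit$coefficients[, "estimate"]), as.vector(beta),
                 tolerance = 1e-10)
    ref <- summary(lm(y ~ X))
    expect_equal(unname(fit$coefficients[, "se"]),
                 unname(ref$coefficients[, "Std. Error"]), tolerance = 1e-10)
    expect_equal(fit$r_squared, ref$r.squared, tolerance = 1e-10)
    expect_equal(unname(fit$f_statistic), unname(ref$fstatistic[1]),
                 tolerance = 1e-10)
  }
  X <- cbind(a = rnorm(30))
  expect_error(ols_fit(rnorm(30), cbind(X, b = 2 * X[, "a"])), "aliased")
})

test_that("backward selection respects marginality and nestedness", {
  set.seed(42)
  n <- 213
  dat <- data.frame(modernity = rnorm(n), power = rnorm(n),
                    subsistence = rnorm(n), age = rnorm(n))
  y <- 2 - 1.5 * dat$modernity - 0.8 * dat$modernity * dat$power +
    rnorm(n)
  sel <- backward_select(dat, y,
                         c("modernity", "power", "subsistence", "age",
                           "modernity:power"))
  expect_true(all(c("modernity", "power", "modernity:power") %in% sel$terms))
  expect_false("subsistence" %in% sel$terms)
  # interaction retained implies both main effects retained
  expect_true(all(c("modernity", "power") %in% sel$terms))
  # dropping terms never increased R^2 along the path
  full_fit <- ols_fit(y, migut:::build_design(
    dat, c("modernity", "power", "subsistence", "age",
           "modernity:power"))$X)
  expect_lte(sel$fit$r_squared, full_fit$r_squared + 1e-12)
  # all-null predictors: no crash, few terms survive
  y0 <- rnorm(n)
  sel0 <- backward_select(dat, y0, c("modernity", "power", "age"))
  expect_true(length(sel0$terms) <= 3)
  expect_s3_class(sel0$fit, "linear_fit")
})

test_that("prediction profiles sweep the moderator as specified", {
  set.seed(7)
  n <- 150
  dat <- data.frame(m = rnorm(n), p = pmax(rnorm(n, 1), 0))
  y <- 1 + 2 * dat$m - 0.5 * dat$p - 1.2 * dat$m * dat$p + rnorm(n, sd = .1)
  d <- migut:::build_design(dat, c("m", "p", "m:p"))
  fit <- ols_fit(y, d$X)
  prof <- prediction_profile(fit, "m", "p", steps = 100)
  expect_equal(nrow(prof), 100L)
  expect_equal(prof$moderator_value[1], 0)
  expect_equal(prof$moderator_value[100], max(dat$p))
  # moderator at zero: the line is intercept + focal main effect
  b <- fit$coefficients[, "estimate"]
  expect_equal(prof$slope[1], unname(b["m"]), tolerance = 1e-12)
  expect_equal(prof$intercept[1], unname(b["(Intercept)"]),
               tolerance = 1e-12)
  # hand-computed prediction at an interior grid point
  i <- 37
  mv <- prof$moderator_value[i]
  x0 <- max(dat$m)
  expect_equal(prof$pred_at_max[i],
               unname(b["(Intercept)"] + b["m"] * x0 + b["p"] * mv +
                        b["m:p"] * x0 * mv), tolerance = 1e-10)
  expect_error(prediction_profile(ols_fit(y, d$X[, 1:2]), "m", "p"),
               "interaction")
})

test_that("PERMANOVA reproduces classical ANOVA on Euclidean distances", {
  # hand case: one-way ANOVA F = 5.0
  y <- c(1, 2, 3, 5)
  g <- data.frame(grp = factor(c("A", "A", "B", "B")))
  tab <- permanova(as.matrix(dist(y)), g, "grp", n_perm = 0)
  expect_equal(tab$pseudo_f[1], 5.0, tolerance = 1e-10)
  set.seed(19)
  for (i in 1:50) {
    n <- sample(12:30, 1)
    yy <- rnorm(n)
    gg <- data.frame(grp = factor(sample(letters[1:3], n, replace = TRUE)))
    if (length(unique(gg$grp)) < 2) next
    tab <- permanova(as.matrix(dist(yy)), gg, "grp", n_perm = 0)
    ref <- anova(lm(yy ~ grp, data = gg))
    expect_equal(tab$pseudo_f[1], ref$`F value`[1], tolerance = 1e-8)
    expect_equal(tab$ss[1:2], ref$`Sum Sq`, tolerance = 1e-8)
  }
})

test_that("PERMANOVA matches the vegan sequential decomposition", {
  set.seed(8)
  n <- 40
  dat <- data.frame(a = rnorm(n),
                    b = factor(sample(letters[1:3], n, TRUE)))
  D <- dist(matrix(rnorm(n * 6), n, 6))
  mine <- permanova(as.matrix(D), dat, c("a", "b"), n_perm = 0)
  ref <- as.data.frame(vegan::adonis2(D ~ a + b, data = dat,
                                      permutations = 2, by = "terms"))
  expect_equal(mine$ss[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(mine$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(mine$r_squared[1:3], ref$R2[1:3], tolerance = 1e-8)
  # permutation p reproducible under a fixed seed
  p1 <- permanova(as.matrix(D), dat, c("a", "b"), n_perm = 199, seed = 3)
  p2 <- permanova(as.matrix(D), dat, c("a", "b"), n_perm = 199, seed = 3)
  expect_identical(p1$p, p2$p)
  dat$dup <- dat$a
  expect_error(permanova(as.matrix(D), dat, c("a", "dup")), "collinear")
  expect_error(permanova(matrix(c(0, 1, 2, 0), 2, 2), dat[1:2, ], "a"),
               "symmetric")
})

test_that("SS decomposition is exact and p-values are calibrated-ish", {
  set.seed(55)
  n <- 30
  D <- as.matrix(dist(matrix(rnorm(n * 4), n, 4)))
  dat <- data.frame(x = rnorm(n))
  tab <- permanova(D, dat, "x", n_perm = 99, seed = 1)
  expect_equal(sum(tab$ss[1:2]), tab$ss[3], tolerance = 1e-8)
  expect_lte(sum(tab$r_squared[1]), 1)
})

test_that("partial db-RDA removes the condition before constraining", {
  set.seed(91)
  n <- 48
  # condition orthogonal to constraints by construction
  cond <- data.frame(z = rep(c(-1, 1), each = n / 2))
  cons <- data.frame(x = rep(rnorm(n / 2), 2))
  Y <- matrix(rnorm(n * 5), n, 5)
  D <- as.matrix(dist(Y))
  with_cond <- partial_dbrda(D, cons, condition = cond, n_perm = 0)
  no_cond <- partial_dbrda(D, cons, n_perm = 0)
  # exactly orthogonal null condition leaves the constrained axes untouched
  expect_equal(with_cond$eigenvalues, no_cond$eigenvalues,
               tolerance = 1e-6)
  # with a null orthogonal condition removed exactly (projection check):
  expect_lt(abs(with_cond$inertia["conditioned"] +
                  with_cond$inertia["constrained"] +
                  with_cond$inertia["unconstrained"] -
                  with_cond$inertia["total"]), 1e-8)
  # grouping constraints reproduce the PERMANOVA decomposition
  grp <- data.frame(g = factor(rep(letters[1:3], length.out = n)))
  ord <- partial_dbrda(D, grp, n_perm = 0)
  tab <- permanova(D, grp, "g", n_perm = 0)
  expect_equal(unname(ord$inertia["constrained"]), tab$ss[1],
               tolerance = 1e-8)
  expect_equal(unname(ord$pseudo_f), tab$pseudo_f[1], tolerance = 1e-8)
  # zero distances: no structure at all
  zero <- matrix(0, 12, 12)
  ord0 <- partial_dbrda(zero, data.frame(x = rnorm(12)), n_perm = 0)
  expect_equal(unname(ord0$eigenvalues), rep(0, length(ord0$eigenvalues)))
  expect_error(partial_dbrda(D, data.frame(x = cons$x, y = cons$x)),
               "collinear")
})

test_that("partial db-RDA agrees with the vegan reference on eigenvalues", {
  set.seed(14)
  n <- 36
  Y <- matrix(rnorm(n * 5), n, 5)
  D <- dist(Y)
  cons <- data.frame(x = rnorm(n), g = factor(rep(letters[1:2],
                                                  length.out = n)))
  cond <- data.frame(z = rnorm(n))
  mine <- partial_dbrda(as.matrix(D), cons, condition = cond, n_perm = 0)
  ref <- vegan::capscale(D ~ x + g + Condition(z), data = cbind(cons, cond))
  # vegan reports variance (SS / (n - 1)); this package reports SS
  expect_equal(unname(mine$eigenvalues[1:2]), unname(ref$CCA$eig) * (n - 1),
               tolerance = 1e-6)
  expect_equal(unname(mine$inertia["constrained"]),
               unname(sum(ref$CCA$eig)) * (n - 1), tolerance = 1e-6)
  expect_equal(unname(mine$inertia["conditioned"]),
               unname(ref$pCCA$tot.chi) * (n - 1), tolerance = 1e-6)
})

test_that("BY adjustment matches the independent step-up oracle", {
  expect_equal(by_adjust(c(0.01, 0.02, 0.04)),
               c(0.0550, 0.0550, 11 / 150), tolerance = 1e-10)
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(by_adjust(0.037), 0.037)       # m = 1: c(1) = 1
  set.seed(66)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(by_adjust(p), oracle_by(p), tolerance = 1e-12)
    expect_equal(by_adjust(p), p.adjust(p, method = "BY"),
                 tolerance = 1e-12)
  }
  expect_error(by_adjust(c(0.5, 1.2)), "0, 1")
  expect_equal(by_adjust(c(0.2, NA, 0.01)),
               c(p.adjust(c(0.2, 0.01), "BY")[1], NA,
                 p.adjust(c(0.2, 0.01), "BY")[2]))
})

test_that("the correlation screen flags linear OTUs and skips constants", {
  set.seed(10)
  n <- 60
  scores <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(NULL, c("modernity", "subsistence",
                                           "power")))
  abund <- matrix(rnorm(n * 8), n, 8,
                  dimnames = list(NULL, paste0("OTU_", 1:8)))
  abund[, 1] <- 3 * scores[, 1]          # exactly linear in modernity
  abund[, 2] <- 5                        # constant
  res <- correlation_screen(abund, scores)
  r1 <- subset(res, otu == "OTU_1" & factor == "modernity")
  expect_equal(r1$r, 1, tolerance = 1e-10)
  expect_true(r1$significant)
  expect_equal(r1$sign, "+")
  r2 <- subset(res, otu == "OTU_2")
  expect_true(all(is.na(r2$r)))
  expect_true(all(is.na(r2$p_adjusted)))
  expect_true(all(res$p_adjusted >= res$p - 1e-12, na.rm = TRUE))
  # t statistics agree with cor.test
  r3 <- subset(res, otu == "OTU_3" & factor == "power")
  ct <- cor.test(abund[, 3], scores[, "power"])
  expect_equal(r3$p, ct$p.value, tolerance = 1e-10)
  expect_error(correlation_screen(abund[1:2, ], scores[1:2, ]), "3 samples")
})
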