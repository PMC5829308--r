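toy_tree <- function() ape::read.tree(text = "((A:1,B:0.5):0.5,C:2);")

test_that("read filter keeps samples at the boundary and logs removals", {
  counts <- rbind(a = c(10000, 9999), b = c(10000, 10000),
                  c = c(200000, 0))
  colnames(counts) <- c("OTU_1", "OTU_2")
  kept <- filter_samples(counts, min_reads = 20000)
  expect_setequal(rownames(kept), c("b", "c"))   # 19,999 removed, 20,000 kept
  expect_identical(attr(kept, "removed"), "a")
  expect_equal(unname(filter_samples(counts, min_reads = 0)),
               unname(counts), ignore_attr = TRUE)
  expect_error(filter_samples(counts, min_reads = 1e9), "below")
})

test_that("rarefaction conserves depth, zeros, and the expected mean", {
  set.seed(2)
  counts <- matrix(rpois(5 * 30, 50), 5, 30,
                   dimnames = list(paste0("s", 1:5), paste0("OTU_", 1:30)))
  counts[, 7] <- 0
  r <- rarefy(counts, 500, seed = 1)
  expect_true(all(rowSums(r) == 500))
  expect_true(all(r[, 7] == 0))                   # zero pattern preserved
  expect_true(all(r <= counts))
  # full draw leaves counts unchanged
  one <- counts[1, , drop = FALSE]
  expect_identical(unname(rarefy(one, sum(one), seed = 1)), unname(one))
  expect_error(rarefy(counts, sum(counts[1, ]) + 1e6), "exceeds")
  expect_identical(rarefy(counts, 500, seed = 9),
                   rarefy(counts, 500, seed = 9))
  # hypergeometric expectation: mean rarefied count ~ depth * proportion
  tot <- sum(counts[1, ])
  draws <- sapply(1:400, function(s) rarefy(one, 200, seed = s)[1, 2])
  expect_lt(abs(mean(draws) - 200 * counts[1, 2] / tot),
            3 * sd(draws) / sqrt(400))
})

test_that("size factors scale correctly and stabilise variance", {
  base <- matrix(rpois(3 * 40, 100), 3, 40,
                 dimnames = list(paste0("s", 1:3), paste0("OTU_", 1:40)))
  doubled <- rbind(base, s4 = 2 * base[1, ])
  tf <- size_factor_transform(doubled)
  s <- attr(tf, "size_factors")
  expect_equal(unname(s["s4"] / s["s1"]), 2, tolerance = 1e-10)
  same <- base[c(1, 1, 1), ]
  expect_equal(var(attr(size_factor_transform(same), "size_factors")), 0)
  expect_error(size_factor_transform(cbind(c(0, 5), c(5, 0))), "pseudo")
  # log-scale transform shrinks cross-sample variance for high-count OTUs
  set.seed(4)
  mu <- rlnorm(60, 4, 1)
  raw <- t(sapply(1:20, function(i) rpois(60, mu * runif(1, 0.5, 2))))
  colnames(raw) <- paste0("OTU_", 1:60)
  tf2 <- size_factor_transform(raw)
  high <- which(mu > quantile(mu, 0.75))
  expect_true(mean(apply(tf2[, high], 2, var)) <
                mean(apply(raw[, high], 2, var)))
})

test_that("Faith's PD matches hand values on the toy tree", {
  tr <- toy_tree()
  expect_equal(faith_pd("A", tr), 1.5)
  expect_equal(faith_pd(c("A", "B"), tr), 2.0)
  expect_equal(faith_pd(c("A", "B", "C"), tr), 4.0)
  expect_equal(faith_pd(character(0), tr), 0)
  # MRCA-rooted variant drops the root path
  expect_equal(faith_pd(c("A", "B"), tr, include_root = FALSE), 1.5)
  expect_equal(faith_pd("A", tr, include_root = FALSE), 0)
  expect_error(faith_pd("Z", tr), "absent")
})

test_that("PD equals the exhaustive branch-enumeration oracle", {
  set.seed(31)
  for (i in 1:100) {
    tr <- simulate_tree(sample(3:12, 1), seed = 1000 + i)
    present <- sample(tr$tip.label, sample(seq_along(tr$tip.label), 1))
    expect_equal(faith_pd(present, tr), oracle_pd(present, tr),
                 tolerance = 1e-10)
  }
  # monotone: adding a taxon never decreases PD
  tr <- simulate_tree(20, seed = 5)
  sub <- sample(tr$tip.label, 8)
  expect_gte(faith_pd(c(sub, sample(setdiff(tr$tip.label, sub), 1)), tr),
             faith_pd(sub, tr))
})

test_that("weighted UniFrac matches hand values and the oracle", {
  tr <- toy_tree()
  expect_equal(weighted_unifrac(c(A = 1), c(A = 1), tr), 0)
  expect_equal(weighted_unifrac(c(A = 1), c(C = 1), tr, normalized = FALSE),
               3.5)
  expect_equal(weighted_unifrac(c(A = 1), c(C = 1), tr), 1.0)
  expect_equal(weighted_unifrac(c(A = 0.5, B = 0.5), c(A = 1), tr,
                                normalized = FALSE), 0.75)
  expect_equal(weighted_unifrac(c(A = 0.5, B = 0.5), c(A = 1), tr),
               0.75 / 2.75)
  expect_error(weighted_unifrac(c(A = -0.1, B = 1.1), c(A = 1), tr),
               "non-negative")
  set.seed(17)
  for (i in 1:100) {
    tr <- simulate_tree(sample(3:12, 1), seed = 2000 + i)
    pa <- random_community(tr); pb <- random_community(tr)
    expect_equal(weighted_unifrac(pa, pb, tr, normalized = FALSE),
                 oracle_wunifrac(pa, pb, tr, normalized = FALSE),
                 tolerance = 1e-10)
    wn <- weighted_unifrac(pa, pb, tr)
    expect_equal(wn, oracle_wunifrac(pa, pb, tr), tolerance = 1e-10)
    expect_true(wn >= 0 && wn <= 1 + 1e-12)
  }
})

test_that("pairwise distances are metric-shaped and match phyloseq", {
  set.seed(23)
  tr <- simulate_tree(50, seed = 10)
  counts <- matrix(rpois(20 * 50, 20), 20, 50,
                   dimnames = list(paste0("S", 1:20), tr$tip.label))
  rel <- relative_abundance(counts)
  for (norm in c(TRUE, FALSE)) {
    D <- pairwise_distances(rel, tr, normalized = norm)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(counts, taxa_are_rows = FALSE),
      phyloseq::phy_tree(tr))
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                       normalized = norm))
    expect_lt(max(abs(D - ref[rownames(D), colnames(D)])), 1e-8)
  }
  # identical samples give a zero block; duplicating adds a zero pair
  rel3 <- rel[c(1, 1, 1), ]
  rownames(rel3) <- paste0("dup", 1:3)
  expect_true(all(pairwise_distances(rel3, tr) == 0))
})

test_that("normalized UniFrac hits 1 only when no branch is shared", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:2):1.5);")
  pa <- c(A = 0.5, B = 0.5)
  pb <- c(C = 0.3, D = 0.7)
  expect_equal(weighted_unifrac(pa, pb, tr), 1.0)  # clade-disjoint supports
  mix <- c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)
  expect_lt(weighted_unifrac(pa, mix, tr), 1.0)
})
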