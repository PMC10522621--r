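# two groups of Dirichlet-like profiles concentrated on different
# category blocks
clustered_profiles <- function(n_per, n_cat = 10, shape_hi = 9,
                               shape_lo = 1) {
  half <- n_cat %/% 2
  a <- cbind(matrix(rgamma(n_per * half, shape_hi), n_per),
             matrix(rgamma(n_per * (n_cat - half), shape_lo), n_per))
  b <- cbind(matrix(rgamma(n_per * half, shape_lo), n_per),
             matrix(rgamma(n_per * (n_cat - half), shape_hi), n_per))
  prof <- rbind(a, b)
  rownames(prof) <- paste0("s", seq_len(2 * n_per))
  prof / rowSums(prof)
}

test_that("Morisita-Horn matches its closed form and limits", {
  expect_equal(morisita_horn(c(0.5, 0.5), c(0.5, 0.5)), 1)
  expect_equal(morisita_horn(c(1, 0), c(0, 1)), 0)
  expect_equal(morisita_horn(c(1, 0), c(0.5, 0.5)), 2 / 3,
               tolerance = 1e-12)
  expect_error(morisita_horn(c(0, 0), c(1, 0)), "zero")
  # scale invariance: raw counts vs proportions
  expect_equal(morisita_horn(c(30, 10), c(2, 6)),
               morisita_horn(c(0.75, 0.25), c(0.25, 0.75)))
})

test_that("similarity matrix agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  prof <- matrix(rgamma(60, 2), 10, 6)
  rownames(prof) <- paste0("s", 1:10)
  s <- similarity_matrix(prof)
  expect_equal(max(abs(s - t(s))), 0)
  expect_true(all(diag(s) == 1))
  d_vegan <- as.matrix(vegan::vegdist(prof, method = "horn"))
  expect_equal(1 - s, d_vegan, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ANOSIM hits its limit cases", {
  # perfect separation: all between > all within
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  res <- anosim(d, rep(c("a", "b"), each = 3), seed = 1)
  expect_equal(res$observed, 1)
  # all dissimilarities equal: R = 0
  d0 <- matrix(0.5, 6, 6)
  diag(d0) <- 0
  expect_equal(anosim(d0, rep(c("a", "b"), each = 3), seed = 1)$observed, 0)
  expect_error(anosim(d, c("a", "a", "a", "a", "a", "b")), "singleton")
})

test_that("exact permutation p equals the brute-force enumeration fraction", {
  set.seed(11)
  x <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(x))
  labels <- c("a", "a", "a", "b", "b", "b")
  res <- anosim(d, labels, seed = 1)
  expect_true(res$exact)
  perms <- all_permutations(labels)
  stats <- vapply(perms, function(p) brute_anosim_r(d, p), 0)
  p_brute <- mean(stats >= res$observed - 1e-12)
  expect_equal(res$p, p_brute, tolerance = 1e-12)
  resF <- permanova(d, labels, seed = 1)
  statsF <- vapply(perms, function(p) brute_pseudo_f(d, p), 0)
  expect_equal(resF$p, mean(statsF >= resF$observed - 1e-12),
               tolerance = 1e-12)
  expect_equal(resF$observed, brute_pseudo_f(d, labels), tolerance = 1e-12)
})

test_that("ANOSIM agrees with vegan and is rank-transform invariant", {
  skip_if_not_installed("vegan")
  set.seed(21)
  prof <- clustered_profiles(5, 8, shape_hi = 4, shape_lo = 2)
  lab <- rep(c("a", "b"), each = 5)
  d <- similarity_to_dissimilarity(similarity_matrix(prof))
  mine <- anosim(d, lab, seed = 2)
  vg <- vegan::anosim(as.dist(d), lab, permutations = 99)
  expect_equal(mine$observed, unname(vg$statistic), tolerance = 1e-12)
  # strictly monotone transform leaves the rank-based statistic unchanged
  expect_equal(anosim(sqrt(d), lab, seed = 2)$observed, mine$observed,
               tolerance = 1e-12)
})

test_that("Monte-Carlo p converges to the exact enumeration value", {
  set.seed(31)
  x <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(x))
  lab <- c("a", "a", "a", "b", "b", "b", "b")
  exact <- anosim(d, lab, seed = 1)
  expect_true(exact$exact)
  mc <- anosim(d, lab, n_perm = 4999, seed = 9, enumeration_cap = 0)
  expect_false(mc$exact)
  expect_gte(mc$p, 1 / 5000)
  expect_lt(abs(mc$p - exact$p), 0.03)
})

test_that("PERMANOVA flags degenerate zero-within-dissimilarity input", {
  d <- matrix(1, 4, 4)
  d[1:2, 1:2] <- 0
  d[3:4, 3:4] <- 0
  diag(d) <- 0
  res <- permanova(d, c("a", "a", "b", "b"), seed = 1)
  expect_true(res$degenerate)
  expect_true(is.infinite(res$observed))
})

test_that("PERMANOVA detects a planted two-cluster structure", {
  set.seed(41)
  prof <- clustered_profiles(10)
  lab <- rep(c("a", "b"), each = 10)
  d <- similarity_to_dissimilarity(similarity_matrix(prof))
  res <- permanova(d, lab, n_perm = 999, seed = 5)
  expect_lte(res$p, 0.05)
})

test_that("PERMDISP centroid distances match brute force on embeddable input", {
  set.seed(51)
  x <- matrix(rnorm(36), 12, 3)
  d <- as.matrix(dist(x))
  lab <- rep(c("a", "b", "c"), each = 4)
  res <- permdisp(d, lab, n_perm = 99, seed = 1)
  brute <- numeric(12)
  for (g in unique(lab)) {
    i <- lab == g
    cen <- colMeans(x[i, ])
    brute[i] <- sqrt(rowSums(sweep(x[i, ], 2, cen)^2))
  }
  expect_equal(res$centroid_distances, brute, tolerance = 1e-8)
})

test_that("PERMDISP separates tight from diffuse clusters, not equal ones", {
  set.seed(61)
  tight <- matrix(rnorm(40, sd = 0.05), 20, 2)
  diffuse <- matrix(rnorm(40, sd = 1.5), 20, 2)
  d <- as.matrix(dist(rbind(tight, diffuse)))
  lab <- rep(c("t", "d"), each = 20)
  res <- permdisp(d, lab, n_perm = 999, seed = 3)
  expect_lte(res$p, 0.05)
  # identical internal geometry: F ~ 0, p high
  shape <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(rbind(shape, shape + 100)))
  res2 <- permdisp(d2, rep(c("a", "b"), each = 10), n_perm = 999, seed = 3)
  expect_lt(res2$observed, 1e-6)
  expect_gt(res2$p, 0.5)
})

test_that("NMDS embeds planar configurations with near-zero stress", {
  xy <- cbind(c(0, 3, 3, 0, 1.5), c(0, 0, 2, 2, 1))
  d <- as.matrix(dist(xy))
  res <- nmds(d, k = 2, restarts = 10, seed = 2)
  expect_lt(res$stress, 0.01)
})

procrustes_gap <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  sv <- svd(crossprod(b, a))
  sqrt(max(0, 1 - sum(sv$d)^2))
}

test_that("NMDS is invariant to input order and monotone transforms", {
  set.seed(71)
  prof <- matrix(rgamma(96, 2), 12, 8)
  d <- similarity_to_dissimilarity(similarity_matrix(prof))
  res <- nmds(d, restarts = 20, seed = 4)
  perm <- sample(nrow(d))
  res_p <- nmds(d[perm, perm], restarts = 20, seed = 4)
  gap <- procrustes_gap(res$points, res_p$points[order(perm), ])
  expect_lt(gap, 0.02)
  # rank-preserving transform: stress unchanged within tolerance
  res_t <- nmds(d^1.7, restarts = 20, seed = 4)
  expect_lt(abs(res_t$stress - res$stress), 0.01)
})

test_that("between-species similarity matches hand computation in both modes", {
  prof <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0.5, 0.5))
  rownames(prof) <- paste0("s", 1:4)
  lab <- c("A", "A", "B", "B")
  # identical single profiles -> 100 in either mode
  same <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  rownames(same) <- c("x", "y")
  for (mode in c("mean-pairwise", "pooled")) {
    bs <- between_group_similarity(same, c("A", "B"), mode = mode)
    expect_equal(bs["A", "B"], 100)
  }
  # disjoint diets -> 0
  disj <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  rownames(disj) <- paste0("d", 1:4)
  expect_equal(
    between_group_similarity(disj, c("A", "A", "B", "B"))["A", "B"], 0)
  # hand-computed mean over the four cross pairs
  hand <- 100 * mean(c(
    morisita_horn(prof[1, ], prof[3, ]), morisita_horn(prof[1, ], prof[4, ]),
    morisita_horn(prof[2, ], prof[3, ]), morisita_horn(prof[2, ], prof[4, ])
  ))
  bs <- between_group_similarity(prof, lab)
  expect_equal(bs["A", "B"], hand, tolerance = 1e-12)
  expect_error(between_group_similarity(prof, lab, mode = "nope"))
})

test_that("permutation p-values never drop below 1/(n_perm + 1)", {
  set.seed(81)
  prof <- clustered_profiles(5)
  lab <- rep(c("a", "b"), each = 5)
  d <- similarity_to_dissimilarity(similarity_matrix(prof))
  res <- anosim(d, lab, n_perm = 99, seed = 1, enumeration_cap = 0)
  expect_gte(res$p, 1 / 100)
})
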