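## Overlap and permutation statistics, implemented from scratch:
## Morisita-Horn similarity, ANOSIM, one-way PERMANOVA, PERMDISP, NMDS.

#' Morisita-Horn similarity between two composition vectors
#'
#' `Cmh = 2 * sum(p*q) / (sum(p^2) + sum(q^2))` on internally renormalized
#' nonnegative vectors: 1 for identical compositions, 0 for disjoint
#' support. Insensitive to total sample size.
#'
#' @param p,q nonnegative vectors of equal length, each with positive sum.
#' @return Similarity in \[0, 1\].
#' @export
morisita_horn <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) <= 0 || sum(q) <= 0) stop("zero composition vector")
  p <- p / sum(p)
  q <- q / sum(q)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' Pairwise Morisita-Horn similarity matrix
#'
#' @param profiles matrix, rows = samples (renormalized internally).
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
similarity_matrix <- function(profiles) {
  p <- profiles / rowSums(profiles)
  cross <- p %*% t(p)
  ss <- rowSums(p^2)
  s <- 2 * cross / outer(ss, ss, `+`)
  diag(s) <- 1
  dimnames(s) <- list(rownames(profiles), rownames(profiles))
  attr(s, "metric") <- "morisita-horn"
  s
}

#' Convert a similarity matrix to dissimilarities
#'
#' Distance-based procedures in this package operate on `1 - Cmh`.
#'
#' @param s similarity matrix in \[0, 1\].
#' @return Dissimilarity matrix.
#' @export
similarity_to_dissimilarity <- function(s) {
  d <- 1 - s
  diag(d) <- 0
  d
}

as_dissimilarity_matrix <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), max(abs(d - t(d))) < 1e-8)
  d
}

## permutation machinery ------------------------------------------------------

# all distinct assignments of a label multiset to positions, as a matrix with
# one column per arrangement (rows = positions)
enumerate_labelings <- function(labels) {
  labels <- as.character(labels)
  rec <- function(remaining) {
    if (length(remaining) == 1L) return(matrix(remaining, nrow = 1L))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      sub <- rec(rest)
      out[[length(out) + 1L]] <- rbind(u, sub)
    }
    do.call(cbind, out)
  }
  rec(labels)
}

n_distinct_labelings <- function(labels) {
  tab <- table(labels)
  exp(lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

permutation_pvalue <- function(stat_fun, labels, n_perm, seed,
                               enumeration_cap = 1e5) {
  observed <- stat_fun(labels)
  n_arr <- n_distinct_labelings(labels)
  if (n_arr <= enumeration_cap) {
    all_lab <- enumerate_labelings(labels)
    stats <- apply(all_lab, 2L, stat_fun)
    p <- sum(stats >= observed - 1e-12) / ncol(all_lab)
    list(observed = observed, p = p, exact = TRUE,
         n_perm = ncol(all_lab), seed = seed)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats <- replicate(n_perm, stat_fun(sample(labels)))
    p <- (1 + sum(stats >= observed - 1e-12)) / (1 + n_perm)
    list(observed = observed, p = p, exact = FALSE,
         n_perm = n_perm, seed = seed)
  }
}

## ANOSIM ---------------------------------------------------------------------

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' `R = (mean rank between - mean rank within) / (M / 2)` with
#' `M = n(n-1)/2` ranked pairs, so `R = 1` when all between-group
#' dissimilarities exceed all within-group ones and `R = 0` under no
#' structure. The p-value permutes group labels; all distinct labelings are
#' enumerated when their number is at most `enumeration_cap`, otherwise
#' `n_perm` Monte-Carlo permutations are used (the observed labeling counts
#' as one arrangement, so `p >= 1/(n_perm + 1)`).
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param labels group membership, length `nrow(d)`; at least two groups of
#'   at least two samples each.
#' @param n_perm Monte-Carlo permutations.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param enumeration_cap maximum number of arrangements to enumerate.
#' @return A list of class `permutation_result`: `statistic` (`"ANOSIM R"`),
#'   `observed`, `p`, `exact`, `n_perm`, `seed`.
#' @export
anosim <- function(d, labels, n_perm = 9999, seed = NULL,
                   enumeration_cap = 1e5) {
  d <- as_dissimilarity_matrix(d)
  check_groups(labels, nrow(d))
  lower <- lower.tri(d)
  ranks <- matrix(0, nrow(d), ncol(d))
  ranks[lower] <- rank(d[lower])
  ranks <- ranks + t(ranks)
  m <- sum(lower)
  stat_fun <- function(lab) {
    within <- outer(lab, lab, `==`) & lower
    (mean(ranks[!within & lower]) - mean(ranks[within])) / (m / 2)
  }
  res <- permutation_pvalue(stat_fun, as.character(labels), n_perm, seed,
                            enumeration_cap)
  structure(c(list(statistic = "ANOSIM R"), res),
            class = "permutation_result")
}

check_groups <- function(labels, n) {
  stopifnot(length(labels) == n)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("every group needs at least two samples; singleton group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
}

## PERMANOVA ------------------------------------------------------------------

#' One-way permutational multivariate analysis of variance (PERMANOVA)
#'
#' Direct sums-of-squares formulation on the dissimilarity matrix:
#' `SS_total = sum(d_ij^2) / n` over all pairs, `SS_within` the analogous
#' per-group quantity, and
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))`.
#' Zero within-group dissimilarity with nonzero between yields `Inf` with a
#' `degenerate` flag. p-value by label permutation as in [anosim()].
#'
#' @inheritParams anosim
#' @return A `permutation_result` with `statistic = "pseudo-F"`.
#' @export
permanova <- function(d, labels, n_perm = 9999, seed = NULL,
                      enumeration_cap = 1e5) {
  d <- as_dissimilarity_matrix(d)
  check_groups(labels, nrow(d))
  d2 <- d^2
  n <- nrow(d)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  stat_fun <- function(lab) {
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
    g <- length(unique(lab))
    ss_between <- ss_total - ss_within
    if (ss_within <= 1e-12) return(Inf)
    (ss_between / (g - 1)) / (ss_within / (n - g))
  }
  res <- permutation_pvalue(stat_fun, as.character(labels), n_perm, seed,
                            enumeration_cap)
  res$degenerate <- !is.finite(res$observed)
  structure(c(list(statistic = "pseudo-F"), res),
            class = "permutation_result")
}

## PERMDISP -------------------------------------------------------------------

# principal-coordinate embedding with Lingoes correction when the
# dissimilarity matrix is not Euclidean-embeddable
pcoa_embed <- function(d, tol = 1e-8) {
  n <- nrow(d)
  d2 <- d^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% d2 %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  lmin <- min(e$values)
  if (lmin < -tol * max(abs(e$values))) {
    # Lingoes: adding -2*lmin to squared off-diagonal dissimilarities makes
    # the matrix embeddable
    d2c <- d2 - 2 * lmin
    diag(d2c) <- 0
    g <- -0.5 * j %*% d2c %*% j
    e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  }
  keep <- e$values > tol * max(abs(e$values))
  x <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(x) <- rownames(d)
  x
}

#' Test for homogeneity of multivariate dispersion (PERMDISP)
#'
#' Samples are embedded by principal-coordinate decomposition of the
#' dissimilarity matrix (Lingoes correction applied when negative
#' eigenvalues arise); each sample's distance to its group centroid (mean in
#' the embedded space) is computed, and the observed statistic is the
#' one-way ANOVA F on those distances. The p-value permutes group labels
#' over the distances.
#'
#' @inheritParams anosim
#' @return A `permutation_result` with `statistic = "PERMDISP F"` and the
#'   per-sample `centroid_distances`.
#' @export
permdisp <- function(d, labels, n_perm = 9999, seed = NULL,
                     enumeration_cap = 1e5) {
  d <- as_dissimilarity_matrix(d)
  check_groups(labels, nrow(d))
  x <- pcoa_embed(d)
  labels <- as.character(labels)
  dist_to_centroid <- numeric(nrow(x))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    cen <- colMeans(x[idx, , drop = FALSE])
    dist_to_centroid[idx] <-
      sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, cen)^2))
  }
  anova_f <- function(lab) {
    gm <- tapply(dist_to_centroid, lab, mean)
    ng <- tapply(dist_to_centroid, lab, length)
    grand <- mean(dist_to_centroid)
    ss_b <- sum(ng * (gm - grand)^2)
    ss_w <- sum((dist_to_centroid - gm[lab])^2)
    k <- length(gm)
    n <- length(lab)
    if (ss_w <= 1e-15) return(Inf)
    (ss_b / (k - 1)) / (ss_w / (n - k))
  }
  res <- permutation_pvalue(anova_f, labels, n_perm, seed, enumeration_cap)
  res$centroid_distances <- dist_to_centroid
  structure(c(list(statistic = "PERMDISP F"), res),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(x$statistic, "=", format(x$observed, digits = 4),
      if (x$exact) sprintf("(exact p = %.5g over %d arrangements)",
                           x$p, x$n_perm)
      else sprintf("(p = %.5g, %d permutations)", x$p, x$n_perm), "\n")
  invisible(x)
}

## NMDS -----------------------------------------------------------------------

#' Non-metric multidimensional scaling
#'
#' Kruskal's stress-1 minimization by iterative majorization (Guttman
#' transform) with monotone regression by pool-adjacent-violators. The best
#' of `restarts` starts is returned: the first start is the
#' principal-coordinate configuration, the rest are random. Coordinates are
#' centered; orientation is arbitrary (solutions are unique up to rotation
#' and reflection).
#'
#' @param d dissimilarity matrix.
#' @param k embedding dimension.
#' @param restarts number of starts.
#' @param seed RNG seed.
#' @param maxit,tol iteration control per start.
#' @return `list(points, stress, converged, restarts)`.
#' @export
nmds <- function(d, k = 2, restarts = 50, seed = NULL, maxit = 500,
                 tol = 1e-7) {
  d <- as_dissimilarity_matrix(d)
  n <- nrow(d)
  if (n < k + 2) stop("need at least k + 2 samples")
  if (!is.null(seed)) set.seed(seed)
  lower <- lower.tri(d)
  dv <- d[lower]
  ord <- order(dv)
  best <- NULL
  for (r in seq_len(restarts)) {
    x <- if (r == 1L) {
      x0 <- pcoa_embed(d)
      if (ncol(x0) < k) {
        cbind(x0, matrix(stats::rnorm(n * (k - ncol(x0)), sd = 1e-3), n))
      } else x0[, seq_len(k), drop = FALSE]
    } else {
      matrix(stats::rnorm(n * k), n, k)
    }
    res <- nmds_one_start(x, dv, ord, lower, n, k, maxit, tol)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  if (is.null(best)) stop("no NMDS start converged")
  pts <- scale(best$points, scale = FALSE)
  rownames(pts) <- rownames(d)
  list(points = pts, stress = best$stress, converged = best$converged,
       restarts = restarts)
}

nmds_one_start <- function(x, dv, ord, lower, n, k, maxit, tol) {
  stress_prev <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    cd <- as.matrix(stats::dist(x))
    cdv <- cd[lower]
    dhat <- numeric(length(cdv))
    dhat[ord] <- isotonize(cdv[ord])
    # normalize disparities to the configuration scale; stress-1 is scale
    # free and this keeps the majorization step from contracting to a point
    if (sum(dhat^2) > 0) dhat <- dhat * sqrt(sum(cdv^2) / sum(dhat^2))
    ss <- sum((cdv - dhat)^2)
    stress <- sqrt(ss / sum(cdv^2))
    if (!is.finite(stress)) {
      stress <- Inf
      break
    }
    if (is.finite(stress_prev) && abs(stress_prev - stress) < tol) {
      converged <- TRUE
      break
    }
    stress_prev <- stress
    # Guttman transform with target distances dhat
    dh <- matrix(0, n, n)
    dh[lower] <- dhat
    dh <- dh + t(dh)
    ratio <- ifelse(cd > 1e-12, dh / cd, 0)
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x <- (b %*% x) / n
  }
  list(points = x, stress = stress, converged = converged)
}

#' Between-species Morisita-Horn similarity
#'
#' Either the average of all cross-species stomach-pair similarities
#' (`"mean-pairwise"`, default) or the similarity between pooled
#' species-level mean profiles (`"pooled"`). Reported x100.
#'
#' @param profiles per-stomach profile matrix.
#' @param labels species per row of `profiles`.
#' @param mode `"mean-pairwise"` or `"pooled"`.
#' @return Symmetric matrix of between-species similarities (x100),
#'   diagonal 100.
#' @export
between_group_similarity <- function(profiles, labels,
                                     mode = c("mean-pairwise", "pooled")) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  species <- sort(unique(labels))
  out <- matrix(100, length(species), length(species),
                dimnames = list(species, species))
  if (mode == "pooled") {
    means <- do.call(rbind, lapply(species, function(s) {
      colMeans(profiles[labels == s, , drop = FALSE])
    }))
    s <- similarity_matrix(means)
    out[, ] <- 100 * s
    diag(out) <- 100
    return(out)
  }
  s <- similarity_matrix(profiles)
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (i >= j) next
      sub <- s[labels == species[i], labels == species[j], drop = FALSE]
      out[i, j] <- out[j, i] <- 100 * mean(sub)
    }
  }
  out
}
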