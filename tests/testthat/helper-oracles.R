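# Independent brute-force oracles for the permutation statistics. These are
# deliberately written from the definitions, not via the package internals.

all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

brute_anosim_r <- function(d, labels) {
  lw <- lower.tri(d)
  rk <- matrix(0, nrow(d), ncol(d))
  rk[lw] <- rank(d[lw])
  rk <- rk + t(rk)
  within <- outer(labels, labels, `==`)
  m <- sum(lw)
  (mean(rk[lw & !within]) - mean(rk[lw & within])) / (m / 2)
}

brute_pseudo_f <- function(d, labels) {
  n <- nrow(d)
  d2 <- d^2
  sst <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    ssw <- ssw + sum(d2[i, i][lower.tri(d2[i, i])]) / length(i)
  }
  k <- length(unique(labels))
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}
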