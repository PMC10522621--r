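## Coverage-based diversity over prey families, incidence framing: each
## stomach is a sampling unit, each prey family an incidence category.

#' Build incidence frequencies from a prey table
#'
#' @param prey a family-level `prey_table`.
#' @param exclude categories never counted (unidentified material).
#' @return `list(n = number of sampling units (prey-containing stomachs),
#'   Y = named vector of incidence frequencies)`, class `incidence_data`.
#' @export
incidence_data <- function(prey, exclude = "unassigned") {
  sub <- prey[!prey$taxon %in% exclude, , drop = FALSE]
  n <- length(unique(sub$specimen_id))
  inc <- table(unique(sub[, c("specimen_id", "taxon")])$taxon)
  y <- as.numeric(inc)
  names(y) <- names(inc)
  structure(list(n = n, Y = y), class = "incidence_data")
}

as_incidence <- function(data) {
  if (inherits(data, "incidence_data")) return(data)
  stopifnot(is.list(data), !is.null(data$n), !is.null(data$Y))
  structure(list(n = data$n, Y = as.numeric(data$Y)), class = "incidence_data")
}

#' Observed Hill-Shannon diversity of order 1
#'
#' The exponential of the Shannon entropy of relative incidence
#' frequencies: the effective number of equally common categories. Bounded
#' between 1 and the number of observed categories.
#'
#' @param data an `incidence_data` (or list with `n`, `Y`).
#' @return Observed diversity (>= 1).
#' @export
hill_shannon <- function(data) {
  data <- as_incidence(data)
  y <- data$Y[data$Y > 0]
  p <- y / sum(y)
  exp(-sum(p * log(p)))
}

#' Incidence-based sample coverage
#'
#' Estimated fraction of the community's total incidence probability
#' represented by the reference sample, from the numbers of unique (`Q1`)
#' and duplicate (`Q2`) categories:
#' `C = 1 - (Q1/U) * ((n-1) Q1 / ((n-1) Q1 + 2 Q2))`, with `U` the total
#' number of incidences and `n` the number of sampling units. Equals 1 when
#' no category is unique to a single unit.
#'
#' @param data an `incidence_data`.
#' @return Coverage in \[0, 1\].
#' @export
sample_coverage <- function(data) {
  data <- as_incidence(data)
  y <- data$Y[data$Y > 0]
  n <- data$n
  u <- sum(y)
  q1 <- sum(y == 1)
  q2 <- sum(y == 2)
  if (q1 == 0) return(1)
  1 - (q1 / u) * (1 - chao_a(q1, q2, n))
}

# shared tail coefficient; the Q2 = 0 case follows the usual bias-corrected
# convention so the estimators stay finite
chao_a <- function(q1, q2, n) {
  if (q2 > 0) {
    2 * q2 / ((n - 1) * q1 + 2 * q2)
  } else if (q1 > 1) {
    2 / ((n - 1) * (q1 - 1) + 2)
  } else {
    1
  }
}

#' Asymptotic (bias-corrected) Hill-Shannon diversity
#'
#' Incidence-based asymptotic Shannon diversity: entropy is estimated with
#' the Chao-Jost bias correction (digamma series plus a tail term driven by
#' unique and duplicate categories), exponentiated. The standard error is a
#' bootstrap over sampling units resampled with replacement.
#'
#' @param data an `incidence_data`.
#' @param bootstrap_reps bootstrap replicates for the standard error; 0
#'   skips the bootstrap.
#' @param seed RNG seed for the bootstrap.
#' @param units optional n x categories incidence (0/1) matrix; required for
#'   the bootstrap when only frequencies were supplied.
#' @return `list(observed, asymptotic, se, coverage, n, bootstrap_reps,
#'   seed)`, class `diversity_estimate`.
#' @export
asymptotic_shannon <- function(data, bootstrap_reps = 200, seed = NULL,
                               units = NULL) {
  data <- as_incidence(data)
  est <- chao_shannon_incidence(data$Y, data$n)
  se <- NA_real_
  if (bootstrap_reps > 0) {
    if (is.null(units)) units <- incidence_units(data, seed = seed)
    if (!is.null(seed)) set.seed(seed + 1L)
    boot <- replicate(bootstrap_reps, {
      idx <- sample(nrow(units), replace = TRUE)
      yb <- colSums(units[idx, , drop = FALSE] > 0)
      chao_shannon_incidence(yb[yb > 0], nrow(units))
    })
    se <- stats::sd(boot)
  }
  structure(
    list(observed = hill_shannon(data), asymptotic = est, se = se,
         coverage = sample_coverage(data), n = data$n,
         bootstrap_reps = bootstrap_reps, seed = seed),
    class = "diversity_estimate"
  )
}

# Chao-Jost entropy estimator for incidence frequencies, exponentiated
chao_shannon_incidence <- function(y, n) {
  y <- y[y > 0]
  u <- sum(y)
  q1 <- sum(y == 1)
  q2 <- sum(y == 2)
  sub <- y[y <= n - 1]
  h_major <- if (length(sub)) {
    sum(sub / n * (digamma(n) - digamma(sub)))
  } else 0
  h_tail <- 0
  if (q1 > 0) {
    a <- chao_a(q1, q2, n)
    if (a < 1) {
      r <- seq_len(n - 1)
      h_tail <- (q1 / n) * (1 - a)^(1 - n) *
        (-log(a) - sum((1 - a)^r / r))
    }
  }
  h <- (n / u) * (h_major + h_tail) + log(u / n)
  exp(h)
}

# reconstruct a plausible unit-by-category incidence matrix from
# frequencies (used only to bootstrap when raw units are unavailable)
incidence_units <- function(data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- data$n
  units <- sapply(data$Y, function(yi) {
    v <- numeric(n)
    v[sample(n, yi)] <- 1
    v
  })
  matrix(units, nrow = n)
}

#' Coverage as a function of sampling effort
#'
#' Interpolated (t < n), reference (t = n) and extrapolated (t > n)
#' incidence coverage along the effort axis.
#'
#' @param data an `incidence_data`.
#' @param t integer efforts (numbers of sampling units).
#' @return Coverage estimates, same length as `t`.
#' @export
coverage_at_effort <- function(data, t) {
  data <- as_incidence(data)
  y <- data$Y[data$Y > 0]
  n <- data$n
  u <- sum(y)
  q1 <- sum(y == 1)
  q2 <- sum(y == 2)
  vapply(t, function(tt) {
    if (tt >= n) {
      if (q1 == 0) return(1)
      a <- 1 - chao_a(q1, q2, n)
      return(1 - (q1 / u) * a^(tt - n + 1))
    }
    # interpolation: expected uncovered incidence probability after tt units
    keep <- (n - y) >= tt
    miss <- if (any(keep)) {
      sum(y[keep] / u *
            exp(lchoose(n - y[keep], tt) - lchoose(n - 1, tt)))
    } else 0
    1 - miss
  }, 0)
}

#' Sampling units needed to reach a coverage target
#'
#' Smallest integer effort whose estimated coverage meets `target`,
#' searched along the interpolated/extrapolated coverage curve up to
#' `cap_multiplier` times the reference effort.
#'
#' @param data an `incidence_data`.
#' @param target coverage target in (0, 1).
#' @param cap_multiplier search cap as a multiple of the reference effort.
#' @return Integer effort, or `NA` (with attribute `beyond_cap = TRUE`) if
#'   the target is not reached within the cap.
#' @export
units_to_coverage <- function(data, target = 0.95, cap_multiplier = 4) {
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  data <- as_incidence(data)
  cap <- ceiling(cap_multiplier * data$n)
  tt <- seq_len(cap)
  cov <- coverage_at_effort(data, tt)
  hit <- which(cov >= target)
  if (!length(hit)) {
    return(structure(NA_integer_, beyond_cap = TRUE))
  }
  tt[hit[1]]
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf(
    "Hill-Shannon diversity: observed %.2f, asymptotic %.2f +/- %.2f (coverage %.3f, n = %d)\n",
    x$observed, x$asymptotic, x$se, x$coverage, x$n))
  invisible(x)
}
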