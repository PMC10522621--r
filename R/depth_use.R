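## Foraging-depth estimation: resolve prey median depths of occurrence,
## recompute adjusted proportional masses, and take the mass-weighted mean.

#' Resolve the median depth of occurrence for a prey taxon
#'
#' Resolution order: a direct reference entry for the taxon (migratory taxa
#' resolve to the mean of day and night median depths; taxa with
#' length-specific rules resolve through the matching size class when a
#' length is supplied, falling back to day/night depths when it is not;
#' `fixed_depth` entries ignore size rules); otherwise, for genus- or
#' family-level queries, the arithmetic mean over the reference entries of
#' member species found through the taxonomy. Unresolvable taxa return an
#' `"unavailable"` path rather than an error.
#'
#' @param taxon taxon name.
#' @param reference a `depth_reference` table.
#' @param taxonomy taxonomy edge list (used for genus/family averaging).
#' @param length_mm optional individual length for size-specific rules.
#' @return `list(taxon, depth_m, path, members)` where `path` is one of
#'   `species-direct`, `dvm-averaged`, `size-rule`, `genus-mean`,
#'   `family-mean`, `unavailable`; `members` lists the reference entries
#'   averaged for rank-level queries.
#' @export
resolve_depth <- function(taxon, reference, taxonomy = NULL,
                          length_mm = NULL) {
  idx <- match(taxon, reference$taxon)
  if (!is.na(idx)) {
    return(resolve_direct(reference, idx, length_mm))
  }
  if (!is.null(taxonomy)) {
    members <- descendant_entries(taxon, reference, taxonomy)
    if (length(members)) {
      depths <- vapply(members, function(tx) {
        resolve_direct(reference, match(tx, reference$taxon), NULL)$depth_m
      }, 0)
      rk <- taxonomy$rank[match(taxon, taxonomy$name)]
      path <- if (identical(rk, "genus")) "genus-mean" else "family-mean"
      return(list(taxon = taxon, depth_m = mean(depths), path = path,
                  members = members))
    }
  }
  list(taxon = taxon, depth_m = NA_real_, path = "unavailable",
       members = character(0))
}

resolve_direct <- function(reference, idx, length_mm) {
  rules <- reference$size_rules[[idx]]
  if (!reference$fixed_depth[idx] && nrow(rules) && !is.null(length_mm) &&
      !is.na(length_mm)) {
    hit <- which(length_mm >= rules$length_min_mm &
                   length_mm < rules$length_max_mm)
    if (length(hit)) {
      return(list(taxon = reference$taxon[idx],
                  depth_m = rules$depth_m[hit[1]], path = "size-rule",
                  members = character(0)))
    }
  }
  day <- reference$day_median_m[idx]
  night <- reference$night_median_m[idx]
  if (reference$migratory[idx] && !is.na(day) && !is.na(night)) {
    return(list(taxon = reference$taxon[idx], depth_m = mean(c(day, night)),
                path = "dvm-averaged", members = character(0)))
  }
  depth <- if (!is.na(day) && !is.na(night)) mean(c(day, night)) else
    if (!is.na(day)) day else night
  if (is.na(depth) && nrow(rules)) {
    # only size rules available but no length: average the rule depths
    depth <- mean(rules$depth_m)
    return(list(taxon = reference$taxon[idx], depth_m = depth,
                path = "size-rule", members = character(0)))
  }
  list(taxon = reference$taxon[idx], depth_m = depth,
       path = "species-direct", members = character(0))
}

descendant_entries <- function(taxon, reference, taxonomy) {
  hits <- character(0)
  for (tx in reference$taxon) {
    cur <- tx
    for (step in seq_len(nrow(taxonomy) + 1L)) {
      if (identical(cur, taxon)) {
        hits <- c(hits, tx)
        break
      }
      idx <- match(cur, taxonomy$name)
      if (is.na(idx)) break
      cur <- taxonomy$parent_name[idx]
      if (is.na(cur) || !nzchar(cur)) break
    }
  }
  unique(hits)
}

#' Mass-weighted foraging depth from resolved prey depths
#'
#' The foraging-depth estimator: `Zf = sum(z_i * w_i)` where `z_i` is the
#' median depth of occurrence of prey taxon `i` and `w_i` its adjusted
#' proportional mass in the stomach (proportions over the depth-resolvable
#' prey mass, summing to 1). Although described as a weighted median depth
#' of occurrence, the estimator is the mass-weighted arithmetic mean of the
#' taxon median depths, so `Zf` always lies within the range of the prey
#' depths used, and is invariant to rescaling all prey masses by a
#' constant.
#'
#' @param depths_m resolved prey depths `z_i`.
#' @param weights adjusted proportional masses (renormalized internally if
#'   they do not sum to 1).
#' @return `Zf` in m.
#' @export
foraging_depth <- function(depths_m, weights) {
  stopifnot(length(depths_m) == length(weights))
  if (!length(depths_m)) stop("no prey depths supplied")
  stopifnot(all(is.finite(depths_m)), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  sum(depths_m * weights)
}

#' Adjusted proportional masses over depth-resolvable prey
#'
#' Renormalizes one stomach's prey masses over the prey for which a depth
#' could be resolved, reporting the fraction of the stomach's total prey
#' mass retained (`mass_coverage`).
#'
#' @param masses_g prey-group masses for one stomach.
#' @param depths_m resolved depths, `NA` where unresolved.
#' @return `list(weights (summing to 1 over resolvable prey), depths_m,
#'   mass_coverage)`; error if nothing is resolvable.
#' @export
adjusted_proportions <- function(masses_g, depths_m) {
  stopifnot(length(masses_g) == length(depths_m), all(masses_g > 0))
  ok <- is.finite(depths_m)
  if (!any(ok)) stop("no depth-resolvable prey in stomach")
  list(weights = masses_g[ok] / sum(masses_g[ok]),
       depths_m = depths_m[ok],
       mass_coverage = sum(masses_g[ok]) / sum(masses_g))
}

#' Per-stomach foraging-depth estimates for a dataset
#'
#' For every prey-containing stomach: restrict to prey whose family-level
#' unit contributes at least `min_pct_M` percent mean proportional mass for
#' some predator species (computed on the full dataset: no predator-size
#' window applies to analyses that account for predator mass explicitly),
#' resolve each remaining taxon's median depth of occurrence (using the
#' median measured/estimated length of the group's individuals for
#' size-specific rules), renormalize proportional masses over the
#' depth-resolvable prey (adjusted proportional mass), and compute the
#' mass-weighted foraging depth. Stomachs with no resolvable prey are
#' excluded and reported.
#'
#' @param stomachs a `stomach_table`.
#' @param prey a `prey_table` at the original identification level.
#' @param reference a `depth_reference` table.
#' @param taxonomy taxonomy edge list.
#' @param min_pct_M family-importance threshold (percent).
#' @return A data frame with one row per estimable stomach: `specimen_id`,
#'   `predator_species`, `predator_mass_g`, `Zf_m`, `mass_coverage`
#'   (fraction of stomach prey mass with depth data), `n_taxa`. Attribute
#'   `excluded` lists stomachs dropped and why.
#' @export
foraging_depths <- function(stomachs, prey, reference, taxonomy,
                            min_pct_M = 1) {
  fam_prey <- family_rollup(prey, taxonomy)
  comp <- composition(stomachs, fam_prey)
  keep_fams <- unique(comp$category[
    stats::ave(comp$pct_M, comp$category, FUN = max) >= min_pct_M
  ])
  keep_fams <- setdiff(keep_fams, "unassigned")
  fam_by_row <- fam_prey$taxon
  rows <- list()
  excluded <- list()
  for (id in unique(prey$specimen_id)) {
    in_stomach <- prey$specimen_id == id
    total_mass <- sum(prey$total_mass_g[in_stomach])
    sel <- in_stomach & fam_by_row %in% keep_fams
    if (!any(sel)) {
      excluded[[id]] <- "no prey in retained families"
      next
    }
    sub <- prey[sel, , drop = FALSE]
    depths <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      med_len <- group_median_length(sub[i, , drop = FALSE])
      res <- resolve_depth(sub$taxon[i], reference, taxonomy,
                           length_mm = med_len)
      depths[i] <- res$depth_m
    }
    ok <- is.finite(depths)
    if (!any(ok)) {
      excluded[[id]] <- "no depth-resolvable prey"
      next
    }
    mass_ok <- sub$total_mass_g[ok]
    zf <- foraging_depth(depths[ok], mass_ok)
    rows[[id]] <- data.frame(
      specimen_id = id,
      predator_species = stomachs$predator_species[
        match(id, stomachs$specimen_id)],
      predator_mass_g = stomachs$predator_mass_g[
        match(id, stomachs$specimen_id)],
      Zf_m = zf,
      mass_coverage = sum(mass_ok) / total_mass,
      n_taxa = length(unique(sub$taxon[ok])),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    stop("foraging-depth stage failed: no stomach had depth-resolvable ",
         "prey (check the depth reference covers the prey taxa)")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

group_median_length <- function(group) {
  m <- group$measurements[[1]]
  if (nrow(m) && any(!is.na(m$length_mm))) {
    return(stats::median(m$length_mm, na.rm = TRUE))
  }
  NULL
}

#' Smooth trend of foraging depth over predator mass
#'
#' Penalized-spline mean-depth curves per species over log10 predator mass,
#' with species-level parametric contrasts:
#' `Zf ~ species + s(log10(mass), by = species)`, gaussian errors. With
#' fewer than `min_per_species` estimates for any species the smooth is
#' dropped and species means are reported instead.
#'
#' @param estimates output of [foraging_depths()].
#' @param min_per_species minimum estimates per species for smoothing.
#' @return `list(model, species_means (mean, se per species), smooth_terms
#'   (per-species approximate significance), fallback)` of class
#'   `depth_trend`.
#' @export
depth_trend <- function(estimates, min_per_species = 10) {
  est <- estimates[is.finite(estimates$predator_mass_g) &
                     estimates$predator_mass_g > 0, , drop = FALSE]
  est$log_mass <- log10(est$predator_mass_g)
  est$species <- factor(est$predator_species)
  counts <- table(est$species)
  fallback <- any(counts < min_per_species)
  if (fallback) {
    mm <- stats::aggregate(Zf_m ~ species, est, mean)
    sds <- stats::aggregate(Zf_m ~ species, est, stats::sd)
    out <- data.frame(species = mm$species, mean_Zf_m = mm$Zf_m,
                      se = sds$Zf_m / sqrt(as.numeric(counts[mm$species])))
    return(structure(list(model = NULL, species_means = out,
                          smooth_terms = NULL, fallback = TRUE),
                     class = "depth_trend"))
  }
  fit <- mgcv::gam(Zf_m ~ species + s(log_mass, by = species),
                   data = est, method = "GCV.Cp")
  sm <- summary(fit)
  # species means at the species-specific mean log mass, with se
  newd <- do.call(rbind, lapply(levels(est$species), function(s) {
    data.frame(species = s, log_mass = mean(est$log_mass[est$species == s]))
  }))
  pr <- mgcv::predict.gam(fit, newdata = newd, se.fit = TRUE)
  means <- data.frame(species = newd$species, mean_Zf_m = as.numeric(pr$fit),
                      se = as.numeric(pr$se.fit))
  structure(
    list(model = fit, species_means = means,
         smooth_terms = data.frame(term = rownames(sm$s.table),
                                   edf = sm$s.table[, "edf"],
                                   F = sm$s.table[, "F"],
                                   p = sm$s.table[, "p-value"]),
         contrasts = data.frame(term = rownames(sm$p.table),
                                estimate = sm$p.table[, 1],
                                se = sm$p.table[, 2],
                                p = sm$p.table[, 4]),
         fallback = FALSE),
    class = "depth_trend"
  )
}

#' Logistic trend of prey occurrence over predator mass
#'
#' Maximum-likelihood logistic regression of a per-stomach presence
#' indicator on log10 predator mass, with a ridge-penalized fallback under
#' complete separation.
#'
#' @param presence logical/0-1 vector per stomach.
#' @param predator_mass_g predator masses.
#' @param ridge penalty used only by the separation fallback.
#' @return `list(coefficients, se, fitted_curve (function of mass returning
#'   percent frequency of occurrence), separation, degenerate)`.
#' @export
occurrence_trend <- function(presence, predator_mass_g, ridge = 1e-3) {
  ok <- is.finite(predator_mass_g) & predator_mass_g > 0 & !is.na(presence)
  y <- as.numeric(presence[ok])
  x <- log10(predator_mass_g[ok])
  if (length(y) < 20) stop("need at least 20 stomachs")
  if (all(y == 0) || all(y == 1)) {
    return(list(coefficients = c(intercept = NA_real_, slope = NA_real_),
                se = c(NA_real_, NA_real_), fitted_curve = NULL,
                separation = FALSE, degenerate = TRUE))
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8) ||
    max(abs(stats::coef(fit))) > 25
  if (sep) {
    warning("complete or quasi-complete separation; ridge-penalized fit used")
    co <- ridge_logistic(cbind(1, x), y, lambda = ridge)
    beta <- co$beta
    se <- co$se
  } else {
    beta <- stats::coef(fit)
    se <- summary(fit)$coefficients[, 2]
  }
  names(beta) <- names(se) <- c("intercept", "slope")
  curve_fun <- function(mass_g) {
    eta <- unname(beta[1] + beta[2] * log10(mass_g))
    100 * stats::plogis(eta)
  }
  list(coefficients = beta, se = se, fitted_curve = curve_fun,
       separation = sep, degenerate = FALSE)
}

ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(H)))
  list(beta = beta, se = se)
}
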