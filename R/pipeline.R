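## End-to-end orchestration: sizing -> composition -> similarity filter ->
## overlap statistics -> diversity -> foraging depth -> allometry.

#' Run the full stomach-content analysis pipeline
#'
#' Executes every stage on an in-memory dataset and (optionally) writes the
#' result tables plus a provenance manifest to an output directory. All
#' stochastic stages (permutation tests, NMDS restarts, diversity
#' bootstrap) derive their RNG streams from `seed`, so a rerun with the
#' same inputs and seed reproduces every number.
#'
#' @param stomachs,prey,taxonomy,reference the dataset (see
#'   [read_stomach_table()], [read_taxonomy()], [read_depth_reference()]).
#' @param seed integer seed for all stochastic stages (required).
#' @param outdir output directory, or `NULL` to skip writing.
#' @param mass_window,min_pct_M,min_stomachs similarity-filter thresholds.
#' @param n_perm permutations for ANOSIM/PERMANOVA/PERMDISP.
#' @param nmds_restarts random starts for the ordination.
#' @param bootstrap_reps diversity bootstrap replicates.
#' @param fo_denominator see [composition()].
#' @return A list bundle with elements `cohort`, `composition_family`,
#'   `similarity` (filter result), `cmh` (similarity matrix),
#'   `between_species`, `anosim`, `permanova`, `permdisp`, `nmds`,
#'   `diversity` (per species), `foraging` (per-stomach estimates),
#'   `depth_trend`, `scaling` (allometric fits + type-III ANCOVA tables),
#'   `manifest`.
#' @export
run_pipeline <- function(stomachs, prey, taxonomy, reference,
                         seed, outdir = NULL,
                         mass_window = c(1, 100), min_pct_M = 1,
                         min_stomachs = 2, n_perm = 999,
                         nmds_restarts = 20, bootstrap_reps = 100,
                         fo_denominator = "with_prey") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  seed <- as.integer(seed)
  fam_prey <- family_rollup(prey, taxonomy)
  comp_fam <- composition(stomachs, fam_prey,
                          fo_denominator = fo_denominator)
  sim <- similarity_filter(stomachs, fam_prey, mass_window = mass_window,
                           min_pct_M = min_pct_M,
                           min_stomachs = min_stomachs)
  cohort <- cohort_summary(stomachs, prey, sim)
  cmh <- similarity_matrix(sim$profiles)
  d <- similarity_to_dissimilarity(cmh)
  res_anosim <- anosim(d, sim$species, n_perm = n_perm, seed = seed)
  res_permanova <- permanova(d, sim$species, n_perm = n_perm,
                             seed = seed + 1L)
  res_permdisp <- permdisp(d, sim$species, n_perm = n_perm,
                           seed = seed + 2L)
  res_nmds <- nmds(d, k = 2, restarts = nmds_restarts, seed = seed + 3L)
  between <- between_group_similarity(sim$profiles, sim$species)
  diversity <- list()
  for (sp in sort(unique(stomachs$predator_species))) {
    ids <- stomachs$specimen_id[stomachs$predator_species == sp]
    sub <- fam_prey[fam_prey$specimen_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) next
    inc <- incidence_data(sub)
    diversity[[sp]] <- asymptotic_shannon(inc, bootstrap_reps =
                                            bootstrap_reps, seed = seed + 4L)
    diversity[[sp]]$t95 <- units_to_coverage(inc, target = 0.95)
  }
  foraging <- foraging_depths(stomachs, prey, reference, taxonomy,
                              min_pct_M = min_pct_M)
  trend <- depth_trend(foraging)
  ind <- expand_group(prey)
  ind$predator_mass_g <- stomachs$predator_mass_g[
    match(ind$specimen_id, stomachs$specimen_id)]
  ind_meas <- ind[ind$digestion_state <= 3L, , drop = FALSE]
  scaling <- list()
  fitdat <- data.frame(response = ind_meas$mass_g,
                       predator_mass_g = ind_meas$predator_mass_g,
                       species = stomachs$predator_species[
                         match(ind_meas$specimen_id, stomachs$specimen_id)])
  scaling$individual_mass <- fit_prey_scaling(fitdat, "individual_mass")
  per_stomach <- stats::aggregate(
    cbind(total_mass = prey$total_mass_g, count = prey$count),
    by = list(specimen_id = prey$specimen_id), FUN = sum)
  per_stomach$predator_mass_g <- stomachs$predator_mass_g[
    match(per_stomach$specimen_id, stomachs$specimen_id)]
  per_stomach$species <- stomachs$predator_species[
    match(per_stomach$specimen_id, stomachs$specimen_id)]
  scaling$total_mass <- fit_prey_scaling(
    data.frame(response = per_stomach$total_mass,
               predator_mass_g = per_stomach$predator_mass_g,
               species = per_stomach$species), "total_mass")
  scaling$prey_count <- fit_prey_scaling(
    data.frame(response = per_stomach$count,
               predator_mass_g = per_stomach$predator_mass_g,
               species = per_stomach$species), "prey_count")
  scaling$ancova <- lapply(scaling[c("individual_mass", "total_mass",
                                     "prey_count")], type3_ancova)
  manifest <- list(
    seed = seed, n_perm = n_perm, mass_window = mass_window,
    min_pct_M = min_pct_M, min_stomachs = min_stomachs,
    nmds_restarts = nmds_restarts, bootstrap_reps = bootstrap_reps,
    n_stomachs = nrow(stomachs), n_prey_groups = nrow(prey),
    r_version = as.character(getRversion())
  )
  bundle <- list(
    cohort = cohort, composition_family = comp_fam, similarity = sim,
    cmh = cmh, between_species = between, anosim = res_anosim,
    permanova = res_permanova, permdisp = res_permdisp, nmds = res_nmds,
    diversity = diversity, foraging = foraging, depth_trend = trend,
    scaling = scaling, manifest = manifest
  )
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$cohort, file.path(outdir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$composition_family,
                   file.path(outdir, "composition_family.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$cmh),
                   file.path(outdir, "similarity_matrix.csv"))
  utils::write.csv(bundle$foraging, file.path(outdir, "foraging_depths.csv"),
                   row.names = FALSE)
  tests <- data.frame(
    test = c("ANOSIM", "PERMANOVA", "PERMDISP"),
    statistic = c(bundle$anosim$observed, bundle$permanova$observed,
                  bundle$permdisp$observed),
    p = c(bundle$anosim$p, bundle$permanova$p, bundle$permdisp$p),
    exact = c(bundle$anosim$exact, bundle$permanova$exact,
              bundle$permdisp$exact)
  )
  utils::write.csv(tests, file.path(outdir, "overlap_tests.csv"),
                   row.names = FALSE)
  div <- do.call(rbind, lapply(names(bundle$diversity), function(sp) {
    d <- bundle$diversity[[sp]]
    data.frame(species = sp, observed = d$observed,
               asymptotic = d$asymptotic, se = d$se, coverage = d$coverage,
               t95 = as.integer(d$t95), n = d$n)
  }))
  utils::write.csv(div, file.path(outdir, "diversity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Human-readable pipeline report
#'
#' @param bundle output of [run_pipeline()].
#' @return A character vector of markdown lines (also printed invisibly).
#' @export
pipeline_report <- function(bundle) {
  lines <- c("# Stomach-content analysis report", "")
  lines <- c(lines, "## Cohort", "")
  co <- bundle$cohort
  lines <- c(lines, utils::capture.output(print(co, row.names = FALSE)), "")
  lines <- c(lines, "## Most important prey (top IRI per species)", "")
  comp <- bundle$composition_family
  for (sp in unique(comp$predator_species)) {
    top <- utils::head(comp[comp$predator_species == sp, ], 4)
    strategy <- feeding_strategy(top$pct_Mps, top$pct_FO)
    lines <- c(lines, sprintf("* %s:", sp))
    lines <- c(lines, sprintf(
      "    - %s: IRI %.0f, %%M %.1f, %%Mps %.1f, %%FO %.1f (%s)",
      top$category, top$iri, top$pct_M, top$pct_Mps, top$pct_FO, strategy))
  }
  lines <- c(lines, "", "## Diet overlap", "")
  lines <- c(lines, sprintf("* ANOSIM R = %.3f, p = %.4g",
                            bundle$anosim$observed, bundle$anosim$p))
  lines <- c(lines, sprintf("* PERMANOVA pseudo-F = %.2f, p = %.4g",
                            bundle$permanova$observed, bundle$permanova$p))
  lines <- c(lines, sprintf("* PERMDISP F = %.2f, p = %.4g",
                            bundle$permdisp$observed, bundle$permdisp$p))
  lines <- c(lines, sprintf("* NMDS stress = %.3f", bundle$nmds$stress))
  lines <- c(lines, "", "## Diversity", "")
  for (sp in names(bundle$diversity)) {
    d <- bundle$diversity[[sp]]
    lines <- c(lines, sprintf(
      "* %s: observed %.2f, asymptotic %.2f +/- %.2f, coverage %.3f, t95 = %s",
      sp, d$observed, d$asymptotic, d$se, d$coverage,
      ifelse(is.na(d$t95), "beyond cap", as.character(d$t95))))
  }
  lines <- c(lines, "", "## Foraging depth", "")
  fd <- bundle$foraging
  for (sp in unique(fd$predator_species)) {
    z <- fd$Zf_m[fd$predator_species == sp]
    cov <- fd$mass_coverage[fd$predator_species == sp]
    lines <- c(lines, sprintf(
      "* %s: mean Zf %.0f m (n = %d, mean mass coverage %.2f)",
      sp, mean(z), length(z), mean(cov)))
  }
  invisible(lines)
}
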