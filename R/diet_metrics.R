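## Diet composition indices, family rollups, analysis filters, feeding
## strategy classification.

#' Roll prey identifications up to mutually exclusive family-level units
#'
#' Species- and genus-level identifications are mapped to their family via
#' the taxonomy. Two hyperiid amphipod families (Brachyscelidae, Lycaeidae)
#' are lumped into the superfamily Platysceloidea; crustacean megalopa, fish
#' leptocephali and ceratioid anglerfishes are kept as their own coarse
#' units. Taxa that reach no family and are not sanctioned coarse groups are
#' labeled `"unassigned"`; they stay in the table (totals and frequency of
#' occurrence still count them) but are excluded from family-level
#' similarity and diversity analyses downstream.
#'
#' Group mass and count are conserved: only the `taxon` labels change.
#'
#' @param prey a `prey_table`.
#' @param taxonomy taxonomy edge list.
#' @return The prey table with `taxon` replaced by the family-level unit,
#'   `rank` set accordingly, and the original taxon kept in `source_taxon`.
#'   Attribute `unassigned` lists the taxa that could not be mapped.
#' @export
family_rollup <- function(prey, taxonomy) {
  fams <- vapply(prey$taxon, family_of, "", taxonomy = taxonomy,
                 USE.NAMES = FALSE)
  out <- prey
  out$source_taxon <- prey$taxon
  out$taxon <- ifelse(is.na(fams), "unassigned", fams)
  out$rank <- ifelse(is.na(fams), "other",
                     ifelse(out$taxon %in% coarse_groups, "other", "family"))
  attr(out, "unassigned") <- sort(unique(prey$taxon[is.na(fams)]))
  out
}

#' Per-stomach diet profiles of proportional mass
#'
#' For each prey-containing stomach, the proportion of stomach content mass
#' in each prey category. Before any exclusion the proportions of a stomach
#' sum to exactly 1.
#'
#' @param prey a `prey_table` (typically after [family_rollup()]).
#' @param value `"mass"` or `"count"`.
#' @return A numeric matrix, one row per prey-containing stomach (rownames =
#'   specimen ids), one column per category; rows sum to 1.
#' @export
diet_profiles <- function(prey, value = c("mass", "count")) {
  value <- match.arg(value)
  v <- if (value == "mass") prey$total_mass_g else as.numeric(prey$count)
  tot <- tapply(v, prey$specimen_id, sum)
  cats <- sort(unique(prey$taxon))
  ids <- sort(unique(prey$specimen_id))
  prof <- matrix(0, nrow = length(ids), ncol = length(cats),
                 dimnames = list(ids, cats))
  agg <- stats::aggregate(v, list(id = prey$specimen_id, cat = prey$taxon),
                          sum)
  prof[cbind(match(agg$id, ids), match(agg$cat, cats))] <- agg$x
  prof / as.numeric(tot[ids])
}

#' Diet composition table per predator species
#'
#' Computes, per (predator species, prey category): total count, total mass,
#' number of stomachs of occurrence, mean proportional abundance
#' (`pct_N`, x100), mean proportional mass (`pct_M`, x100), percent
#' frequency of occurrence (`pct_FO`), prey-specific proportional mass
#' (`pct_Mps`, mean over only the stomachs containing the category, x100)
#' and the index of relative importance `iri = (pct_N + pct_M) * pct_FO`.
#' All proportional metrics are means over prey-containing stomachs of the
#' species; by default the frequency-of-occurrence denominator is the number
#' of prey-containing stomachs.
#'
#' @param stomachs a `stomach_table`.
#' @param prey a `prey_table`, at the taxonomic level wanted (use
#'   [family_rollup()] or [prey_type_rollup()] first for coarser levels).
#' @param fo_denominator `"with_prey"` (default) or `"all"`: whether percent
#'   frequency of occurrence divides by prey-containing stomachs or by all
#'   stomachs examined.
#' @return A data frame, one row per (species, category), sorted by species
#'   then decreasing `iri`. Attribute `n_stomachs` tabulates examined and
#'   prey-containing stomachs per species.
#' @export
composition <- function(stomachs, prey,
                        fo_denominator = c("with_prey", "all")) {
  fo_denominator <- match.arg(fo_denominator)
  species <- sort(unique(stomachs$predator_species))
  rows <- list()
  n_tab <- data.frame(species = species, n_examined = NA_integer_,
                      n_with_prey = NA_integer_)
  for (si in seq_along(species)) {
    sp <- species[si]
    ids <- stomachs$specimen_id[stomachs$predator_species == sp]
    sub <- prey[prey$specimen_id %in% ids, , drop = FALSE]
    wp <- unique(sub$specimen_id)
    n_tab$n_examined[si] <- length(ids)
    n_tab$n_with_prey[si] <- length(wp)
    if (length(wp) == 0L) {
      warning("species '", sp, "' has no prey-containing stomachs; excluded")
      next
    }
    denom <- if (fo_denominator == "with_prey") length(wp) else length(ids)
    pm <- diet_profiles(sub, value = "mass")
    pn <- diet_profiles(sub, value = "count")
    cats <- colnames(pm)
    occ <- colSums(pm > 0)
    rows[[sp]] <- data.frame(
      predator_species = sp,
      category = cats,
      total_count = as.integer(tapply(sub$count, factor(sub$taxon, cats),
                                      sum)),
      total_mass_g = as.numeric(tapply(sub$total_mass_g,
                                       factor(sub$taxon, cats), sum)),
      n_occurrence = as.integer(occ),
      pct_N = 100 * colMeans(pn),
      pct_M = 100 * colMeans(pm),
      pct_FO = 100 * occ / denom,
      pct_Mps = 100 * colSums(pm) / occ,
      stringsAsFactors = FALSE, row.names = NULL
    )
    rows[[sp]]$iri <- (rows[[sp]]$pct_N + rows[[sp]]$pct_M) *
      rows[[sp]]$pct_FO
    rows[[sp]] <- rows[[sp]][order(-rows[[sp]]$iri), ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_stomachs") <- n_tab
  out
}

#' Prey-specific proportional mass for one category
#'
#' Mean proportional mass computed only over the stomachs that contain the
#' category, x100. Values above 50 indicate specialization on the category
#' by the individuals that consume it.
#'
#' @param profiles per-stomach profile matrix from [diet_profiles()].
#' @param category column name.
#' @return Percentage in (0, 100], or `NA` if the category never occurs.
#' @export
prey_specific_mass <- function(profiles, category) {
  if (!category %in% colnames(profiles)) return(NA_real_)
  p <- profiles[, category]
  if (!any(p > 0)) return(NA_real_)
  100 * mean(p[p > 0])
}

#' Index of relative importance
#'
#' `iri = (pct_N + pct_M) * pct_FO`, ranking prey categories by their joint
#' contribution in numbers, mass and frequency. Maximum 20000.
#'
#' @param pct_N,pct_M,pct_FO percentages in \[0, 100\].
#' @return Index values.
#' @export
iri <- function(pct_N, pct_M, pct_FO) {
  stopifnot(all(pct_N >= 0 & pct_N <= 100, na.rm = TRUE),
            all(pct_M >= 0 & pct_M <= 100, na.rm = TRUE),
            all(pct_FO >= 0 & pct_FO <= 100, na.rm = TRUE))
  (pct_N + pct_M) * pct_FO
}

#' Classify a feeding strategy from prey-specific mass and occurrence
#'
#' Prey-specific proportional mass above 50 marks specialist feeding on the
#' category (below 50, generalist); frequency of occurrence above 50 marks a
#' population-level pattern (below 50, individual-level). Ties at exactly 50
#' classify as generalist / individual (strict `> 50`).
#'
#' @param pct_Mps,pct_FO percentages in \[0, 100\] (vectorized).
#' @return Character vector: `"specialist-population"`,
#'   `"specialist-individual"`, `"generalist-population"` or
#'   `"generalist-individual"`.
#' @export
feeding_strategy <- function(pct_Mps, pct_FO) {
  stopifnot(all(pct_Mps >= 0 & pct_Mps <= 100, na.rm = TRUE),
            all(pct_FO >= 0 & pct_FO <= 100, na.rm = TRUE))
  paste0(ifelse(pct_Mps > 50, "specialist", "generalist"), "-",
         ifelse(pct_FO > 50, "population", "individual"))
}

#' Roll prey up to broad prey types
#'
#' Relabels every prey group by its broad prey class (fish, mollusk,
#' crustacean, other), for per-stomach prey-type proportions comparable
#' across studies.
#'
#' @param prey a `prey_table`.
#' @return The prey table with `taxon` replaced by `prey_class`.
#' @export
prey_type_rollup <- function(prey) {
  out <- prey
  out$source_taxon <- prey$taxon
  out$taxon <- prey$prey_class
  out$rank <- "other"
  out
}

#' Filter stomachs and categories for diet-similarity analyses
#'
#' Restricts to predators within a mass window (to reduce the influence of
#' unequal size distributions), drops unassigned/unidentified categories,
#' and keeps only categories that contribute more than `min_pct_M` percent
#' mean proportional mass for at least one predator species and occur in
#' more than `min_stomachs - 1` stomachs overall (rare taxa distort
#' abundance-based distances).
#'
#' @param stomachs a `stomach_table`.
#' @param prey a family-level `prey_table` (after [family_rollup()]).
#' @param mass_window closed predator-mass interval in g, default `c(1, 100)`.
#' @param min_pct_M retention threshold on percent mean proportional mass.
#' @param min_stomachs a category must occur in at least this many stomachs.
#' @param drop_categories categories always excluded (unidentified material).
#' @return `list(profiles = matrix of renormalized proportional masses over
#'   retained categories, retained_categories, n_retained = per-species
#'   retained stomach counts, stomach_ids)`. Errors if nothing survives.
#' @export
similarity_filter <- function(stomachs, prey, mass_window = c(1, 100),
                              min_pct_M = 1, min_stomachs = 2,
                              drop_categories = "unassigned") {
  comp <- composition(stomachs, prey)
  keep_cat <- unique(comp$category[
    stats::ave(comp$pct_M, comp$category, FUN = max) > min_pct_M
  ])
  occ_tot <- tapply(comp$n_occurrence, comp$category, sum)
  keep_cat <- setdiff(
    intersect(keep_cat, names(occ_tot)[occ_tot >= min_stomachs]),
    drop_categories
  )
  in_window <- !is.na(stomachs$predator_mass_g) &
    stomachs$predator_mass_g >= mass_window[1] &
    stomachs$predator_mass_g <= mass_window[2]
  ids_window <- stomachs$specimen_id[in_window]
  sub <- prey[prey$specimen_id %in% ids_window &
                prey$taxon %in% keep_cat, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("similarity filter removed every prey category or stomach")
  }
  profiles <- diet_profiles(sub, value = "mass")
  sp <- stomachs$predator_species[match(rownames(profiles),
                                        stomachs$specimen_id)]
  list(
    profiles = profiles,
    retained_categories = sort(keep_cat),
    n_retained = table(sp),
    stomach_ids = rownames(profiles),
    species = sp
  )
}
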