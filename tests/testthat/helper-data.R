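# Shared fixture builders. Everything is generated in code; no data files.

tiny_dataset <- function() {
  stomachs <- stomach_table(
    specimen_id = c("s1", "s2", "s3"),
    predator_species = c("Alepisaurus ferox", "Anoplogaster cornuta",
                         "Omosudis lowii"),
    standard_length_mm = c(200, 60, 150),
    stomach_content_mass_g = c(3, 1, 0),
    predator_mass_g = c(30, 6, 12)
  )
  prey <- prey_table(
    specimen_id = c("s1", "s1", "s2"),
    taxon = c("Sternoptyx diaphana", "Phrosina semilunata",
              "Phrosina semilunata"),
    rank = "species",
    prey_class = c("fish", "crustacean", "crustacean"),
    digestion_state = c(1L, 2L, 1L),
    count = c(2L, 4L, 5L),
    total_mass_g = c(2, 1, 1)
  )
  catalog <- default_catalog()
  list(stomachs = stomachs, prey = prey,
       taxonomy = catalog_taxonomy(catalog),
       reference = catalog_depth_reference(catalog))
}

# config helpers -------------------------------------------------------------

tweak_config <- function(config, species = NULL, ...) {
  dots <- list(...)
  top <- intersect(names(dots), names(config))
  for (nm in top) config[[nm]] <- dots[[nm]]
  per_species <- setdiff(names(dots), top)
  targets <- if (is.null(species)) names(config$species) else species
  for (sp in targets) {
    for (nm in per_species) config$species[[sp]][[nm]] <- dots[[nm]]
  }
  config
}

# two prey taxa with equal typical mass on a shallow (185.38 m) and a deep
# (675 m) layer; one predator species with mixture weight w on the deep layer
two_layer_config <- function(w_deep, n = 200L, seed = 1L) {
  catalog <- default_catalog()
  catalog <- catalog[catalog$taxon %in%
                       c("Phrosina semilunata", "Sternoptyx diaphana"), ]
  catalog$mass_scale_g <- 0.5
  config <- default_generator_config(seed = seed, catalog = catalog)
  config$species <- config$species["Alepisaurus ferox"]
  config$species[["Alepisaurus ferox"]]$n <- as.integer(n)
  config$species[["Alepisaurus ferox"]]$vacuity <- 0
  config$species[["Alepisaurus ferox"]]$mixture <-
    c("Phrosina semilunata" = 1 - w_deep, "Sternoptyx diaphana" = w_deep)
  config$species[["Alepisaurus ferox"]]$groups_lambda <- 2
  config
}

# iid Dirichlet(1) profiles: exchangeable across groups (null of no diet
# structure)
null_profiles <- function(n_samples, n_cats) {
  g <- matrix(stats::rexp(n_samples * n_cats), n_samples, n_cats)
  g / rowSums(g)
}
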