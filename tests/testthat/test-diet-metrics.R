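one_stomach_each <- function(props_by_stomach, species = "Omosudis lowii") {
  # props_by_stomach: named list stomach -> named numeric of category masses
  ids <- names(props_by_stomach)
  stomachs <- stomach_table(ids, species,
                            stomach_content_mass_g =
                              vapply(props_by_stomach, sum, 0),
                            predator_mass_g = 10)
  rows <- do.call(rbind, lapply(ids, function(id) {
    v <- props_by_stomach[[id]]
    data.frame(specimen_id = id, taxon = names(v), mass = as.numeric(v))
  }))
  prey <- prey_table(rows$specimen_id, rows$taxon, rank = "family",
                     prey_class = "fish", total_mass_g = rows$mass)
  list(stomachs = stomachs, prey = prey)
}

test_that("composition reproduces hand-computed indices", {
  d <- one_stomach_each(list(a = c(X = 2)))
  comp <- composition(d$stomachs, d$prey)
  expect_equal(comp$pct_N, 100)
  expect_equal(comp$pct_M, 100)
  expect_equal(comp$pct_FO, 100)
  d2 <- one_stomach_each(list(a = c(X = 5), b = c(Y = 3)))
  comp2 <- composition(d2$stomachs, d2$prey)
  x <- comp2[comp2$category == "X", ]
  expect_equal(x$pct_M, 50)
  expect_equal(x$pct_FO, 50)
  # three stomachs with hand-set proportions
  d3 <- one_stomach_each(list(a = c(X = 8, Y = 2), b = c(X = 1, Y = 1),
                              c = c(Y = 4)))
  comp3 <- composition(d3$stomachs, d3$prey)
  expect_equal(comp3$pct_M[comp3$category == "X"],
               100 * mean(c(0.8, 0.5, 0)))
  expect_equal(comp3$pct_M[comp3$category == "Y"],
               100 * mean(c(0.2, 0.5, 1)))
})

test_that("percent FO denominator is configurable", {
  stomachs <- stomach_table(c("a", "b"), "Omosudis lowii",
                            stomach_content_mass_g = c(1, 0),
                            predator_mass_g = 10)
  prey <- prey_table("a", "X", rank = "family", total_mass_g = 1)
  expect_equal(composition(stomachs, prey)$pct_FO, 100)
  expect_equal(composition(stomachs, prey, fo_denominator = "all")$pct_FO,
               50)
})

test_that("prey-specific mass uses only containing stomachs", {
  profs <- diet_profiles(one_stomach_each(
    list(a = c(X = 1), b = c(Y = 1), c = c(X = 4, Y = 6))
  )$prey)
  expect_equal(prey_specific_mass(profs, "X"), 100 * mean(c(1, 0.4)))
  # present in one of many stomachs: Mps 100, M = 100/n
  profs2 <- diet_profiles(one_stomach_each(
    c(list(z = c(X = 1)), setNames(lapply(1:9, function(i) c(Y = 1)),
                                   paste0("s", 1:9)))
  )$prey)
  expect_equal(prey_specific_mass(profs2, "X"), 100)
  expect_equal(100 * mean(profs2[, "X"]), 10)
  # two containing stomachs at 0.8 and 0.4
  profs3 <- diet_profiles(one_stomach_each(
    list(a = c(X = 8, Y = 2), b = c(X = 4, Y = 6), c = c(Y = 1))
  )$prey)
  expect_equal(prey_specific_mass(profs3, "X"), 60)
  expect_true(is.na(prey_specific_mass(profs3, "Z")))
})

test_that("composition identity pct_M = pct_Mps * pct_FO / 100 holds", {
  d <- generate_dataset(default_generator_config(seed = 5))
  fam <- family_rollup(d$prey, d$taxonomy)
  comp <- composition(d$stomachs, fam)
  expect_equal(comp$pct_M, comp$pct_Mps * comp$pct_FO / 100,
               tolerance = 1e-12)
  # simplex closure per species
  for (sp in unique(comp$predator_species)) {
    expect_equal(sum(comp$pct_M[comp$predator_species == sp]), 100,
                 tolerance = 1e-9)
    expect_equal(sum(comp$pct_N[comp$predator_species == sp]), 100,
                 tolerance = 1e-9)
  }
})

test_that("family rollup maps species, lumps hyperiids, conserves mass", {
  d <- tiny_dataset()
  prey <- prey_table(
    specimen_id = c("s1", "s1", "s1"),
    taxon = c("Sternoptyx diaphana", "Brachyscelus crusculum",
              "unidentified fish"),
    rank = "species", prey_class = "fish",
    total_mass_g = c(2, 1, 0.5)
  )
  rolled <- family_rollup(prey, d$taxonomy)
  expect_equal(rolled$taxon,
               c("Sternoptychidae", "Platysceloidea", "unassigned"))
  expect_equal(attr(rolled, "unassigned"), "unidentified fish")
  expect_equal(sum(rolled$total_mass_g), sum(prey$total_mass_g))
  expect_equal(tapply(rolled$total_mass_g, rolled$specimen_id, sum),
               tapply(prey$total_mass_g, prey$specimen_id, sum))
})

test_that("iri and feeding strategy follow their definitions", {
  expect_equal(iri(100, 100, 100), 20000)
  expect_equal(iri(0, 0, 77), 0)
  expect_equal(iri(10, 30, 50), 2000)
  expect_error(iri(150, 0, 0))
  expect_equal(feeding_strategy(91, 67), "specialist-population")
  expect_equal(feeding_strategy(65, 86), "specialist-population")
  expect_equal(feeding_strategy(49, 49), "generalist-individual")
  expect_equal(feeding_strategy(50, 50), "generalist-individual")
  expect_equal(feeding_strategy(80, 20), "specialist-individual")
})

test_that("similarity filter applies mass window and retention thresholds", {
  stomachs <- stomach_table(
    c("a", "b", "c", "d"), "Omosudis lowii",
    stomach_content_mass_g = 1,
    predator_mass_g = c(0.9, 10, 50, 100)  # 0.9 g falls outside [1, 100]
  )
  prey <- prey_table(
    specimen_id = c("a", "b", "c", "d", "b"),
    taxon = c("X", "X", "X", "X", "Rare"),
    rank = "family", prey_class = "fish",
    total_mass_g = c(1, 1, 1, 1, 0.004)  # Rare ~ 0.4 %M, one stomach
  )
  sim <- similarity_filter(stomachs, prey)
  expect_false("a" %in% sim$stomach_ids)
  expect_setequal(sim$stomach_ids, c("b", "c", "d"))
  expect_equal(sim$retained_categories, "X")
  expect_error(similarity_filter(stomachs, prey, min_pct_M = 200),
               "removed every")
})

test_that("prey-type rollup yields per-stomach simplex over classes", {
  prey <- prey_table(
    specimen_id = c("s1", "s1"), taxon = c("f", "c"), rank = "species",
    prey_class = c("fish", "crustacean"), total_mass_g = c(3, 1)
  )
  profs <- diet_profiles(prey_type_rollup(prey))
  expect_equal(as.numeric(profs["s1", c("crustacean", "fish")]),
               c(0.25, 0.75))
})

test_that("generator's piscivorous species shows fish >> mollusk proportions", {
  d <- generate_dataset(default_generator_config(seed = 9))
  ids <- d$stomachs$specimen_id[
    d$stomachs$predator_species == "Omosudis lowii"]
  sub <- d$prey[d$prey$specimen_id %in% ids, ]
  profs <- diet_profiles(prey_type_rollup(sub))
  fish <- mean(profs[, "fish"])
  mollusk <- if ("mollusk" %in% colnames(profs)) mean(profs[, "mollusk"]) else 0
  expect_gt(fish, 2 * mollusk)
})
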