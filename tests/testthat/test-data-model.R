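test_that("minimal CSV input yields one stomach record and one prey group", {
  sdir <- withr::local_tempdir()
  sp <- file.path(sdir, "stomachs.csv")
  pp <- file.path(sdir, "prey.csv")
  writeLines(c(
    "specimen_id,predator_species,stomach_content_mass_g,predator_mass_g",
    "s1,Omosudis lowii,1.5,12"
  ), sp)
  writeLines(c(
    "specimen_id,taxon,rank,prey_class,digestion_state,count,total_mass_g",
    "s1,Sternoptyx diaphana,species,fish,1,1,1.5"
  ), pp)
  ds <- read_stomach_table(sp, pp)
  expect_equal(nrow(ds$stomachs), 1L)
  expect_equal(nrow(ds$prey), 1L)
  expect_equal(ds$prey$taxon, "Sternoptyx diaphana")
})

test_that("reader rejects invalid digestion states, orphans, missing columns", {
  sdir <- withr::local_tempdir()
  sp <- file.path(sdir, "stomachs.csv")
  writeLines(c(
    "specimen_id,predator_species,stomach_content_mass_g,predator_mass_g",
    "s1,Omosudis lowii,1.5,12"
  ), sp)
  pp <- file.path(sdir, "prey_bad_state.csv")
  writeLines(c(
    "specimen_id,taxon,rank,prey_class,digestion_state,count,total_mass_g",
    "s1,Sternoptyx diaphana,species,fish,5,1,1.5"
  ), pp)
  expect_error(read_stomach_table(sp, pp), "digestion_state.*rows: 1")
  pp2 <- file.path(sdir, "prey_orphan.csv")
  writeLines(c(
    "specimen_id,taxon,rank,prey_class,digestion_state,count,total_mass_g",
    "ghost,Sternoptyx diaphana,species,fish,1,1,1.5"
  ), pp2)
  expect_error(read_stomach_table(sp, pp2), "unknown specimens.*ghost")
  sp2 <- file.path(sdir, "stomachs_missing.csv")
  writeLines(c("specimen_id,stomach_content_mass_g", "s1,1.5"), sp2)
  expect_error(read_stomach_table(sp2), "predator_species")
})

test_that("schema remapping adapts foreign column names", {
  sdir <- withr::local_tempdir()
  sp <- file.path(sdir, "stomachs.csv")
  writeLines(c("ID,Species,GutMass", "s1,Omosudis lowii,1.5"), sp)
  ds <- read_stomach_table(
    sp, schema = c(specimen_id = "ID", predator_species = "Species",
                   stomach_content_mass_g = "GutMass"))
  expect_equal(ds$stomachs$specimen_id, "s1")
})

test_that("write/read round trip preserves the dataset, empty stomachs included", {
  d <- generate_dataset(tweak_config(default_generator_config(seed = 11),
                                     n = 15L))
  sdir <- withr::local_tempdir()
  sp <- file.path(sdir, "s.csv")
  pp <- file.path(sdir, "p.csv")
  write_stomach_table(d$stomachs, d$prey, sp, pp)
  back <- read_stomach_table(sp, pp)
  expect_equal(nrow(back$stomachs), nrow(d$stomachs))
  expect_equal(back$stomachs$specimen_id, d$stomachs$specimen_id)
  expect_equal(back$stomachs$predator_mass_g, d$stomachs$predator_mass_g,
               tolerance = 1e-12)
  expect_equal(nrow(back$prey), nrow(d$prey))
  expect_equal(back$prey$total_mass_g, d$prey$total_mass_g,
               tolerance = 1e-12)
  expect_equal(back$prey$measurements[[1]]$mass_g,
               d$prey$measurements[[1]]$mass_g, tolerance = 1e-12)
  # empty stomachs survive the round trip
  empties <- setdiff(d$stomachs$specimen_id, d$prey$specimen_id)
  expect_true(length(empties) > 0)
  expect_true(all(empties %in% back$stomachs$specimen_id))
})

test_that("predator mass derivation follows precedence and flags negatives", {
  s <- stomach_table("a", "Omosudis lowii", whole_mass_g = 20,
                     stomach_content_mass_g = 3)
  expect_equal(s$predator_mass_g, 17)
  s2 <- stomach_table("a", "Omosudis lowii", whole_mass_g = 20,
                      stomach_content_mass_g = 3, predator_mass_g = 99)
  expect_equal(s2$predator_mass_g, 99)
  s3 <- stomach_table("a", "Omosudis lowii", whole_mass_g = 2,
                      stomach_content_mass_g = 3)
  expect_true(is.na(s3$predator_mass_g))
  expect_equal(attr(s3, "derived_mass_flagged"), "a")
})

test_that("prey group invariants are enforced", {
  expect_error(prey_table("s1", "x", digestion_state = 0L),
               "digestion_state")
  expect_error(prey_table("s1", "x", count = 0L), "count")
  expect_error(prey_table("s1", "x", total_mass_g = 0), "total_mass_g")
  m <- data.frame(mass_g = c(1, 1), length_mm = NA_real_,
                  length_type = NA_character_)
  expect_error(prey_table("s1", "x", count = 1L, total_mass_g = 2,
                          measurements = list(m)),
               "more measurements")
  expect_error(prey_table("s1", "x", count = 3L, total_mass_g = 1,
                          measurements = list(m)),
               "exceed group total")
})

test_that("depth reference reader resolves depths and merges size classes", {
  sdir <- withr::local_tempdir()
  rp <- file.path(sdir, "ref.csv")
  writeLines(c(
    "taxon,rank,day_median_m,night_median_m,migratory,length_min_mm,length_max_mm,depth_m",
    "Sternoptyx diaphana,species,675,675,FALSE,,,",
    "Sizey fish,species,,,FALSE,0,50,150",
    "Sizey fish,species,,,FALSE,50,200,600"
  ), rp)
  ref <- read_depth_reference(rp)
  expect_equal(nrow(ref), 2L)
  r1 <- resolve_depth("Sternoptyx diaphana", ref)
  expect_equal(r1$depth_m, 675)
  expect_equal(r1$path, "species-direct")
  expect_equal(nrow(ref$size_rules[[match("Sizey fish", ref$taxon)]]), 2L)
  r2 <- resolve_depth("Sizey fish", ref, length_mm = 100)
  expect_equal(r2$depth_m, 600)
  # size-rule taxon without a length falls back to the rule average
  r3 <- resolve_depth("Sizey fish", ref)
  expect_equal(r3$depth_m, 375)
})

test_that("depth reference validation rejects depthless and overlapping entries", {
  expect_error(depth_reference("x"), "neither day/night depths nor size")
  bad_rules <- data.frame(length_min_mm = c(0, 40), length_max_mm = c(50, 90),
                          depth_m = c(100, 200))
  expect_error(depth_reference("x", size_rules = list(bad_rules)),
               "overlapping")
})

test_that("family lookup walks the taxonomy and honors coarse groups", {
  tx <- data.frame(
    name = c("Sternoptyx diaphana", "Sternoptyx", "Sternoptychidae",
             "Brachyscelus crusculum", "Brachyscelidae"),
    rank = c("species", "genus", "family", "species", "family"),
    parent_name = c("Sternoptyx", "Sternoptychidae", NA,
                    "Brachyscelidae", NA)
  )
  expect_equal(family_of("Sternoptyx diaphana", tx), "Sternoptychidae")
  expect_equal(family_of("Brachyscelus crusculum", tx), "Platysceloidea")
  expect_equal(family_of("megalopa", tx), "megalopa")
  expect_true(is.na(family_of("unidentified fish", tx)))
  cyc <- data.frame(name = c("a", "b"), rank = "species",
                    parent_name = c("b", "a"))
  expect_error(validate_taxonomy(cyc), "cycle")
})

test_that("dataset validation reports failures without modifying data", {
  d <- tiny_dataset()
  rep1 <- validate_dataset(d$stomachs, d$prey, d$taxonomy)
  expect_true(all(rep1$n_fail == 0))
  prey2 <- d$prey
  prey2$taxon[1] <- "unidentified fish"
  rep2 <- validate_dataset(d$stomachs, prey2, d$taxonomy)
  fam_check <- rep2[rep2$check == "taxa reach a family-level unit", ]
  expect_equal(fam_check$n_fail, 1L)
})
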