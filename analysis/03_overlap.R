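#!/usr/bin/env Rscript
# Stage 3: diet overlap. Morisita-Horn similarities among stomachs of
# 1-100 g predators over retained families, ANOSIM / PERMANOVA / PERMDISP
# permutation tests, NMDS ordination, and between-species similarity.

suppressPackageStartupMessages(library(deepdiet))

seed <- 20230927L
data_dir <- "results/data"
ds <- read_stomach_table(file.path(data_dir, "stomachs.csv"),
                         file.path(data_dir, "prey_groups.csv"))
taxonomy <- read_taxonomy(file.path(data_dir, "taxonomy.csv"))

fam <- family_rollup(ds$prey, taxonomy)
sim <- similarity_filter(ds$stomachs, fam)
message(sprintf("similarity analyses use %d stomachs over %d families",
                length(sim$stomach_ids), length(sim$retained_categories)))

cmh <- similarity_matrix(sim$profiles)
write.csv(as.data.frame(cmh), "results/similarity_matrix.csv")
d <- similarity_to_dissimilarity(cmh)

res_a <- anosim(d, sim$species, n_perm = 999, seed = seed)
res_p <- permanova(d, sim$species, n_perm = 999, seed = seed + 1L)
res_d <- permdisp(d, sim$species, n_perm = 999, seed = seed + 2L)
ord <- nmds(d, k = 2, restarts = 20, seed = seed + 3L)
message(sprintf("ANOSIM R = %.3f (p = %.4g); PERMANOVA F = %.2f (p = %.4g)",
                res_a$observed, res_a$p, res_p$observed, res_p$p))
message(sprintf("PERMDISP F = %.2f (p = %.4g); NMDS stress = %.3f",
                res_d$observed, res_d$p, ord$stress))

write.csv(data.frame(
  test = c("ANOSIM", "PERMANOVA", "PERMDISP"),
  statistic = c(res_a$observed, res_p$observed, res_d$observed),
  p = c(res_a$p, res_p$p, res_d$p)
), "results/overlap_tests.csv", row.names = FALSE)

bt <- between_group_similarity(sim$profiles, sim$species)
write.csv(as.data.frame(bt), "results/between_species_cmh.csv")
message("between-species Cmh (x100):")
print(round(bt, 2))

coords <- data.frame(specimen_id = rownames(ord$points), ord$points,
                     species = sim$species)
write.csv(coords, "results/nmds_coordinates.csv", row.names = FALSE)
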