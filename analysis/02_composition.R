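#!/usr/bin/env Rscript
# Stage 2: diet composition. Family-level rollup with mutually exclusive
# categories, composition indices (%N, %M, %FO, %Mps, IRI), cohort table,
# and feeding-strategy classification of the four most important prey per
# predator.

suppressPackageStartupMessages(library(deepdiet))

data_dir <- "results/data"
ds <- read_stomach_table(file.path(data_dir, "stomachs.csv"),
                         file.path(data_dir, "prey_groups.csv"))
taxonomy <- read_taxonomy(file.path(data_dir, "taxonomy.csv"))

fam <- family_rollup(ds$prey, taxonomy)
comp <- composition(ds$stomachs, fam)
write.csv(comp, "results/composition_family.csv", row.names = FALSE)

sim <- similarity_filter(ds$stomachs, fam)
cohort <- cohort_summary(ds$stomachs, ds$prey, sim)
write.csv(cohort, "results/cohort.csv", row.names = FALSE)
message("cohort: ", paste(sprintf("%s %d/%d with prey", cohort$species,
                                  cohort$n_with_prey, cohort$n_examined),
                          collapse = "; "))

strategies <- do.call(rbind, lapply(unique(comp$predator_species),
                                    function(sp) {
  top <- head(comp[comp$predator_species == sp, ], 4)
  top$strategy <- feeding_strategy(top$pct_Mps, top$pct_FO)
  top[, c("predator_species", "category", "iri", "pct_Mps", "pct_FO",
          "strategy")]
}))
write.csv(strategies, "results/feeding_strategies.csv", row.names = FALSE)
for (i in seq_len(nrow(strategies))) {
  message(sprintf("  %s / %s: IRI %.0f -> %s",
                  strategies$predator_species[i], strategies$category[i],
                  strategies$iri[i], strategies$strategy[i]))
}
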