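#!/usr/bin/env Rscript
# Aggregate the composition survey across taxonomic levels, quantify how
# much biomass the characterized strains represent, and build the
# abundance-weighted community metabolic profile used by all estimators.

suppressPackageStartupMessages(library(gutharvest))
suppressPackageStartupMessages(library(tidyverse))

fix <- "results/fixtures"
ab <- read_abundance_tsv(file.path(fix, "abundance_genus.tsv"))
profiles <- read_rate_profiles_csv(file.path(fix, "strain_rates.csv"))
represented <- unique(purrr::map_chr(profiles, function(p)
  p$lineage[["genus"]]))

# coverage rises as the level coarsens
cov_tbl <- purrr::map_dfr(c("genus", "family", "phylum"), function(lvl) {
  tab <- aggregate_abundance(ab, lvl)
  reps <- switch(lvl,
    genus = represented,
    family = c("Bacteroidaceae", "Lachnospiraceae", "Ruminococcaceae",
               "Bifidobacteriaceae", "Enterobacteriaceae"),
    phylum = c("Bacteroidota", "Bacillota", "Actinomycetota",
               "Pseudomonadota"))
  cv <- coverage(tab, reps)
  tibble::tibble(level = lvl, mean_coverage = cv$mean,
                 sd_coverage = sd(cv$per_sample))
})
readr::write_csv(cov_tbl, "results/coverage_by_level.csv")
print(cov_tbl)

# community profile from the survey-average composition
mean_ab <- setNames(rowMeans(ab$abundances), ab$taxa)
community <- weight_profiles(profiles, mean_ab, level = "genus")
print(community)
write_community_json(community, "results/community_profile.json",
                     provenance = list(abundances = "abundance_genus.tsv",
                                       rates = "strain_rates.csv",
                                       n_samples = ncol(ab$abundances)))

cat(sprintf("community: eps_tot %.2f mmol/g, demand %.2f mmol/g, yield %.4f g/mmol\n",
            community$epsilon_tot, community$carb_demand, community$y_carb))
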