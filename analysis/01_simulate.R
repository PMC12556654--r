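#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analyses:
# growth-experiment time series, strain rate tables, a microbiome
# composition survey, diet cohorts, and fecal-weight cohorts.

suppressPackageStartupMessages(library(gutharvest))
suppressPackageStartupMessages(library(tidyverse))

seed <- 20250730
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# growth experiments: three replicates for two archetypal strains
message("simulating growth experiments ...")
exps <- purrr::flatten(purrr::map2(
  c("Bacteroides_sim", "Blautia_sim"), c(15, 14),
  function(strain, eps) purrr::map(1:3, function(r)
    gen_growth_experiment(mu = 0.45, u = 13,
                          e = c(acetate = eps, butyrate = 0.4 * eps),
                          noise_sd = 0.15, seed = seed + r,
                          strain_id = strain, replicate_id = paste0("r", r)))))
growth_long <- purrr::map_dfr(exps, function(e)
  tidyr::pivot_longer(
    dplyr::mutate(e$samples, strain_id = e$strain_id,
                  replicate_id = e$replicate_id, medium = e$medium,
                  ph = 7, sugar = e$sugar),
    cols = -c(time_h, od600, strain_id, replicate_id, medium, ph, sugar),
    names_to = "metabolite", values_to = "concentration_mM"))
readr::write_csv(growth_long, file.path(out, "growth_experiments.csv"))

# strain rate profiles for the five major families
message("simulating strain rate profiles ...")
profiles <- gen_strain_archetypes(seed = seed)
write_rate_profiles_csv(profiles, file.path(out, "strain_rates.csv"))

# 219-sample genus-level composition survey
message("simulating abundance survey ...")
ab <- gen_abundance_samples(n_samples = 219, seed = seed)
write_abundance_tsv(ab, file.path(out, "abundance_genus.tsv"))

# diet cohorts: British reference, US-style, Hadza-style seasonal
message("simulating diet cohorts ...")
write_diet_csv(gen_diet_cohort("reference"),
               file.path(out, "diet_reference.csv"))
write_diet_csv(gen_diet_cohort("us", n = 219, seed = seed),
               file.path(out, "diet_us.csv"))
write_diet_csv(gen_diet_cohort("hadza_seasonal", seed = seed),
               file.path(out, "diet_hadza_seasonal.csv"))

# fecal wet-weight cohorts
message("simulating fecal cohorts ...")
fecal <- dplyr::bind_rows(
  tibble::tibble(cohort_id = "british",
                 individual_id = sprintf("b%03d", 1:219),
                 wet_g_per_day = gen_fecal_cohort("british", 219, seed)),
  tibble::tibble(cohort_id = "global",
                 individual_id = sprintf("g%03d", 1:219),
                 wet_g_per_day = gen_fecal_cohort("global", 219, seed)))
readr::write_csv(fecal, file.path(out, "fecal_cohorts.csv"))

message("fixtures written to ", out)
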