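#!/usr/bin/env Rscript
# Variation of the daily harvest with microbiome composition (fixed diet)
# and with diet/digestion (cohort sweeps), summarized as CVs and
# percentiles.

suppressPackageStartupMessages(library(gutharvest))
suppressPackageStartupMessages(library(tidyverse))

fix <- "results/fixtures"
ab <- read_abundance_tsv(file.path(fix, "abundance_genus.tsv"))
profiles <- read_rate_profiles_csv(file.path(fix, "strain_rates.csv"))
mean_ab <- setNames(rowMeans(ab$abundances), ab$taxa)
community <- weight_profiles(profiles, mean_ab, level = "genus")
mac <- mac_result(mac_mmol_hexose = 198, scenario = "medium")

# composition variation at fixed carbohydrate supply
vs <- composition_variation(ab, profiles, mac)
print(vs)
cv_tbl <- tibble::tibble(
  quantity = c("total", "biomass", names(vs$cv_by_product)),
  cv = c(vs$cv_total, vs$cv_biomass, unname(vs$cv_by_product)))
readr::write_csv(cv_tbl, "results/composition_cvs.csv")
cat(sprintf("CV(total) %.3f vs max per-product CV %.3f (%s)\n",
            vs$cv_total, max(vs$cv_by_product),
            names(which.max(vs$cv_by_product))))

# diet cohorts through the via-carbohydrates route
for (kind in c("us", "hadza_seasonal")) {
  cohort <- read_diet_csv(file.path(fix, paste0("diet_", kind, ".csv")))
  cs <- cohort_apply(cohort, community, scenario_params("medium"))
  readr::write_csv(cohort_tidy(cs),
                   sprintf("results/cohort_%s.csv", kind))
  cat(sprintf("%s cohort: median %.0f mmol/day (5th %.0f, 95th %.0f)\n",
              kind, cs$percentiles[["50"]], cs$percentiles[["5"]],
              cs$percentiles[["95"]]))
}

# fecal cohorts through the via-feces route (nonlinear water model)
fecal <- readr::read_csv(file.path(fix, "fecal_cohorts.csv"),
                         show_col_types = FALSE)
for (kind in unique(fecal$cohort_id)) {
  wets <- fecal$wet_g_per_day[fecal$cohort_id == kind]
  records <- lapply(wets, function(w)
    suppressWarnings(bacterial_biomass(w, model = "nonlinear")))
  cs <- cohort_apply(records, community)
  readr::write_csv(cohort_tidy(cs),
                   sprintf("results/cohort_fecal_%s.csv", kind))
  cat(sprintf("fecal %s cohort: median %.0f mmol/day (5th %.0f, 95th %.0f)\n",
              kind, cs$percentiles[["50"]], cs$percentiles[["5"]],
              cs$percentiles[["95"]]))
}
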