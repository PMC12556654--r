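#!/usr/bin/env Rscript
# Host energy accounting: energy content of the harvest across cohorts,
# the fraction of daily expenditure it covers, and the human-mouse
# comparison (germ-free gap vs harvest-based route, per-kg and per-area
# normalizations).

suppressPackageStartupMessages(library(gutharvest))
suppressPackageStartupMessages(library(tidyverse))

fix <- "results/fixtures"
profiles <- read_rate_profiles_csv(file.path(fix, "strain_rates.csv"))
ab <- read_abundance_tsv(file.path(fix, "abundance_genus.tsv"))
mean_ab <- setNames(rowMeans(ab$abundances), ab$taxa)
community <- weight_profiles(profiles, mean_ab, level = "genus")
ctx <- energy_context("human")

frac_of <- function(est) energy_fraction(harvest_energy(est), ctx)

british <- estimate_via_feces(
  bacterial_biomass(110, "constant", alpha_bac = 16 / 30), community)
us <- cohort_apply(read_diet_csv(file.path(fix, "diet_us.csv")), community)
glob_wets <- readr::read_csv(file.path(fix, "fecal_cohorts.csv"),
                             show_col_types = FALSE) |>
  dplyr::filter(cohort_id == "global") |> dplyr::pull(wet_g_per_day)
glob_fracs <- purrr::map_dbl(glob_wets, function(w)
  frac_of(estimate_via_feces(
    suppressWarnings(bacterial_biomass(w, "nonlinear")), community)))

us_fracs <- purrr::map_dbl(us$per_sample, frac_of)
energy_tbl <- tibble::tibble(
  scenario = c("us_median", "us_p5", "us_p95", "british_reference",
               "global_fecal_median", "global_fecal_p95"),
  percent_of_expenditure = c(
    median(us_fracs), quantile(us_fracs, 0.05, names = FALSE),
    quantile(us_fracs, 0.95, names = FALSE), frac_of(british),
    median(glob_fracs), quantile(glob_fracs, 0.95, names = FALSE)))
readr::write_csv(energy_tbl, "results/energy_fractions.csv")
print(energy_tbl)

mouse <- run_mouse_comparison()
print(mouse)
readr::write_csv(tibble::tibble(
  quantity = c("mouse_harvest_mmol_per_day", "mouse_energy_kj_per_day",
               "mouse_percent_harvest", "mouse_percent_gap",
               "mouse_mmol_per_kg", "human_mmol_per_kg",
               "mouse_mmol_per_m2", "human_mmol_per_m2"),
  value = c(mouse$mouse$estimate$fp_tot, mouse$mouse$energy_kj,
            mouse$mouse$percent_harvest, mouse$mouse$percent_gap,
            mouse$mouse$mmol_per_kg, mouse$human$mmol_per_kg,
            mouse$mouse$mmol_per_m2, mouse$human$mmol_per_m2)),
  "results/mouse_comparison.csv")
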