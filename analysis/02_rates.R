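#!/usr/bin/env Rscript
# Extract per-biomass uptake/excretion rates from the simulated growth
# experiments and validate every strain profile by carbon balance.

suppressPackageStartupMessages(library(gutharvest))
suppressPackageStartupMessages(library(tidyverse))

fix <- "results/fixtures"
stopifnot(file.exists(file.path(fix, "growth_experiments.csv")))

exps <- read_growth_csv(file.path(fix, "growth_experiments.csv"))
by_strain <- split(exps, purrr::map_chr(exps, "strain_id"))

fitted <- purrr::imap(by_strain, function(reps, strain) {
  prof <- compute_rate_profile(reps, od_to_dw = 0.5)
  mu <- fit_growth_rate(reps[[1]])
  cat(sprintf("%s: mu = %.3f /h (r2 %.3f), u = %.2f mmol/g, eps_tot = %.2f mmol/g\n",
              strain, mu$mu, mu$r_squared, prof$u, sum(pmax(prof$e, 0))))
  prof
})
write_rate_profiles_csv(unname(fitted), "results/fitted_rates.csv")

# carbon balances of the full archetype set
profiles <- read_rate_profiles_csv(file.path(fix, "strain_rates.csv"))
balances <- purrr::map_dfr(profiles, function(p) {
  cb <- carbon_balance(p)
  tibble::tibble(strain_id = p$strain_id, family = p$lineage[["family"]],
                 carbon_in_mmol_per_g = cb$carbon_in,
                 carbon_out_mmol_per_g = cb$carbon_out,
                 ratio = cb$ratio, flagged = cb$flagged)
})
readr::write_csv(balances, "results/carbon_balances.csv")
cat(sprintf("carbon balance across %d strains: %.3f (range %.3f-%.3f), %d flagged\n",
            nrow(balances), mean(balances$ratio), min(balances$ratio),
            max(balances$ratio), sum(balances$flagged)))
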