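# shared fixtures, built in code

# community profile carrying the published reference constants: total
# excretion 29 mmol/g split across products in gut-typical proportions,
# carbohydrate demand 13 mmol hexose equivalents per g biomass
reference_community <- function(sds = NULL) {
  split <- c(acetate = 0.442, propionate = 0.100, butyrate = 0.175,
             lactate = 0.078, formate = 0.113, succinate = 0.092)
  community_profile(29 * split / sum(split), carb_demand = 13, sds = sds)
}

# the British reference inputs: ~110 g/day wet weight at a constant dry
# fraction giving 30 g dry, of which 16/30 is bacterial biomass
reference_fecal <- function() {
  bacterial_biomass(110, model = "constant", alpha_bac = 16 / 30)
}

reference_mac <- function() {
  mac_result(mac_mmol_hexose = 198, scenario = "medium")
}

# default synthetic world (archetype strains + abundance survey), memoised
# so the suite builds it once
.world_cache <- new.env(parent = emptyenv())
default_world <- function(seed = 20250730, n_samples = 60) {
  key <- paste0("w", seed, "_", n_samples)
  if (is.null(.world_cache[[key]])) {
    profiles <- gen_strain_archetypes(seed = seed)
    ab <- gen_abundance_samples(n_samples = n_samples, seed = seed)
    mean_ab <- stats::setNames(rowMeans(ab$abundances), ab$taxa)
    .world_cache[[key]] <- list(
      profiles = profiles, abundances = ab, mean_ab = mean_ab,
      community = weight_profiles(profiles, mean_ab, level = "genus"))
  }
  .world_cache[[key]]
}

# independent OLS oracle: slope and its SE from the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  list(slope = slope, intercept = intercept, se = se)
}
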