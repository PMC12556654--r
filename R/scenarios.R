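#' Default scenario configuration
#'
#' Every tunable constant of the pipeline in one validated list:
#' rate extraction (`od_to_dw`, OD window), community weighting (level,
#' mode), MAC mapping (scenario, hexose mass), fecal model (model,
#' `alpha_bac`, British reference wet weight), carbon-flow fractions,
#' protein/mucin-route parameters, energy contexts, and the base seed for
#' all synthetic draws.
#'
#' @return Named list of class `scenario_config`.
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    seed = 20250730,
    rates = list(od_to_dw = 0.5, od_window = c(0.04, 0.5),
                 min_r_squared = 0.9),
    community = list(level = "genus", mode = "renormalize",
                     n_samples = 219, n_genera = 60, concentration = 50,
                     n_per_family = 4),
    mac = list(scenario = "medium", g_per_mmol_hexose = 0.18,
               sugar_passage = 0),
    fecal = list(model = "constant", alpha_bac = 16 / 30,
                 british_wet_g = 110, transit_k = 6000),
    carbon = list(frac_carb = 0.40, frac_biomass = 0.39,
                  fecal_fp_loss = 0.02),
    protein = list(ileal_passage = 0.1, mucin_g = 5, fp_yield = 2),
    mouse = list(wet_g = 1.5, alpha_dw = 0.30, alpha_bac = 0.50,
                 gap_kj = 8.1)
  ), class = "scenario_config")
}

.config_keys <- function() names(default_config())

#' Validate and complete a scenario configuration
#'
#' Unknown top-level keys are rejected; missing keys are filled from
#' [default_config()].
#'
#' @param config Named list of overrides (possibly nested), or `NULL`.
#' @return A validated `scenario_config`.
#' @export
validate_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (inherits(config, "scenario_config")) config <- unclass(config)
  unknown <- setdiff(names(config), names(base))
  abort_if(length(unknown) > 0,
           paste("unknown config keys:", paste(unknown, collapse = ", ")),
           "gh_config_error")
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(base[[k]]))
      abort_if(length(bad) > 0,
               paste0("unknown config keys under '", k, "': ",
                      paste(bad, collapse = ", ")),
               "gh_config_error")
      base[[k]][names(config[[k]])] <- config[[k]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  abort_if(!base$mac$scenario %in% c("low", "medium", "high"),
           "mac.scenario must be low, medium or high", "gh_config_error")
  abort_if(base$rates$od_to_dw <= 0, "rates.od_to_dw must be positive",
           "gh_config_error")
  class(base) <- "scenario_config"
  base
}

#' Write / read a scenario configuration as YAML
#'
#' @param config A `scenario_config`.
#' @param path YAML path.
#' @return `write_config`: the path, invisibly. `read_config`: a validated
#'   `scenario_config` identical to the one written.
#' @export
write_config <- function(config, path) {
  # full precision so a round trip reproduces the scenario exactly
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

# build the default synthetic community profile used by the scenarios
build_default_community <- function(config) {
  profiles <- gen_strain_archetypes(
    n_per_family = config$community$n_per_family, seed = config$seed)
  ab <- gen_abundance_samples(
    n_samples = config$community$n_samples,
    n_genera = config$community$n_genera,
    concentration = config$community$concentration, seed = config$seed)
  mean_ab <- stats::setNames(rowMeans(ab$abundances), ab$taxa)
  list(profiles = profiles, abundances = ab,
       community = weight_profiles(profiles, mean_ab,
                                   level = config$community$level,
                                   mode = config$community$mode))
}

#' Run the British reference scenario end to end
#'
#' Builds the synthetic community, forms the reference diet and fecal
#' inputs, and reports both harvest estimators with propagated SDs, the
#' carbon-flow ledger, the protein/mucin upper bound, and the host energy
#' fraction. All numbers are computed at run time from the configuration;
#' the report is deterministic for a fixed config.
#'
#' @param config Overrides merged into [default_config()].
#' @return List of class `scenario_report` with elements `community`,
#'   `mac`, `fecal`, `via_feces`, `via_carbs`, `carbon_flow`,
#'   `protein_bound`, `energy` and `config`.
#' @export
run_reference_scenario <- function(config = NULL) {
  config <- validate_config(config)
  world <- build_default_community(config)
  community <- world$community

  diet <- gen_diet_cohort("reference")[[1]]
  params <- scenario_params(config$mac$scenario,
                            sugar_passage = config$mac$sugar_passage,
                            g_per_mmol_hexose = config$mac$g_per_mmol_hexose)
  mac <- map_to_mac(diet, params)

  fecal <- bacterial_biomass(config$fecal$british_wet_g,
                             model = config$fecal$model,
                             alpha_bac = config$fecal$alpha_bac,
                             transit_k = config$fecal$transit_k)

  via_feces <- estimate_via_feces(fecal, community)
  via_carbs <- estimate_via_carbs(mac, community)
  flow <- carbon_flow(mac, via_carbs,
                      carbon_frac_carb = config$carbon$frac_carb,
                      carbon_frac_biomass = config$carbon$frac_biomass,
                      fecal_fp_loss = config$carbon$fecal_fp_loss)
  bound <- protein_mucin_bound(diet, total_fp = via_feces$fp_tot,
                               ileal_protein_passage = config$protein$ileal_passage,
                               mucin_secretion_g = config$protein$mucin_g,
                               fp_yield_mmol_per_g = config$protein$fp_yield)
  ctx <- energy_context("human")
  energy_kj <- harvest_energy(via_feces)
  structure(list(
    community = community, mac = mac, fecal = fecal,
    via_feces = via_feces, via_carbs = via_carbs,
    carbon_flow = flow, protein_bound = bound,
    energy = list(context = ctx, energy_kj = energy_kj,
                  percent_of_expenditure = energy_fraction(energy_kj, ctx),
                  mmol_per_kg = normalize_harvest(via_feces, ctx, "mass"),
                  mmol_per_m2 = normalize_harvest(via_feces, ctx, "area")),
    config = config
  ), class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("== British reference scenario ==\n")
  cat(sprintf("community: epsilon_tot %.1f mmol/g, carb demand %.1f mmol/g, coverage %.0f%%\n",
              x$community$epsilon_tot, x$community$carb_demand,
              100 * x$community$coverage))
  cat(sprintf("MAC: %.1f g/day = %.0f mmol hexose/day (%s scenario)\n",
              x$mac$mac_g, x$mac$mac_mmol_hexose, x$mac$scenario))
  cat(sprintf("feces: %.0f g wet -> %.1f g dry -> %.1f g bacterial/day\n",
              x$fecal$wet_g, x$fecal$dry_g, x$fecal$bacterial_g))
  cat(sprintf("harvest via feces:         %.0f +/- %.0f mmol/day\n",
              x$via_feces$fp_tot, x$via_feces$fp_tot_sd))
  cat(sprintf("harvest via carbohydrates: %.0f +/- %.0f mmol/day (biomass %.1f g/day)\n",
              x$via_carbs$fp_tot, x$via_carbs$fp_tot_sd,
              x$via_carbs$biomass_g))
  cat(sprintf("carbon to products: %.0f%% of MAC carbon; protein/mucin bound: %.1f%% of total\n",
              100 * x$carbon_flow$fractions[["fraction_to_fp"]],
              100 * x$protein_bound$fraction_of_total))
  cat(sprintf("energy: %.0f kJ/day = %.1f%% of expenditure; %.1f mmol/kg/day; %.0f mmol/m2/day\n",
              x$energy$energy_kj, x$energy$percent_of_expenditure,
              x$energy$mmol_per_kg, x$energy$mmol_per_m2))
  invisible(x)
}

#' Run the human-mouse comparison
#'
#' Computes the mouse harvest via the fecal route (mouse fixture: wet
#' weight, dry fraction and bacterial fraction from the configuration),
#' converts it to energy, and sets the harvest-based percentage of the
#' mouse's daily expenditure beside the percentage implied by the
#' conventional/germ-free energy-extraction gap; also reports per-kg
#' normalizations for both hosts.
#'
#' @param config Overrides merged into [default_config()].
#' @return List of class `mouse_report`.
#' @export
run_mouse_comparison <- function(config = NULL) {
  config <- validate_config(config)
  world <- build_default_community(config)
  community <- world$community
  mouse_ctx <- energy_context("mouse")
  human_ctx <- energy_context("human")

  mouse_fecal <- fecal_output(config$mouse$wet_g,
                              alpha_dw = config$mouse$alpha_dw,
                              alpha_bac = config$mouse$alpha_bac,
                              model = "constant")
  mouse_est <- estimate_via_feces(mouse_fecal, community)
  mouse_energy <- harvest_energy(mouse_est)
  gap <- mouse_energy_gap(config$mouse$gap_kj, 0, mouse_ctx)

  human_fecal <- bacterial_biomass(config$fecal$british_wet_g,
                                   model = config$fecal$model,
                                   alpha_bac = config$fecal$alpha_bac)
  human_est <- estimate_via_feces(human_fecal, community)

  structure(list(
    mouse = list(estimate = mouse_est, energy_kj = mouse_energy,
                 percent_harvest = energy_fraction(mouse_energy, mouse_ctx),
                 percent_gap = gap$percent,
                 mmol_per_kg = normalize_harvest(mouse_est, mouse_ctx, "mass"),
                 mmol_per_m2 = normalize_harvest(mouse_est, mouse_ctx, "area")),
    human = list(estimate = human_est,
                 mmol_per_kg = normalize_harvest(human_est, human_ctx, "mass"),
                 mmol_per_m2 = normalize_harvest(human_est, human_ctx, "area")),
    config = config
  ), class = "mouse_report")
}

#' @export
print.mouse_report <- function(x, ...) {
  cat("== Human-mouse comparison ==\n")
  cat(sprintf("mouse harvest: %.1f mmol/day = %.1f kJ/day; harvest route %.1f%%, gap route %.1f%% of %.0f kJ/day\n",
              x$mouse$estimate$fp_tot, x$mouse$energy_kj,
              x$mouse$percent_harvest, x$mouse$percent_gap,
              x$config$mouse$gap_kj / x$mouse$percent_gap * 100))
  cat(sprintf("per kg: mouse %.0f vs human %.1f mmol/kg/day; per m2: mouse %.0f vs human %.0f mmol/m2/day\n",
              x$mouse$mmol_per_kg, x$human$mmol_per_kg,
              x$mouse$mmol_per_m2, x$human$mmol_per_m2))
  invisible(x)
}

#' Serialize a scenario report to JSON
#'
#' Machine-readable counterpart of the printed report; every numeric field
#' carries a units suffix in its name.
#'
#' @param report A `scenario_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "scenario_report"))
  jsonlite::write_json(list(
    epsilon_tot_mmol_per_g = report$community$epsilon_tot,
    carb_demand_mmol_per_g = report$community$carb_demand,
    coverage_fraction = report$community$coverage,
    mac_g_per_day = report$mac$mac_g,
    mac_mmol_hexose_per_day = report$mac$mac_mmol_hexose,
    fecal_dry_g_per_day = report$fecal$dry_g,
    fecal_bacterial_g_per_day = report$fecal$bacterial_g,
    fp_tot_via_feces_mmol_per_day = report$via_feces$fp_tot,
    fp_tot_via_feces_sd_mmol_per_day = report$via_feces$fp_tot_sd,
    fp_tot_via_carbs_mmol_per_day = report$via_carbs$fp_tot,
    fp_tot_via_carbs_sd_mmol_per_day = report$via_carbs$fp_tot_sd,
    fp_by_product_via_feces_mmol_per_day =
      as.list(report$via_feces$fp_by_product),
    carbon_fraction_to_fp = unname(
      report$carbon_flow$fractions[["fraction_to_fp"]]),
    protein_mucin_fraction_of_total = report$protein_bound$fraction_of_total,
    energy_kj_per_day = report$energy$energy_kj,
    energy_percent_of_expenditure = report$energy$percent_of_expenditure,
    harvest_mmol_per_kg_per_day = report$energy$mmol_per_kg,
    harvest_mmol_per_m2_per_day = report$energy$mmol_per_m2
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
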