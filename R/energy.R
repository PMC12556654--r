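#' Host energy context
#'
#' Daily energy expenditure and body geometry used to place the harvest in
#' the host's energy budget. Human defaults: 10 MJ/day expenditure, 70 kg
#' reference body mass, 2.14 m^2 large-intestinal epithelial area. Mouse
#' defaults: 38 kJ/day, 25 g, 0.038 m^2. Body mass and epithelial areas are
#' reference-adult assumptions, not measured quantities.
#'
#' @param species `"human"` or `"mouse"`, or pass all fields explicitly.
#' @param expenditure_kj Daily energy expenditure, kJ/day (> 0).
#' @param body_mass_kg Body mass, kg (> 0).
#' @param epithelial_area_m2 Epithelial surface area, m^2 (> 0).
#' @return Object of class `energy_context`.
#' @export
energy_context <- function(species = c("human", "mouse"),
                           expenditure_kj = NULL, body_mass_kg = NULL,
                           epithelial_area_m2 = NULL) {
  species <- match.arg(species)
  defaults <- switch(species,
    human = list(expenditure_kj = 10000, body_mass_kg = 70,
                 epithelial_area_m2 = 2.14),
    mouse = list(expenditure_kj = 38, body_mass_kg = 0.025,
                 epithelial_area_m2 = 0.038)
  )
  ctx <- list(species = species,
              expenditure_kj = expenditure_kj %||% defaults$expenditure_kj,
              body_mass_kg = body_mass_kg %||% defaults$body_mass_kg,
              epithelial_area_m2 = epithelial_area_m2 %||%
                defaults$epithelial_area_m2)
  abort_if(any(unlist(ctx[-1]) <= 0), "context fields must be positive",
           "gh_context_error")
  structure(ctx, class = "energy_context")
}

#' Energy content of a harvest
#'
#' Multiplies each product flux by its combustion enthalpy and sums:
#' `E = sum_i FP_i * dH_i` (kJ/day). Only positive (released) fluxes count.
#'
#' @param est A `harvest_estimate`.
#' @param table Named enthalpies, kJ/mmol; must cover every product with
#'   positive flux (default [enthalpy_default]).
#' @return Energy, kJ/day.
#' @examples
#' cp <- community_profile(c(butyrate = 29), carb_demand = 13)
#' harvest_energy(estimate_via_feces(fecal_output(110, dry_g = 30), cp))
#' @export
harvest_energy <- function(est, table = enthalpy_default) {
  stopifnot(inherits(est, "harvest_estimate"))
  fp <- pmax(est$fp_by_product, 0)
  active <- names(fp)[fp > 0]
  missing <- setdiff(active, names(table))
  abort_if(length(missing) > 0,
           paste("enthalpy table misses products:",
                 paste(missing, collapse = ", ")),
           "gh_coverage_error")
  abort_if(any(table[active] <= 0), "enthalpies must be positive",
           "gh_domain_error")
  sum(fp[active] * table[active])
}

#' Fraction of the host's daily energy expenditure
#'
#' @param energy_kj Harvest energy, kJ/day.
#' @param ctx An [energy_context()].
#' @return Percent of daily expenditure.
#' @export
energy_fraction <- function(energy_kj, ctx) {
  stopifnot(inherits(ctx, "energy_context"))
  100 * energy_kj / ctx$expenditure_kj
}

#' Microbiota energy contribution from the germ-free comparison
#'
#' The difference in energy extraction between conventionally colonized and
#' germ-free animals bounds the microbiota's energetic contribution; it is
#' expressed as a percentage of the daily expenditure.
#'
#' @param extraction_conventional,extraction_germfree kJ/day (>= 0).
#' @param ctx An [energy_context()].
#' @return List with `gap_kj` and `percent`.
#' @export
mouse_energy_gap <- function(extraction_conventional, extraction_germfree,
                             ctx = energy_context("mouse")) {
  abort_if(extraction_conventional < 0 || extraction_germfree < 0,
           "extractions must be non-negative", "gh_domain_error")
  gap <- extraction_conventional - extraction_germfree
  if (gap < 0)
    warning("negative gap: colonization penalty scenario")
  list(gap_kj = gap, percent = 100 * gap / ctx$expenditure_kj)
}

#' Normalize a harvest by body mass or epithelial area
#'
#' Systemic exposure scales with body mass (mmol/kg/day); local epithelial
#' exposure scales with surface area (mmol/m^2/day).
#'
#' @param est A `harvest_estimate`.
#' @param ctx An [energy_context()].
#' @param by `"mass"` or `"area"`.
#' @return Normalized flux.
#' @export
normalize_harvest <- function(est, ctx, by = c("mass", "area")) {
  stopifnot(inherits(est, "harvest_estimate"),
            inherits(ctx, "energy_context"))
  by <- match.arg(by)
  denom <- switch(by, mass = ctx$body_mass_kg, area = ctx$epithelial_area_m2)
  abort_if(is.null(denom) || !is.finite(denom) || denom <= 0,
           paste("context is missing a positive", by, "field"),
           "gh_context_error")
  est$fp_tot / denom
}

#' Read an enthalpy table from CSV
#'
#' Two columns: `product`, `kJ_per_mmol`.
#'
#' @param path CSV path.
#' @return Named numeric vector, kJ/mmol.
#' @export
read_enthalpy_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  abort_if(!all(c("product", "kJ_per_mmol") %in% names(tb)),
           "enthalpy CSV needs columns product, kJ_per_mmol",
           "gh_format_error")
  stats::setNames(tb$kJ_per_mmol, tb$product)
}
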