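#' Construct a diet record
#'
#' Daily intake of the macronutrient classes relevant to colonic
#' fermentation, in g/day.
#'
#' @param fiber_g,starch_g,sugar_g,protein_g Daily intakes, g/day (>= 0).
#' @param id Individual or month identifier.
#' @return Object of class `diet_record`.
#' @export
diet_record <- function(fiber_g, starch_g, sugar_g = 0, protein_g = 0,
                        id = "diet") {
  vals <- c(fiber_g, starch_g, sugar_g, protein_g)
  abort_if(any(vals < 0), "diet components must be non-negative",
           "gh_domain_error")
  structure(list(id = id, fiber_g = fiber_g, starch_g = starch_g,
                 sugar_g = sugar_g, protein_g = protein_g),
            class = "diet_record")
}

#' Digestion-scenario parameters for the MAC mapping
#'
#' Fraction of each dietary carbohydrate class that escapes host digestion
#' and reaches the large intestine in microbially usable form:
#' high = 15% starch passage / 75% fiber digestion,
#' medium = 13% / 50%, low = 10% / 30%. Simple sugars are absorbed in the
#' small intestine, so `sugar_passage` defaults to 0 in every scenario
#' (override for malabsorption analyses).
#'
#' @param name `"low"`, `"medium"` or `"high"`.
#' @param sugar_passage Fraction of simple sugars reaching the colon.
#' @param g_per_mmol_hexose Mass of one mmol hexose equivalent; 0.180 g for
#'   free glucose (default), 0.162 g for anhydroglucose polymer units.
#' @return List of class `mac_params` with fields `starch_passage`,
#'   `fiber_digestibility`, `sugar_passage`, `g_per_mmol_hexose`, `scenario`.
#' @export
scenario_params <- function(name = c("medium", "low", "high"),
                            sugar_passage = 0,
                            g_per_mmol_hexose = .g_per_mol_hexose_free / 1000) {
  name <- match.arg(name)
  p <- switch(name,
    low    = c(0.10, 0.30),
    medium = c(0.13, 0.50),
    high   = c(0.15, 0.75)
  )
  mac_params(starch_passage = p[1], fiber_digestibility = p[2],
             sugar_passage = sugar_passage,
             g_per_mmol_hexose = g_per_mmol_hexose, scenario = name)
}

#' Explicit MAC mapping parameters
#'
#' @param starch_passage,fiber_digestibility,sugar_passage Fractions in [0,1].
#' @param g_per_mmol_hexose g per mmol hexose equivalent (> 0).
#' @param scenario Label recorded in results.
#' @return Object of class `mac_params`.
#' @export
mac_params <- function(starch_passage, fiber_digestibility, sugar_passage = 0,
                       g_per_mmol_hexose = .g_per_mol_hexose_free / 1000,
                       scenario = "custom") {
  fr <- c(starch_passage, fiber_digestibility, sugar_passage)
  abort_if(any(fr < 0 | fr > 1), "passage/digestibility must be in [0, 1]",
           "gh_config_error")
  abort_if(g_per_mmol_hexose <= 0, "g_per_mmol_hexose must be positive",
           "gh_config_error")
  structure(list(starch_passage = starch_passage,
                 fiber_digestibility = fiber_digestibility,
                 sugar_passage = sugar_passage,
                 g_per_mmol_hexose = g_per_mmol_hexose,
                 scenario = scenario),
            class = "mac_params")
}

#' Map a diet record to microbiota-available carbohydrates
#'
#' MAC mass is the digestion-weighted sum of the carbohydrate classes:
#' `mac_g = starch_passage * starch + fiber_digestibility * fiber +
#' sugar_passage * sugar`, converted to mmol hexose equivalents with the
#' configured hexose mass.
#'
#' @param diet A [diet_record()].
#' @param params A [mac_params()] or [scenario_params()] result.
#' @return List of class `mac_result`: `mac_g` (g/day), `mac_mmol_hexose`
#'   (mmol/day), `scenario`, `g_per_mmol_hexose`.
#' @examples
#' map_to_mac(diet_record(fiber_g = 20, starch_g = 100), scenario_params("medium"))
#' @export
map_to_mac <- function(diet, params = scenario_params("medium")) {
  stopifnot(inherits(diet, "diet_record"), inherits(params, "mac_params"))
  mac_g <- params$starch_passage * diet$starch_g +
    params$fiber_digestibility * diet$fiber_g +
    params$sugar_passage * diet$sugar_g
  structure(list(mac_g = mac_g,
                 mac_mmol_hexose = mac_g / params$g_per_mmol_hexose,
                 scenario = params$scenario,
                 g_per_mmol_hexose = params$g_per_mmol_hexose),
            class = "mac_result")
}

#' Construct a MAC result directly
#'
#' For workflows that start from a known MAC amount (e.g. a literature value
#' in g/day or mmol hexose equivalents/day) rather than from a diet record.
#'
#' @param mac_g g/day; give either this or `mac_mmol_hexose`.
#' @param mac_mmol_hexose mmol hexose equivalents/day.
#' @param g_per_mmol_hexose Conversion constant, g per mmol.
#' @param scenario Label.
#' @return Object of class `mac_result`.
#' @export
mac_result <- function(mac_g = NULL, mac_mmol_hexose = NULL,
                       g_per_mmol_hexose = .g_per_mol_hexose_free / 1000,
                       scenario = "custom") {
  abort_if(is.null(mac_g) && is.null(mac_mmol_hexose),
           "give mac_g or mac_mmol_hexose", "gh_domain_error")
  if (is.null(mac_g)) mac_g <- mac_mmol_hexose * g_per_mmol_hexose
  if (is.null(mac_mmol_hexose)) mac_mmol_hexose <- mac_g / g_per_mmol_hexose
  abort_if(mac_g < 0, "MAC must be non-negative", "gh_domain_error")
  structure(list(mac_g = mac_g, mac_mmol_hexose = mac_mmol_hexose,
                 scenario = scenario, g_per_mmol_hexose = g_per_mmol_hexose),
            class = "mac_result")
}

#' Upper-bound fermentation contribution of dietary protein and mucin
#'
#' Protein escaping ileal absorption plus secreted mucin is assumed to be
#' fermented completely to products (none used for bacterial protein
#' synthesis), making the result an explicit upper bound on the share of the
#' total fermentation product release attributable to protein routes.
#'
#' @param diet A [diet_record()] (uses `protein_g`).
#' @param total_fp Total carbohydrate-derived fermentation product release,
#'   mmol/day (> 0).
#' @param ileal_protein_passage Fraction of dietary protein reaching the
#'   colon (default 0.1).
#' @param mucin_secretion_g Daily mucin reaching the colon, g/day (default 5).
#' @param fp_yield_mmol_per_g Fermentation products per g protein fermented
#'   (default 2 mmol/g).
#' @return List of class `protein_mucin_bound`: `protein_to_colon_g`,
#'   `fp_from_protein_mmol`, `fraction_of_total`.
#' @export
protein_mucin_bound <- function(diet, total_fp, ileal_protein_passage = 0.1,
                                mucin_secretion_g = 5,
                                fp_yield_mmol_per_g = 2) {
  stopifnot(inherits(diet, "diet_record"))
  abort_if(total_fp <= 0, "total_fp must be positive", "gh_domain_error")
  pars <- c(ileal_protein_passage, mucin_secretion_g, fp_yield_mmol_per_g)
  abort_if(any(pars < 0), "protein-route parameters must be non-negative",
           "gh_domain_error")
  protein_to_colon <- ileal_protein_passage * diet$protein_g +
    mucin_secretion_g
  fp_from_protein <- fp_yield_mmol_per_g * protein_to_colon
  structure(list(protein_to_colon_g = protein_to_colon,
                 mucin_g = mucin_secretion_g,
                 fp_from_protein_mmol = fp_from_protein,
                 fraction_of_total = fp_from_protein /
                   (fp_from_protein + total_fp)),
            class = "protein_mucin_bound")
}

#' Theoretical harvest from bacterial ATP turnover
#'
#' An independent consistency check: the ATP needed to build the daily
#' bacterial biomass, divided by the ATP gained per fermentation product
#' released, predicts the total product release. Defaults use a biomass
#' yield on ATP of ~10.5 g/mol (95 mmol ATP per g biomass) and ~3 mmol ATP
#' per mmol fermentation product.
#'
#' @param biomass_g Daily bacterial biomass production, g/day.
#' @param atp_per_biomass mmol ATP per g biomass (default 95).
#' @param atp_per_fp mmol ATP gained per mmol product (default 3, > 0).
#' @return Predicted release, mmol/day.
#' @export
atp_theoretical_harvest <- function(biomass_g, atp_per_biomass = 95,
                                    atp_per_fp = 3) {
  abort_if(atp_per_fp <= 0, "atp_per_fp must be positive", "gh_domain_error")
  abort_if(biomass_g < 0 || atp_per_biomass < 0,
           "biomass and ATP demand must be non-negative", "gh_domain_error")
  biomass_g * atp_per_biomass / atp_per_fp
}

#' Read diet records from CSV
#'
#' Columns: `individual_id` (or `month`), `fiber_g`, `starch_g`, `sugar_g`,
#' `protein_g`.
#'
#' @param path CSV path.
#' @return List of [diet_record()] objects.
#' @export
read_diet_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  idcol <- intersect(c("individual_id", "month"), names(tb))
  abort_if(length(idcol) == 0, "diet CSV needs individual_id or month column",
           "gh_format_error")
  purrr::pmap(tb, function(...) {
    r <- list(...)
    diet_record(fiber_g = r$fiber_g, starch_g = r$starch_g,
                sugar_g = r$sugar_g %||% 0, protein_g = r$protein_g %||% 0,
                id = as.character(r[[idcol[1]]]))
  })
}

#' Write diet records to CSV
#'
#' @param records List of [diet_record()] objects.
#' @param path Output path.
#' @return The tibble written, invisibly.
#' @export
write_diet_csv <- function(records, path) {
  tb <- purrr::map_dfr(records, function(d)
    tibble::tibble(individual_id = d$id, fiber_g = d$fiber_g,
                   starch_g = d$starch_g, sugar_g = d$sugar_g,
                   protein_g = d$protein_g))
  readr::write_csv(tb, path)
  invisible(tb)
}
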