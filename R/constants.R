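#' Fermentation products tracked by the framework
#'
#' The six organic acids that dominate the metabolite exchange between an
#' anaerobically fermenting gut community and its host.
#'
#' @format Character vector of length 6.
#' @export
fermentation_products <- c(
  "acetate", "propionate", "butyrate", "lactate", "formate", "succinate"
)

#' Carbon atom counts for sugars and fermentation products
#'
#' Number of carbon atoms per molecule, used for carbon-balance validation of
#' strain rate profiles and for the community carbon-flow ledger.
#'
#' @format Named numeric vector (mol C / mol compound).
#' @export
carbon_atoms_default <- c(
  glucose = 6, maltose = 12,
  acetate = 2, propionate = 3, butyrate = 4,
  lactate = 3, formate = 1, succinate = 4
)

#' Default combustion enthalpies of fermentation products
#'
#' Standard combustion enthalpies in kJ per mmol, used to convert product
#' fluxes into host-available energy. Values come from standard
#' thermochemical tables and can be overridden with a user table
#' (see [read_enthalpy_csv()]).
#'
#' @format Named numeric vector (kJ/mmol).
#' @export
enthalpy_default <- c(
  acetate = 0.875, propionate = 1.527, butyrate = 2.184,
  lactate = 1.368, formate = 0.255, succinate = 1.491
)

# molar mass of free glucose, g/mol; anhydroglucose (polymer) alternative 162
.g_per_mol_hexose_free <- 180
.g_per_mol_hexose_polymer <- 162

.sugars <- c("glucose", "maltose")

# hexose units per molecule of sugar (maltose is a glucose dimer)
.hexose_units <- c(glucose = 1, maltose = 2)
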