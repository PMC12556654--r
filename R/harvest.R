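new_harvest_estimate <- function(fp_by_product, biomass_g, method,
                                 fp_tot_sd = NA_real_, provenance = list()) {
  fp_by_product <- canonical_products(fp_by_product)
  # absorbed flux cannot be negative: totals floor each product at 0,
  # so net acetate consumption reduces the acetate term but not below zero
  fp_tot <- sum(pmax(fp_by_product, 0))
  structure(
    list(fp_tot = fp_tot, fp_by_product = fp_by_product,
         biomass_g = biomass_g, fp_tot_sd = fp_tot_sd, method = method,
         provenance = provenance),
    class = "harvest_estimate"
  )
}

#' @export
print.harvest_estimate <- function(x, ...) {
  sd_txt <- if (is.finite(x$fp_tot_sd)) sprintf(" +/- %.0f", x$fp_tot_sd) else ""
  cat(sprintf("<harvest_estimate> [%s] %.1f%s mmol/day from %.2f g biomass/day\n",
              x$method, x$fp_tot, sd_txt, x$biomass_g))
  for (p in fermentation_products)
    cat(sprintf("  %-11s %8.1f mmol/day\n", p, x$fp_by_product[[p]]))
  invisible(x)
}

#' Harvest estimate via fecal bacterial biomass
#'
#' The bacterial biomass lost daily in feces must be replaced by growth, and
#' growth releases fermentation products at the community per-biomass rate:
#' `FP_tot = epsilon_tot * M_bacterial` and per product
#' `FP_i = e_w_i * M_bacterial`.
#'
#' @param fecal A [fecal_output()] (or [bacterial_biomass()] result).
#' @param community A [community_profile()].
#' @return A `harvest_estimate` (method `"via_feces"`), with the total's SD
#'   propagated from the community profile uncertainty.
#' @examples
#' cp <- community_profile(c(acetate = 29), carb_demand = 13)
#' estimate_via_feces(fecal_output(110, dry_g = 30), cp)$fp_tot # ~464
#' @export
estimate_via_feces <- function(fecal, community) {
  abort_if(!inherits(community, "community_profile"),
           "community profile required", "gh_dependency_error")
  stopifnot(inherits(fecal, "fecal_output"))
  abort_if(fecal$bacterial_g < 0, "bacterial biomass must be non-negative",
           "gh_domain_error")
  b <- fecal$bacterial_g
  sd_tot <- b * (sd_lookup(community$sds, "epsilon_tot"))
  new_harvest_estimate(
    fp_by_product = community$e_w * b, biomass_g = b, method = "via_feces",
    fp_tot_sd = sd_tot,
    provenance = list(wet_g = fecal$wet_g, dry_g = fecal$dry_g,
                      fecal_model = fecal$model,
                      epsilon_tot = community$epsilon_tot)
  )
}

#' Harvest estimate via dietary carbohydrates
#'
#' Microbiota-available carbohydrates fix the daily biomass production
#' through the community carbohydrate demand, and biomass production fixes
#' the product release: `M_bact = MAC_mmol / demand`,
#' `FP_tot = epsilon_tot * M_bact`.
#'
#' @param mac A [mac_result()] or [map_to_mac()] output.
#' @param community A [community_profile()].
#' @return A `harvest_estimate` (method `"via_carbohydrates"`), with the
#'   total's SD by Gaussian propagation through the quotient and product.
#' @examples
#' cp <- community_profile(c(acetate = 29), carb_demand = 13)
#' estimate_via_carbs(mac_result(mac_mmol_hexose = 198), cp)$fp_tot # ~442
#' @export
estimate_via_carbs <- function(mac, community) {
  stopifnot(inherits(mac, "mac_result"),
            inherits(community, "community_profile"))
  abort_if(community$carb_demand <= 0, "carb_demand must be positive",
           "gh_domain_error")
  biomass <- mac$mac_mmol_hexose / community$carb_demand
  fp <- community$e_w * biomass
  fp_tot <- sum(pmax(fp, 0))
  sd_tot <- if (fp_tot > 0 && community$epsilon_tot > 0) {
    propagate_error(values = c(community$epsilon_tot, community$carb_demand),
                    sds = c(sd_lookup(community$sds, "epsilon_tot"),
                            sd_lookup(community$sds, "carb_demand")),
                    structure = "quotient", result = fp_tot)
  } else 0
  new_harvest_estimate(
    fp_by_product = fp, biomass_g = biomass, method = "via_carbohydrates",
    fp_tot_sd = sd_tot,
    provenance = list(mac_g = mac$mac_g, mac_mmol = mac$mac_mmol_hexose,
                      scenario = mac$scenario,
                      carb_demand = community$carb_demand)
  )
}

#' Gaussian error propagation for product/quotient chains
#'
#' For results formed purely by multiplication and division, the relative
#' variance of the result is the sum of the relative variances of the
#' terms: `sd_rel(z)^2 = sum_i sd_rel(x_i)^2`. Terms with zero SD contribute
#' nothing; a zero-valued term with nonzero SD has no defined relative
#' error.
#'
#' @param values Numeric vector of term values (nonzero where `sds > 0`).
#' @param sds Matching standard deviations.
#' @param structure `"product"` or `"quotient"` (identical variance
#'   arithmetic; recorded for clarity of intent).
#' @param result Value of the combined quantity; defaults to
#'   `prod(values)` for products and `values[1]/prod(values[-1])` for
#'   quotients.
#' @return Standard deviation of the result, on the result's scale.
#' @examples
#' propagate_error(c(10, 20), c(1, 2)) / (10 * 20) # 0.1414...
#' @export
propagate_error <- function(values, sds, structure = c("product", "quotient"),
                            result = NULL) {
  structure <- match.arg(structure)
  stopifnot(length(values) == length(sds))
  abort_if(any(values == 0 & sds > 0),
           "zero-valued term with nonzero sd: relative error undefined",
           "gh_degenerate_error")
  rel <- ifelse(sds == 0, 0, sds / abs(values))
  if (is.null(result)) {
    result <- if (structure == "product") prod(values)
              else values[1] / prod(values[-1])
  }
  abs(result) * sqrt(sum(rel^2))
}

#' Carbon-flow ledger along the large intestine
#'
#' Accounts the daily carbon in microbiota-available carbohydrates, in
#' released fermentation products, in produced bacterial biomass, and the
#' split of product carbon between fecal loss and host absorption.
#' Carbohydrate carbon uses the mass fraction of carbon in glucose (0.40);
#' biomass carbon uses 0.39 g C per g dry biomass; product carbon comes
#' from per-product carbon atom counts (12 g/mol C).
#'
#' @param mac A [mac_result()].
#' @param est A `harvest_estimate`.
#' @param carbon_frac_carb Carbon mass fraction of carbohydrates.
#' @param carbon_frac_biomass Carbon mass fraction of dry biomass.
#' @param fecal_fp_loss Fraction of released products lost in feces
#'   (default 0.02).
#' @param carbon_atoms Per-compound carbon counts.
#' @return List of class `carbon_flow` with `nodes` (named g C/day) and
#'   `fractions` (`fraction_to_fp`, `fraction_to_biomass`,
#'   `fraction_absorbed`).
#' @export
carbon_flow <- function(mac, est, carbon_frac_carb = 0.40,
                        carbon_frac_biomass = 0.39, fecal_fp_loss = 0.02,
                        carbon_atoms = carbon_atoms_default) {
  stopifnot(inherits(mac, "mac_result"), inherits(est, "harvest_estimate"))
  fr <- c(carbon_frac_carb, carbon_frac_biomass, fecal_fp_loss)
  abort_if(any(fr < 0 | fr > 1), "fractions must lie in [0, 1]",
           "gh_domain_error")
  mac_c <- mac$mac_g * carbon_frac_carb
  fp_pos <- pmax(est$fp_by_product, 0)
  fp_c <- sum(fp_pos * carbon_atoms[names(fp_pos)]) * 12 / 1000
  biomass_c <- est$biomass_g * carbon_frac_biomass
  fecal_c <- fp_c * fecal_fp_loss
  absorbed_c <- fp_c * (1 - fecal_fp_loss)
  structure(
    list(nodes = c(mac_carbon_g = mac_c, fp_carbon_g = fp_c,
                   biomass_carbon_g = biomass_c,
                   fecal_fp_carbon_g = fecal_c,
                   absorbed_fp_carbon_g = absorbed_c),
         fractions = c(fraction_to_fp = if (mac_c > 0) fp_c / mac_c else 0,
                       fraction_to_biomass = if (mac_c > 0) biomass_c / mac_c
                                             else 0,
                       fraction_absorbed = 1 - fecal_fp_loss)),
    class = "carbon_flow"
  )
}

#' @export
print.carbon_flow <- function(x, ...) {
  cat("<carbon_flow> g carbon/day:\n")
  for (n in names(x$nodes)) cat(sprintf("  %-22s %8.3f\n", n, x$nodes[[n]]))
  cat(sprintf("  fraction of MAC carbon to products: %.1f%%\n",
              100 * x$fractions[["fraction_to_fp"]]))
  invisible(x)
}

quantile_levels <- c(5, 25, 50, 75, 95)

summarize_estimates <- function(estimates) {
  totals <- purrr::map_dbl(estimates, function(e) e$fp_tot)
  prod_mat <- do.call(rbind, purrr::map(estimates, function(e)
    pmax(e$fp_by_product, 0)))
  cv <- function(x) if (mean(x) == 0) 0 else stats::sd(x) / mean(x)
  structure(
    list(per_sample = estimates,
         totals = totals,
         cv_total = cv(totals),
         cv_biomass = cv(purrr::map_dbl(estimates, function(e) e$biomass_g)),
         cv_by_product = apply(prod_mat, 2, cv),
         percentiles = stats::setNames(
           stats::quantile(totals, quantile_levels / 100, type = 7,
                           names = FALSE),
           quantile_levels)),
    class = "variation_summary"
  )
}

#' @export
print.variation_summary <- function(x, ...) {
  cat(sprintf("<variation_summary> n = %d, median total = %.0f mmol/day, CV(total) = %.3f\n",
              length(x$per_sample), x$percentiles[["50"]], x$cv_total))
  cat("  per-product CV:",
      paste(sprintf("%s %.2f", names(x$cv_by_product), x$cv_by_product),
            collapse = ", "), "\n")
  invisible(x)
}

#' Harvest variation across microbiome compositions
#'
#' Holds the carbohydrate input fixed and recomputes the via-carbohydrates
#' estimate for every sample of an abundance table, then summarizes the
#' spread: coefficients of variation of the total, of the biomass, and of
#' each product, plus percentiles of the total.
#'
#' @param table An [abundance_table()].
#' @param profiles Strain rate profiles (see [weight_profiles()]).
#' @param mac A fixed [mac_result()].
#' @param level,mode Passed to [weight_profiles()].
#' @return A `variation_summary`.
#' @export
composition_variation <- function(table, profiles, mac, level = "genus",
                                  mode = "renormalize") {
  stopifnot(inherits(table, "abundance_table"))
  abort_if(ncol(table$abundances) < 2,
           "need >= 2 samples for a coefficient of variation",
           "gh_insufficient_data")
  estimates <- purrr::map(
    stats::setNames(seq_len(ncol(table$abundances)),
                    colnames(table$abundances)),
    function(j) {
      ab <- stats::setNames(table$abundances[, j], table$taxa)
      cp <- weight_profiles(profiles, ab, level = level, mode = mode)
      estimate_via_carbs(mac, cp)
    })
  summarize_estimates(estimates)
}

#' Apply the matching estimator across a cohort
#'
#' Diet records are mapped through the MAC scenario and the
#' via-carbohydrates estimator; fecal records go through the via-feces
#' estimator. Mixed cohorts are rejected. Percentiles use linear
#' interpolation between order statistics (the median is the 50th).
#'
#' @param records List of [diet_record()] or [fecal_output()] objects.
#' @param community A [community_profile()].
#' @param scenario A [mac_params()] (diet cohorts only).
#' @return A `variation_summary`.
#' @export
cohort_apply <- function(records, community,
                         scenario = scenario_params("medium")) {
  abort_if(length(records) == 0, "cohort is empty", "gh_domain_error")
  is_diet <- purrr::map_lgl(records, inherits, "diet_record")
  is_fecal <- purrr::map_lgl(records, inherits, "fecal_output")
  abort_if(!all(is_diet) && !all(is_fecal),
           "cohort must be all diet records or all fecal records",
           "gh_type_error")
  estimates <- if (all(is_diet)) {
    purrr::map(records, function(d)
      estimate_via_carbs(map_to_mac(d, scenario), community))
  } else {
    purrr::map(records, function(f) estimate_via_feces(f, community))
  }
  names(estimates) <- purrr::map_chr(seq_along(records), function(i) {
    id <- records[[i]]$id %||% NULL
    if (is.null(id)) paste0("record_", i) else as.character(id)
  })
  if (length(estimates) == 1) {
    e <- estimates[[1]]
    structure(list(per_sample = estimates, totals = e$fp_tot, cv_total = NA_real_,
                   cv_biomass = NA_real_,
                   cv_by_product = stats::setNames(
                     rep(NA_real_, length(fermentation_products)),
                     fermentation_products),
                   percentiles = stats::setNames(
                     rep(e$fp_tot, length(quantile_levels)), quantile_levels)),
              class = "variation_summary")
  } else {
    summarize_estimates(estimates)
  }
}

#' Write harvest estimates as JSON
#'
#' @param est A `harvest_estimate`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_estimate_json <- function(est, path) {
  jsonlite::write_json(
    list(method = est$method,
         fp_tot_mmol_per_day = est$fp_tot,
         fp_by_product_mmol_per_day = as.list(est$fp_by_product),
         biomass_g_per_day = est$biomass_g,
         fp_tot_sd_mmol_per_day = est$fp_tot_sd,
         provenance = est$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tidy per-sample cohort table
#'
#' @param vs A `variation_summary`.
#' @return Tibble with one row per record: id, method, biomass, total and
#'   per-product fluxes.
#' @export
cohort_tidy <- function(vs) {
  stopifnot(inherits(vs, "variation_summary"))
  purrr::imap_dfr(vs$per_sample, function(e, id) {
    row <- tibble::tibble(id = id, method = e$method,
                          biomass_g_per_day = e$biomass_g,
                          fp_tot_mmol_per_day = e$fp_tot)
    for (p in fermentation_products)
      row[[paste0(p, "_mmol_per_day")]] <- e$fp_by_product[[p]]
    row
  })
}
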