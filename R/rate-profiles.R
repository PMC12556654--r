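#' Construct a strain rate profile
#'
#' Per-biomass sugar uptake and fermentation-product excretion rates of one
#' strain in one medium, in mmol per g dry biomass. `u_hexose` expresses the
#' uptake in hexose (glucose-unit) equivalents: maltose counts double.
#'
#' Net acetate uptake is permitted (media may contain background acetate and
#' acetogenic strains can consume it); all other product rates must be
#' non-negative.
#'
#' @param strain_id Strain identifier.
#' @param u Sugar uptake rate, mmol sugar / g dry biomass (>= 0).
#' @param e Named numeric: excretion rates mmol/g for the six products;
#'   missing products default to 0.
#' @param sugar `"glucose"` or `"maltose"`.
#' @param lineage Named character vector of taxonomy labels
#'   (e.g. `c(family = "Bacteroidaceae", genus = "Bacteroides")`).
#' @param medium Medium label.
#' @param sds Named numeric standard deviations for `u` and each product
#'   (names `"u"` and product names); defaults to zeros.
#' @param n_replicates Number of biological replicates behind the profile.
#' @param od_to_dw OD600-to-dry-weight conversion used (g/L per OD unit),
#'   recorded for provenance.
#' @return An object of class `strain_rate_profile`.
#' @export
strain_rate_profile <- function(strain_id, u, e, sugar = "glucose",
                                lineage = c(genus = NA_character_),
                                medium = "YCA", sds = NULL,
                                n_replicates = 1L, od_to_dw = NA_real_) {
  sugar <- match.arg(sugar, .sugars)
  abort_if(u < 0, "sugar uptake u must be non-negative", "gh_domain_error")
  e <- canonical_products(e)
  abort_if(any(!is.finite(e)), "all excretion rates must be finite",
           "gh_domain_error")
  neg <- e < 0 & names(e) != "acetate"
  abort_if(any(neg),
           paste("negative excretion for", paste(names(e)[neg], collapse = ", "),
                 "- only net acetate uptake is allowed"),
           "gh_domain_error")
  if (is.null(sds)) sds <- c(u = 0, canonical_products(NULL))
  abort_if(any(sds < 0, na.rm = TRUE), "sds must be non-negative",
           "gh_domain_error")
  structure(
    list(strain_id = strain_id, lineage = lineage, medium = medium,
         sugar = sugar, u = u, u_hexose = u * .hexose_units[[sugar]],
         e = e, sds = sds, n_replicates = as.integer(n_replicates),
         od_to_dw = od_to_dw),
    class = "strain_rate_profile"
  )
}

#' @export
print.strain_rate_profile <- function(x, ...) {
  cat(sprintf("<strain_rate_profile> %s (%s, %s): u = %.2f mmol/g (%.2f hexose eq.), total excretion = %.2f mmol/g, n = %d\n",
              x$strain_id, x$medium, x$sugar, x$u, x$u_hexose,
              sum(pmax(x$e, 0)), x$n_replicates))
  invisible(x)
}

#' Turn growth experiments into a per-biomass rate profile
#'
#' Converts concentration-versus-OD slopes into per-dry-biomass rates:
#' `e_i = slope_i / od_to_dw` and `u = -slope_sugar / od_to_dw` (mM per OD
#' divided by g/L per OD gives mmol per g). Replicates are screened for
#' steady exponential growth (positive growth rate and good log-linear fit),
#' then averaged without weighting; the reported uncertainties are standard
#' deviations across biological replicates.
#'
#' @param exps A [growth_experiment()] or list of replicate experiments of
#'   the same strain and medium.
#' @param od_to_dw Dry-biomass conversion, g/L per OD600 unit (> 0). No
#'   universal value is printed in the literature for gut anaerobes; the
#'   documented default 0.5 g/L/OD must be calibrated per instrument for
#'   quantitative work, and is recorded in the output.
#' @param lineage Taxonomy labels passed to [strain_rate_profile()].
#' @param od_window OD600 window of steady exponential growth.
#' @param min_r_squared Replicates whose log-OD fit has `r^2` below this (or
#'   a non-positive growth rate) are excluded, with a message.
#' @param clip_negative Products (other than acetate) with a negative fitted
#'   rate are clipped to 0; a warning is raised when the negative fit is
#'   significant (|rate| > 2 SE).
#' @return A [strain_rate_profile()].
#' @export
compute_rate_profile <- function(exps, od_to_dw = 0.5, lineage = NULL,
                                 od_window = c(0.04, 0.5),
                                 min_r_squared = 0.9, clip_negative = TRUE) {
  abort_if(od_to_dw <= 0, "od_to_dw must be positive", "gh_domain_error")
  if (inherits(exps, "growth_experiment")) exps <- list(exps)
  stopifnot(length(exps) >= 1, all(purrr::map_lgl(exps, inherits,
                                                  "growth_experiment")))
  sugar <- exps[[1]]$sugar
  keep <- purrr::map_lgl(exps, function(e) {
    g <- fit_growth_rate(e, od_window)
    ok <- g$growing && g$r_squared >= min_r_squared
    if (!ok) message(sprintf(
      "excluding replicate %s: mu = %.3g /h, r^2 = %.3f (non-growing or poor fit)",
      e$replicate_id, g$mu, g$r_squared))
    ok
  })
  abort_if(!any(keep), "no replicate passed the growth screen",
           "gh_insufficient_data")
  exps <- exps[keep]

  per_rep <- purrr::map(exps, function(e) {
    sl <- fit_concentration_slopes(e, od_window)
    rates <- stats::setNames(sl$slope / od_to_dw, sl$metabolite)
    sds <- stats::setNames(sl$slope_sd / od_to_dw, sl$metabolite)
    list(rates = rates, sds = sds)
  })
  metab <- names(per_rep[[1]]$rates)
  rate_mat <- do.call(rbind, purrr::map(per_rep, function(p) p$rates[metab]))
  mean_rates <- colMeans(rate_mat)
  rep_sd <- if (nrow(rate_mat) > 1) apply(rate_mat, 2, stats::sd)
            else per_rep[[1]]$sds[metab]

  abort_if(!sugar %in% metab,
           sprintf("sugar column '%s' missing from experiment", sugar),
           "gh_domain_error")
  u <- -mean_rates[[sugar]]
  abort_if(u < 0, "fitted sugar slope is positive: no net uptake",
           "gh_domain_error")
  e <- mean_rates[intersect(fermentation_products, metab)]
  if (clip_negative) {
    for (p in setdiff(names(e), "acetate")) {
      if (e[[p]] < 0) {
        if (abs(e[[p]]) > 2 * rep_sd[[p]])
          warning(sprintf("significant negative excretion fitted for %s (%.3g mmol/g); clipped to 0", p, e[[p]]))
        e[[p]] <- 0
      }
    }
  }
  sds <- c(u = unname(rep_sd[[sugar]]),
           canonical_products(rep_sd[intersect(fermentation_products, metab)]))
  strain_rate_profile(
    strain_id = exps[[1]]$strain_id, u = u, e = e, sugar = sugar,
    lineage = lineage %||% c(genus = NA_character_),
    medium = exps[[1]]$medium, sds = sds,
    n_replicates = length(exps), od_to_dw = od_to_dw
  )
}

#' Carbon balance of a strain rate profile
#'
#' Compares the carbon taken up as sugar with the carbon excreted as
#' fermentation products, both in mmol C per g dry biomass. Ratios near 1
#' indicate that fermentation of the supplied sugar accounts for the
#' excreted products; ratios well above ~1.1 are flagged as likely
#' utilization of other media components.
#'
#' @param profile A [strain_rate_profile()].
#' @param carbon_atoms Named carbon counts covering the sugar and products.
#' @param flag_threshold Ratio above which the profile is flagged.
#' @return List with `carbon_in`, `carbon_out` (mmol C/g), `ratio`, and
#'   `flagged`.
#' @export
carbon_balance <- function(profile, carbon_atoms = carbon_atoms_default,
                           flag_threshold = 1.1) {
  stopifnot(inherits(profile, "strain_rate_profile"))
  needed <- c(profile$sugar, names(profile$e))
  abort_if(!all(needed %in% names(carbon_atoms)),
           "carbon_atoms must cover the sugar and all products",
           "gh_domain_error")
  abort_if(profile$u == 0, "carbon balance undefined for u = 0",
           "gh_domain_error")
  carbon_in <- profile$u * carbon_atoms[[profile$sugar]]
  pos_e <- pmax(profile$e, 0)  # only excreted carbon counts as output
  carbon_out <- sum(pos_e * carbon_atoms[names(pos_e)])
  ratio <- carbon_out / carbon_in
  list(carbon_in = carbon_in, carbon_out = carbon_out, ratio = ratio,
       flagged = ratio > flag_threshold)
}

#' pH sensitivity of uptake and excretion rates
#'
#' Regresses each per-biomass rate against culture pH across profiles of the
#' same strain measured at several pH levels, and reports the slope per pH
#' unit together with the relative change implied between pH 6 and pH 7
#' (slope times one pH unit divided by the fitted rate at pH 7, sign
#' preserved).
#'
#' @param profiles List of [strain_rate_profile()] objects with `$ph` set
#'   (attach pH with `profile$ph <- value` or via [compute_rate_profile()]
#'   inputs); at least 3 distinct pH levels are required.
#' @param ph Numeric vector of pH values matching `profiles` (overrides any
#'   `$ph` elements if given).
#' @return Tibble with one row per quantity (`u`, each product, and
#'   `excretion_total`): `slope_per_ph_unit`, `slope_sd`, `value_at_ph7`,
#'   `relative_change_6_to_7`.
#' @export
ph_sensitivity <- function(profiles, ph = NULL) {
  stopifnot(all(purrr::map_lgl(profiles, inherits, "strain_rate_profile")))
  ph <- ph %||% purrr::map_dbl(profiles, function(p) p$ph %||% NA_real_)
  abort_if(anyNA(ph), "every profile needs a pH value", "gh_domain_error")
  abort_if(length(unique(ph)) < 3, "need at least 3 distinct pH levels",
           "gh_insufficient_data")
  quantities <- c("u", fermentation_products, "excretion_total")
  vals <- purrr::map(profiles, function(p)
    c(u = p$u, p$e, excretion_total = sum(pmax(p$e, 0))))
  mat <- do.call(rbind, vals)
  purrr::map_dfr(quantities, function(q) {
    y <- mat[, q]
    fit <- stats::lm(y ~ ph)
    slope <- unname(stats::coef(fit)[["ph"]])
    at7 <- unname(stats::predict(fit, newdata = data.frame(ph = 7)))
    tibble::tibble(
      quantity = q,
      slope_per_ph_unit = slope,
      slope_sd = quiet_summary(fit)$coefficients["ph", "Std. Error"],
      value_at_ph7 = at7,
      relative_change_6_to_7 = if (at7 == 0) 0 else slope / at7
    )
  })
}

#' Write strain rate profiles to CSV
#'
#' One row per strain and medium with columns `u_mmol_per_g`,
#' `u_hexose_mmol_per_g`, `e_<product>_mmol_per_g`, matching `sd_*` columns,
#' and `n_replicates`.
#'
#' @param profiles List of [strain_rate_profile()] objects.
#' @param path Output CSV path.
#' @return The tibble written, invisibly.
#' @export
write_rate_profiles_csv <- function(profiles, path) {
  tb <- purrr::map_dfr(profiles, function(p) {
    row <- tibble::tibble(
      strain_id = p$strain_id,
      genus = p$lineage[["genus"]] %||% NA_character_,
      family = if ("family" %in% names(p$lineage)) p$lineage[["family"]] else NA_character_,
      medium = p$medium, sugar = p$sugar,
      u_mmol_per_g = p$u, u_hexose_mmol_per_g = p$u_hexose,
      sd_u_mmol_per_g = unname(p$sds[["u"]])
    )
    for (pr in fermentation_products) {
      row[[paste0("e_", pr, "_mmol_per_g")]] <- p$e[[pr]]
      row[[paste0("sd_", pr, "_mmol_per_g")]] <- unname(p$sds[pr])
    }
    row$n_replicates <- p$n_replicates
    row$od_to_dw <- p$od_to_dw
    row
  })
  readr::write_csv(tb, path)
  invisible(tb)
}

#' Read strain rate profiles from CSV
#'
#' Inverse of [write_rate_profiles_csv()].
#'
#' @param path CSV path.
#' @return List of [strain_rate_profile()] objects.
#' @export
read_rate_profiles_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  purrr::pmap(tb, function(...) {
    r <- list(...)
    e <- stats::setNames(
      purrr::map_dbl(fermentation_products,
                     function(p) r[[paste0("e_", p, "_mmol_per_g")]]),
      fermentation_products)
    sds <- c(u = r$sd_u_mmol_per_g,
             stats::setNames(
               purrr::map_dbl(fermentation_products,
                              function(p) r[[paste0("sd_", p, "_mmol_per_g")]]),
               fermentation_products))
    strain_rate_profile(
      strain_id = r$strain_id, u = r$u_mmol_per_g, e = e, sugar = r$sugar,
      lineage = c(family = r$family %||% NA_character_, genus = r$genus),
      medium = r$medium, sds = sds, n_replicates = r$n_replicates,
      od_to_dw = r$od_to_dw %||% NA_real_
    )
  })
}

#' Read growth experiments from long-format CSV
#'
#' Expects columns `strain_id`, `replicate_id`, `medium`, `ph`, `time_h`,
#' `od600`, `metabolite`, `concentration_mM` and an optional `sugar` column
#' (default glucose). Returns one [growth_experiment()] per
#' strain/medium/replicate combination.
#'
#' @param path CSV path.
#' @return List of [growth_experiment()] objects.
#' @export
read_growth_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("strain_id", "replicate_id", "medium", "ph", "time_h", "od600",
            "metabolite", "concentration_mM")
  abort_if(!all(need %in% names(tb)),
           paste("growth CSV must have columns:", paste(need, collapse = ", ")),
           "gh_format_error")
  if (!"sugar" %in% names(tb)) tb$sugar <- "glucose"
  groups <- dplyr::group_split(tb, .data$strain_id, .data$medium,
                               .data$replicate_id)
  purrr::map(groups, function(g) {
    wide <- tidyr::pivot_wider(g, id_cols = c("time_h", "od600"),
                               names_from = "metabolite",
                               values_from = "concentration_mM")
    growth_experiment(
      strain_id = g$strain_id[1], samples = dplyr::arrange(wide, .data$time_h),
      medium = g$medium[1], ph = g$ph[1], replicate_id = g$replicate_id[1],
      sugar = g$sugar[1]
    )
  })
}
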