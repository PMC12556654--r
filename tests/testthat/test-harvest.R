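test_that("via-feces estimator multiplies biomass by the community rate", {
  est <- estimate_via_feces(reference_fecal(), reference_community())
  expect_equal(est$fp_tot, 16 * 29, tolerance = 1e-9)   # 464 mmol/day
  expect_equal(est$biomass_g, 16, tolerance = 1e-9)

  zero <- estimate_via_feces(
    bacterial_biomass(110, "constant", alpha_bac = 0), reference_community())
  expect_equal(zero$fp_tot, 0)
})

test_that("via-carbohydrates estimator chains MAC, demand and excretion", {
  est <- estimate_via_carbs(reference_mac(), reference_community())
  expect_equal(est$biomass_g, 198 / 13, tolerance = 1e-9)  # ~15.2 g/day
  expect_equal(est$fp_tot, 198 / 13 * 29, tolerance = 1e-9) # ~441.7

  zero <- estimate_via_carbs(mac_result(mac_g = 0), reference_community())
  expect_equal(zero$fp_tot, 0)
  expect_equal(zero$biomass_g, 0)
})

test_that("per-product fluxes sum to the total on synthetic profiles", {
  w <- default_world()
  est <- estimate_via_carbs(reference_mac(), w$community)
  expect_equal(sum(pmax(est$fp_by_product, 0)), est$fp_tot,
               tolerance = 1e-12)
  est2 <- estimate_via_feces(reference_fecal(), w$community)
  expect_equal(sum(pmax(est2$fp_by_product, 0)), est2$fp_tot,
               tolerance = 1e-12)
})

test_that("harvest is exactly linear in biomass and in MAC", {
  cp <- reference_community()
  e1 <- estimate_via_feces(fecal_output(100, dry_g = 20, alpha_bac = 0.5), cp)
  e2 <- estimate_via_feces(fecal_output(300, dry_g = 60, alpha_bac = 0.5), cp)
  expect_equal(e2$fp_tot, 3 * e1$fp_tot, tolerance = 1e-12)

  c1 <- estimate_via_carbs(mac_result(mac_mmol_hexose = 100), cp)
  c2 <- estimate_via_carbs(mac_result(mac_mmol_hexose = 250), cp)
  expect_equal(c2$fp_tot, 2.5 * c1$fp_tot, tolerance = 1e-12)
})

test_that("the two estimators agree exactly on consistency-constructed worlds", {
  w <- default_world()
  cp <- w$community
  mac <- mac_result(mac_mmol_hexose = 198)
  # construct fecal loss equal to the biomass the carbohydrates produce
  biomass <- mac$mac_mmol_hexose / cp$carb_demand
  fecal <- fecal_output(biomass / 0.5 / 0.27, alpha_dw = 0.27,
                        alpha_bac = 0.5)
  expect_equal(fecal$bacterial_g, biomass, tolerance = 1e-12)
  via_f <- estimate_via_feces(fecal, cp)
  via_c <- estimate_via_carbs(mac, cp)
  expect_equal(via_f$fp_tot, via_c$fp_tot, tolerance = 1e-9)
  expect_equal(via_f$fp_by_product, via_c$fp_by_product, tolerance = 1e-9)
})

test_that("net acetate uptake reduces acetate but never below zero in totals", {
  cp <- community_profile(c(acetate = -2, butyrate = 10, propionate = 5),
                          carb_demand = 13)
  est <- estimate_via_feces(fecal_output(110, dry_g = 30), cp)
  expect_equal(est$fp_tot, (10 + 5) * 16, tolerance = 1e-9)
  expect_lt(est$fp_by_product[["acetate"]], 0)  # net term kept visible
})

test_that("Gaussian propagation follows the quadrature rule", {
  # 10% and 10% relative -> 14.14% relative
  sd <- propagate_error(c(10, 20), c(1, 2))
  expect_equal(sd / 200, sqrt(0.02), tolerance = 1e-12)
  # zero-sd terms contribute nothing
  expect_equal(propagate_error(c(10, 20, 5), c(1, 2, 0)) / 1000, sqrt(0.02),
               tolerance = 1e-12)
  expect_error(propagate_error(c(0, 1), c(1, 1)),
               class = "gh_degenerate_error")
})

test_that("Gaussian propagation matches a Monte-Carlo oracle", {
  withr::with_seed(99, {
    vals <- c(29, 16); sds <- c(2.9, 1.6)          # 10% each
    gauss <- propagate_error(vals, sds)
    draws <- rnorm(1e5, vals[1], sds[1]) * rnorm(1e5, vals[2], sds[2])
    expect_lt(abs(gauss - sd(draws)) / sd(draws), 0.05)

    # quotient structure, 15% relative
    valsq <- c(198, 13); sdsq <- c(198 * 0.15, 13 * 0.10)
    gq <- propagate_error(valsq, sdsq, structure = "quotient")
    dq <- rnorm(1e5, valsq[1], sdsq[1]) / rnorm(1e5, valsq[2], sdsq[2])
    expect_lt(abs(gq - sd(dq)) / sd(dq), 0.05)
  })
})

test_that("estimator SDs propagate community uncertainty", {
  sds <- c(canonical_products(NULL), carb_demand = 1.3, epsilon_tot = 2.9)
  cp <- reference_community(sds = sds)
  ef <- estimate_via_feces(reference_fecal(), cp)
  expect_equal(ef$fp_tot_sd, 16 * 2.9, tolerance = 1e-9)
  ec <- estimate_via_carbs(reference_mac(), cp)
  expect_equal(ec$fp_tot_sd / ec$fp_tot, sqrt(0.1^2 + 0.1^2),
               tolerance = 1e-9)
})

test_that("carbon ledger balances exactly and hits the >90% headline", {
  w <- default_world()
  mac <- reference_mac()
  est <- estimate_via_carbs(mac, w$community)
  flow <- carbon_flow(mac, est)
  n <- flow$nodes
  expect_equal(n[["fp_carbon_g"]],
               n[["absorbed_fp_carbon_g"]] + n[["fecal_fp_carbon_g"]],
               tolerance = 1e-12)
  expect_gt(flow$fractions[["fraction_to_fp"]], 0.90)

  zero <- carbon_flow(mac, estimate_via_carbs(mac_result(mac_g = 0),
                                              w$community))
  expect_equal(unname(zero$nodes[c("fp_carbon_g", "absorbed_fp_carbon_g")]),
               c(0, 0))
})

test_that("composition variation summarizes per-sample estimates", {
  w <- default_world()
  mac <- reference_mac()

  # identical samples: all CVs zero
  same <- abundance_table(w$abundances$taxa,
                          matrix(rep(w$abundances$abundances[, 1], 3),
                                 ncol = 3),
                          level = "genus")
  vs0 <- composition_variation(same, w$profiles, mac)
  expect_equal(vs0$cv_total, 0, tolerance = 1e-12)
  expect_true(all(vs0$cv_by_product < 1e-12))

  vs <- composition_variation(w$abundances, w$profiles, mac)
  # brute-force CV oracle on the totals
  totals <- vs$totals
  expect_equal(vs$cv_total, sd(totals) / mean(totals), tolerance = 1e-12)
  by_prod <- sapply(vs$per_sample, function(e) pmax(e$fp_by_product, 0))
  brute <- apply(by_prod, 1, function(x) sd(x) / mean(x))
  expect_equal(vs$cv_by_product, brute, tolerance = 1e-12)

  # total release varies less than the most variable single product
  expect_lt(vs$cv_total, max(vs$cv_by_product))

  one <- abundance_table(w$abundances$taxa,
                         w$abundances$abundances[, 1, drop = FALSE],
                         level = "genus")
  expect_error(composition_variation(one, w$profiles, mac),
               class = "gh_insufficient_data")
})

test_that("cohort estimates use the matching estimator and sorted percentiles", {
  cp <- reference_community()

  # single record: median equals that record's estimate
  solo <- cohort_apply(gen_diet_cohort("reference"), cp)
  est <- estimate_via_carbs(
    map_to_mac(gen_diet_cohort("reference")[[1]], scenario_params("medium")),
    cp)
  expect_equal(solo$percentiles[["50"]], est$fp_tot, tolerance = 1e-9)

  us <- cohort_apply(gen_diet_cohort("us", n = 41, seed = 23), cp)
  totals <- sort(us$totals)
  expect_equal(us$percentiles[["50"]], unname(totals[21]), tolerance = 1e-12)
  expect_true(all(diff(us$percentiles) >= 0))
  expect_gte(us$percentiles[["5"]], min(totals))
  expect_lte(us$percentiles[["95"]], max(totals))

  # US-style cohort sits below the British reference point estimate
  expect_lt(us$percentiles[["50"]], est$fp_tot)

  fecal <- lapply(gen_fecal_cohort("british", n = 10, seed = 23),
                  function(wt) bacterial_biomass(wt, "constant"))
  vf <- cohort_apply(fecal, cp)
  expect_equal(vf$per_sample[[1]]$method, "via_feces")

  expect_error(cohort_apply(c(gen_diet_cohort("reference"), fecal[1]), cp),
               class = "gh_type_error")
  expect_error(cohort_apply(list(), cp), class = "gh_domain_error")
})
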