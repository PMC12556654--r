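test_that("generators are pure functions of their seed", {
  a <- gen_growth_experiment(seed = 42, noise_sd = 0.05)
  b <- gen_growth_experiment(seed = 42, noise_sd = 0.05)
  expect_identical(a$samples, b$samples)
  expect_false(identical(
    a$samples, gen_growth_experiment(seed = 43, noise_sd = 0.05)$samples))

  expect_identical(gen_abundance_samples(n_samples = 5, seed = 7)$abundances,
                   gen_abundance_samples(n_samples = 5, seed = 7)$abundances)
  expect_identical(gen_fecal_cohort("global", n = 20, seed = 7),
                   gen_fecal_cohort("global", n = 20, seed = 7))
  expect_identical(purrr::map_dbl(gen_diet_cohort("us", 10, seed = 7),
                                  "fiber_g"),
                   purrr::map_dbl(gen_diet_cohort("us", 10, seed = 7),
                                  "fiber_g"))
})

test_that("noisy generate-and-refit recovers rates within 5% at 2% noise", {
  # noise_sd = 2% of the ~10 mM signal span, n = 6 samples
  errs <- purrr::map_dbl(1:8, function(s) {
    exp <- gen_growth_experiment(mu = 0.5, u = 13, e = c(acetate = 15),
                                 od_to_dw = 0.5, n_points = 6,
                                 noise_sd = 0.06, seed = s)
    prof <- compute_rate_profile(exp, od_to_dw = 0.5)
    abs(prof$u - 13) / 13
  })
  expect_lt(stats::median(errs), 0.05)
  expect_true(all(errs < 0.10))
})

test_that("strain archetypes satisfy their structural constraints", {
  profs <- gen_strain_archetypes(seed = 20250730)
  expect_length(profs, 20)
  for (p in profs) {
    expect_s3_class(p, "strain_rate_profile")
    expect_gte(p$u, 0)
    expect_true(all(p$e >= 0))
    cb <- carbon_balance(p)
    expect_gte(cb$ratio, 0.90); expect_lte(cb$ratio, 1.05)
    # uptake and excretion magnitudes around the community-typical values
    expect_gt(p$u_hexose, 13 * 0.5); expect_lt(p$u_hexose, 13 * 2)
  }
  # Bifidobacteriaceae ferment lactate:acetate at 3:2 molar
  bifs <- purrr::keep(profs, function(p) p$lineage[["family"]] ==
                        "Bifidobacteriaceae")
  for (p in bifs)
    expect_equal(p$e[["lactate"]] / p$e[["acetate"]], 1.5, tolerance = 1e-9)
  expect_error(gen_strain_archetypes(families = "Listeriaceae"),
               class = "gh_config_error")
})

test_that("abundance samples are simplex draws with tunable variability", {
  ab <- gen_abundance_samples(n_samples = 30, seed = 5)
  expect_equal(unname(colSums(ab$abundances)), rep(1, 30), tolerance = 1e-12)
  expect_true(all(ab$abundances >= 0))

  tight <- gen_abundance_samples(n_samples = 40, concentration = 500,
                                 seed = 5)
  loose <- gen_abundance_samples(n_samples = 40, concentration = 5, seed = 5)
  cv_row <- function(tb, g) {
    x <- tb$abundances[grep(paste0("g__", g, "$"), tb$taxa), ]
    sd(x) / mean(x)
  }
  expect_gt(cv_row(loose, "Bacteroides"), cv_row(tight, "Bacteroides"))
})

test_that("diet cohorts carry the intended population structure", {
  ref <- gen_diet_cohort("reference")[[1]]
  ref_mac <- map_to_mac(ref, scenario_params("medium"))$mac_g
  expect_lt(abs(ref_mac - 36), 2)

  us <- gen_diet_cohort("us", n = 150, seed = 20250730)
  us_mac <- purrr::map_dbl(us, function(d)
    map_to_mac(d, scenario_params("medium"))$mac_g)
  expect_lt(stats::median(us_mac), ref_mac)
  # right skew: mean above median
  expect_gt(mean(us_mac), stats::median(us_mac))

  hadza <- gen_diet_cohort("hadza_seasonal", seed = 20250730)
  expect_length(hadza, 12)
  hadza_mac <- purrr::map_dbl(hadza, function(d)
    map_to_mac(d, scenario_params("medium"))$mac_g)
  expect_gt(min(hadza_mac), ref_mac)  # year-round above the reference
  expect_gt(max(hadza_mac) - min(hadza_mac), 10)  # strong seasonal swing
})

test_that("fecal cohorts span the narrow-British to broad-global range", {
  brit <- gen_fecal_cohort("british", n = 219, seed = 20250730)
  glob <- gen_fecal_cohort("global", n = 219, seed = 20250730)
  expect_true(all(brit > 0) && all(glob > 0))
  expect_gte(max(glob) / mean(brit), 3)
  expect_lt(sd(brit) / mean(brit), sd(glob) / mean(glob))
})

test_that("full synthetic pipeline keeps the two estimators consistent", {
  w <- default_world()
  mac <- reference_mac()
  via_c <- estimate_via_carbs(mac, w$community)
  via_f <- estimate_via_feces(reference_fecal(), w$community)
  expect_lt(abs(via_c$fp_tot - via_f$fp_tot) / via_f$fp_tot, 0.20)
})
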