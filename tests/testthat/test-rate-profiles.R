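test_that("slope-to-rate conversion is plain unit arithmetic", {
  od <- c(0.05, 0.1, 0.2, 0.4)
  tb <- tibble::tibble(time_h = 0:3, od600 = od,
                       glucose = 10 - 6.5 * od, acetate = 14.5 * od)
  prof <- compute_rate_profile(growth_experiment("s", tb), od_to_dw = 0.5)
  expect_equal(prof$e[["acetate"]], 29.0, tolerance = 1e-9)
  expect_equal(prof$u, 13.0, tolerance = 1e-9)
  expect_equal(prof$u_hexose, 13.0)  # glucose: 1 hexose unit
  expect_error(compute_rate_profile(growth_experiment("s", tb),
                                    od_to_dw = 0), class = "gh_domain_error")
})

test_that("noiseless generate-and-refit recovers rates to 1e-9 relative", {
  e_true <- c(acetate = 15, propionate = 4, butyrate = 6)
  exp <- gen_growth_experiment(mu = 0.4, u = 13, e = e_true, od_to_dw = 0.5,
                               noise_sd = 0, seed = 3)
  prof <- compute_rate_profile(exp, od_to_dw = 0.5)
  expect_equal(prof$u, 13, tolerance = 1e-9)
  for (p in names(e_true))
    expect_equal(prof$e[[p]], e_true[[p]], tolerance = 1e-9)
  g <- fit_growth_rate(exp)
  expect_equal(g$mu, 0.4, tolerance = 1e-9)
})

test_that("replicate profiles average to the truth with replicate SDs", {
  reps <- lapply(1:3, function(i)
    gen_growth_experiment(mu = 0.4, u = 13, e = c(acetate = 15),
                          od_to_dw = 0.5, noise_sd = 0.05, seed = 11,
                          replicate_id = paste0("r", i)))
  prof <- compute_rate_profile(reps, od_to_dw = 0.5)
  expect_equal(prof$n_replicates, 3L)
  expect_lt(abs(prof$u - 13) / 13, 0.05)
  expect_lt(abs(prof$e[["acetate"]] - 15) / 15, 0.05)
  expect_gt(prof$sds[["acetate"]], 0)  # spread across replicates recorded
})

test_that("non-growing replicates are excluded from aggregation", {
  good <- gen_growth_experiment(mu = 0.4, u = 13, e = c(acetate = 15),
                                seed = 5, replicate_id = "r1")
  flat <- good
  flat$samples$od600 <- rep(0.05, nrow(flat$samples))
  flat$samples$time_h <- seq(0, 10, length.out = nrow(flat$samples))
  flat$replicate_id <- "r2"
  expect_message(prof <- compute_rate_profile(list(good, flat)),
                 "excluding replicate r2")
  expect_equal(prof$n_replicates, 1L)
})

test_that("maltose profiles obey the hexose doubling law", {
  exp <- gen_growth_experiment(u = 6.5, e = c(acetate = 15), sugar = "maltose",
                               seed = 9, noise_sd = 0)
  prof <- compute_rate_profile(exp)
  expect_equal(prof$u_hexose, 2 * prof$u, tolerance = 1e-12)
})

test_that("carbon balance counts carbon atoms correctly", {
  # 10 mmol glucose/g in (60 C); acetate 15*2 + butyrate 5*4 + formate 10*1
  prof <- strain_rate_profile("s", u = 10,
                              e = c(acetate = 15, butyrate = 5, formate = 10))
  cb <- carbon_balance(prof)
  expect_equal(cb$carbon_in, 60)
  expect_equal(cb$carbon_out, 60)
  expect_equal(cb$ratio, 1.0)
  expect_false(cb$flagged)

  # no excretion: ratio 0
  cb0 <- carbon_balance(strain_rate_profile("s", u = 10, e = NULL))
  expect_equal(cb0$ratio, 0)

  # apparent excess carbon flags utilization of other media components
  rich <- strain_rate_profile("s", u = 5, e = c(acetate = 40, butyrate = 10))
  expect_true(carbon_balance(rich)$flagged)

  expect_error(carbon_balance(strain_rate_profile("s", u = 0, e = NULL)),
               class = "gh_domain_error")
})

test_that("pH sensitivity reports slopes and the 6-to-7 relative change", {
  mk <- function(ph, eps) {
    p <- strain_rate_profile("s", u = 10, e = c(acetate = eps))
    p$ph <- ph
    p
  }
  # exactly linear: slope 2 mmol/g per pH unit, value 20 at pH 7
  profs <- lapply(c(5.5, 6, 6.5, 7), function(ph) mk(ph, 20 + 2 * (ph - 7)))
  ps <- ph_sensitivity(profs)
  ac <- ps[ps$quantity == "acetate", ]
  expect_equal(ac$slope_per_ph_unit, 2, tolerance = 1e-9)
  expect_equal(ac$relative_change_6_to_7, 0.10, tolerance = 1e-9)

  # pH-invariant rates
  flat <- ph_sensitivity(lapply(c(6, 6.5, 7), function(ph) mk(ph, 20)))
  expect_equal(flat$slope_per_ph_unit[flat$quantity == "acetate"], 0,
               tolerance = 1e-9)
  expect_equal(flat$relative_change_6_to_7[flat$quantity == "acetate"], 0,
               tolerance = 1e-9)

  expect_error(ph_sensitivity(lapply(c(6, 7), function(ph) mk(ph, 20))),
               class = "gh_insufficient_data")
})

test_that("noisy pH slopes are recovered within 2 standard errors", {
  withr::with_seed(13, {
    phs <- c(5.5, 6.17, 6.83, 7.5)
    profs <- lapply(phs, function(ph) {
      p <- strain_rate_profile("s", u = 10,
                               e = c(acetate = 10 + 1.5 * ph + rnorm(1, 0, 0.4)))
      p$ph <- ph
      p
    })
    ps <- ph_sensitivity(profs)
    ac <- ps[ps$quantity == "acetate", ]
    expect_lt(abs(ac$slope_per_ph_unit - 1.5), 2 * ac$slope_sd)
  })
})

test_that("rate profiles survive a CSV round trip", {
  profs <- gen_strain_archetypes(n_per_family = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_profiles_csv(profs, path)
  back <- read_rate_profiles_csv(path)
  expect_length(back, length(profs))
  expect_equal(back[[1]]$u, profs[[1]]$u, tolerance = 1e-9)
  expect_equal(back[[1]]$e, profs[[1]]$e, tolerance = 1e-9)
  expect_equal(back[[1]]$lineage[["genus"]], profs[[1]]$lineage[["genus"]])
})

test_that("long-format growth CSVs are parsed into experiments", {
  exp <- gen_growth_experiment(seed = 21, noise_sd = 0)
  long <- tidyr::pivot_longer(
    dplyr::mutate(exp$samples, strain_id = "sA", replicate_id = "r1",
                  medium = "YCA", ph = 7),
    cols = -c("time_h", "od600", "strain_id", "replicate_id", "medium", "ph"),
    names_to = "metabolite", values_to = "concentration_mM")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(long, path)
  exps <- read_growth_csv(path)
  expect_length(exps, 1)
  expect_equal(exps[[1]]$samples$od600, exp$samples$od600)
})
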