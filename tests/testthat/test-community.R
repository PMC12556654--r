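lin <- function(p, f, g) sprintf("k__Bacteria|p__%s|f__%s|g__%s", p, f, g)

test_that("aggregation sums within groups and preserves per-sample totals", {
  taxa <- c(paste0(lin("Bacteroidota", "Bacteroidaceae", "Bacteroides"),
                   "|s__sp1"),
            paste0(lin("Bacteroidota", "Bacteroidaceae", "Bacteroides"),
                   "|s__sp2"),
            paste0(lin("Bacillota", "Lachnospiraceae", "Blautia"), "|s__sp3"))
  tb <- abundance_table(taxa, matrix(c(0.2, 0.3, 0.5), ncol = 1),
                        level = "species")
  genus <- aggregate_abundance(tb, "genus")
  bact <- genus$abundances[grep("Bacteroides", genus$taxa), 1]
  expect_equal(unname(bact), 0.5, tolerance = 1e-12)

  # identity at own level; finer target rejected
  expect_identical(aggregate_abundance(tb, "species"), tb)
  g2 <- aggregate_abundance(tb, "genus")
  expect_error(aggregate_abundance(g2, "species"), class = "gh_rank_error")
})

test_that("aggregation conserves totals on random tables", {
  ab <- gen_abundance_samples(n_samples = 8, n_genera = 50, seed = 2)
  fam <- aggregate_abundance(ab, "family")
  expect_equal(colSums(fam$abundances), colSums(ab$abundances),
               tolerance = 1e-12)
  phy <- aggregate_abundance(ab, "phylum")
  expect_equal(unname(colSums(phy$abundances)), rep(1, 8), tolerance = 1e-12)
})

test_that("coverage is the represented share of biomass", {
  tb <- abundance_table(c("A", "B", "C"),
                        matrix(c(0.6, 0.3, 0.1), ncol = 1), level = "genus")
  expect_equal(coverage(tb, c("A", "B"))$mean, 0.9, tolerance = 1e-12)
  expect_equal(coverage(tb, c("A", "B", "C"))$mean, 1.0, tolerance = 1e-12)
  expect_warning(cv0 <- coverage(tb, "Z"), "no represented taxa")
  expect_equal(cv0$mean, 0)
})

test_that("coverage equals brute-force per-sample sums on a Dirichlet fixture", {
  ab <- gen_abundance_samples(n_samples = 40, n_genera = 60, seed = 6)
  represented <- lineage_at_genus <- c("Bacteroides", "Blautia",
                                       "Faecalibacterium", "Bifidobacterium",
                                       "Escherichia")
  cov <- coverage(ab, represented)
  # brute force: locate rows by string matching, sum each column
  rows <- vapply(represented, function(g) grep(paste0("g__", g, "$"), ab$taxa),
                 integer(1))
  brute <- colSums(ab$abundances[rows, , drop = FALSE])
  expect_equal(unname(cov$per_sample), unname(brute), tolerance = 1e-12)
  expect_equal(cov$mean, mean(brute), tolerance = 1e-12)
})

test_that("weighting with a single represented genus returns that strain's profile", {
  prof <- strain_rate_profile("s", u = 12, e = c(acetate = 20, butyrate = 9),
                              lineage = c(genus = "Bacteroides"))
  ab <- c(Bacteroides = 0.4, Unknown = 0.6)
  cp <- weight_profiles(list(prof), ab)
  expect_equal(cp$e_w[["acetate"]], 20, tolerance = 1e-12)
  expect_equal(cp$e_w[["butyrate"]], 9, tolerance = 1e-12)
  expect_equal(cp$carb_demand, 12, tolerance = 1e-12)
  expect_equal(cp$coverage, 0.4, tolerance = 1e-12)
})

test_that("weighted community rates are the abundance-weighted strain means", {
  profs <- purrr::map2(
    c("G1", "G2", "G3"), c(20, 30, 40),
    function(g, eps) strain_rate_profile(g, u = 10, e = c(acetate = eps),
                                         lineage = c(genus = g)))
  cp <- weight_profiles(profs, c(G1 = 0.5, G2 = 0.3, G3 = 0.2))
  expect_equal(cp$epsilon_tot, 27, tolerance = 1e-12)  # hand-computed

  # convexity: weighted rate inside [min, max] of strain rates
  expect_gte(cp$epsilon_tot, 20)
  expect_lte(cp$epsilon_tot, 40)

  expect_error(weight_profiles(profs, c(Zz = 1)),
               class = "gh_no_representation")
})

test_that("renormalization is idempotent and convexity holds on the fixture", {
  w <- default_world()
  cp1 <- w$community
  # weighting with the already-renormalized represented abundances
  labels <- lineage_at(names(w$mean_ab), "genus")
  rep_idx <- labels %in% c("Bacteroides", "Blautia", "Faecalibacterium",
                           "Bifidobacterium", "Escherichia")
  a2 <- w$mean_ab[rep_idx] / sum(w$mean_ab[rep_idx])
  cp2 <- weight_profiles(w$profiles, a2)
  expect_equal(cp2$epsilon_tot, cp1$epsilon_tot, tolerance = 1e-12)
  expect_equal(cp2$e_w, cp1$e_w, tolerance = 1e-12)

  totals <- purrr::map_dbl(w$profiles, function(p) sum(pmax(p$e, 0)))
  expect_gte(cp1$epsilon_tot, min(totals))
  expect_lte(cp1$epsilon_tot, max(totals))
})

test_that("the default synthetic community reproduces the reference constants", {
  cp <- default_world()$community
  expect_lt(abs(cp$epsilon_tot - 29) / 29, 0.10)
  expect_lt(abs(cp$carb_demand - 13) / 13, 0.10)
  expect_gt(cp$coverage, 0.8)
})

test_that("coverage-discount mode scales fluxes by coverage", {
  w <- default_world()
  full <- w$community
  disc <- weight_profiles(w$profiles, w$mean_ab, mode = "coverage_discount")
  expect_equal(disc$epsilon_tot, full$epsilon_tot * full$coverage,
               tolerance = 1e-9)
})

test_that("abundance TSVs round-trip and percentages are auto-detected", {
  ab <- gen_abundance_samples(n_samples = 5, n_genera = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_tsv(ab, path)
  back <- read_abundance_tsv(path)
  expect_equal(back$abundances, ab$abundances, tolerance = 1e-12)

  # percentage-scaled file
  pct <- tibble::as_tibble(ab$abundances * 100)
  pct <- dplyr::bind_cols(tibble::tibble(clade_name = ab$taxa), pct)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(pct, path2)
  expect_message(back2 <- read_abundance_tsv(path2), "percentages")
  expect_equal(back2$abundances, ab$abundances, tolerance = 1e-9)
})

test_that("malformed abundance inputs are rejected", {
  expect_error(abundance_table("A", matrix(-0.1), level = "genus"),
               class = "gh_domain_error")
  expect_error(abundance_table(c("A", "B"), matrix(c(0.4, 0.4), ncol = 1)),
               class = "gh_domain_error")  # sum 0.8 < tolerance
  expect_error(abundance_table("A", matrix(1), level = "subclade"),
               class = "gh_rank_error")
})
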