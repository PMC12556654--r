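#' Simulate a batch-culture growth experiment
#'
#' Emulates the measurement structure of the rate-extraction workflow:
#' OD600 grows exponentially at rate `mu` between `od_range`, and each
#' metabolite concentration changes linearly with OD at a slope fixed by its
#' per-biomass rate times the OD-to-dry-weight conversion, plus Gaussian
#' measurement noise. The sugar decreases (net uptake); products increase.
#'
#' @param mu Growth rate, 1/h (> 0).
#' @param u Sugar uptake rate, mmol/g dry biomass.
#' @param e Named excretion rates, mmol/g (negative allowed for acetate).
#' @param od_to_dw Dry-weight conversion, g/L per OD600.
#' @param n_points Number of samples (>= 4; experiments take 4-6).
#' @param noise_sd Gaussian SD added to every concentration, mM (>= 0).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param sugar `"glucose"` or `"maltose"`.
#' @param sugar_start Initial sugar concentration, mM.
#' @param od_range OD600 window covered by the sampling.
#' @param strain_id,medium,ph,replicate_id Metadata for the experiment.
#' @return A [growth_experiment()].
#' @export
gen_growth_experiment <- function(mu = 0.5, u = 13,
                                  e = c(acetate = 15, butyrate = 5),
                                  od_to_dw = 0.5, n_points = 6,
                                  noise_sd = 0, seed = 20250730,
                                  sugar = "glucose", sugar_start = 20,
                                  od_range = c(0.04, 0.5),
                                  strain_id = "sim_strain", medium = "YCA",
                                  ph = NA_real_, replicate_id = "r1") {
  abort_if(mu <= 0, "mu must be positive", "gh_domain_error")
  abort_if(n_points < 4, "need at least 4 sample points", "gh_domain_error")
  abort_if(noise_sd < 0, "noise_sd must be non-negative", "gh_domain_error")
  sugar <- match.arg(sugar, .sugars)
  e <- canonical_products(e)
  with_stream(seed, paste0("growth_", replicate_id), {
    od <- exp(seq(log(od_range[1]), log(od_range[2]), length.out = n_points))
    time_h <- log(od / od[1]) / mu
    samples <- tibble::tibble(time_h = time_h, od600 = od)
    # concentration slope (mM per OD) = rate (mmol/g) * od_to_dw (g/L per OD)
    samples[[sugar]] <- pmax(
      sugar_start - u * od_to_dw * (od - od[1]) +
        stats::rnorm(n_points, 0, noise_sd), 0)
    for (p in names(e)) {
      base <- if (p == "acetate" && e[[p]] < 0) 10 else 0  # medium acetate
      samples[[p]] <- pmax(
        base + e[[p]] * od_to_dw * (od - od[1]) +
          stats::rnorm(n_points, 0, noise_sd), 0)
    }
    growth_experiment(strain_id, samples, medium = medium, ph = ph,
                      replicate_id = replicate_id, sugar = sugar)
  })
}

# family archetypes: molar product split and taxonomy of the representative
# genus; splits reflect the canonical fermentation modes of each clade
.family_archetypes <- list(
  Bacteroidaceae = list(
    genus = "Bacteroides", phylum = "Bacteroidota",
    split = c(acetate = 0.45, propionate = 0.30, succinate = 0.25)),
  Lachnospiraceae = list(
    genus = "Blautia", phylum = "Bacillota",
    split = c(acetate = 0.50, butyrate = 0.35, formate = 0.15)),
  Bifidobacteriaceae = list(
    genus = "Bifidobacterium", phylum = "Actinomycetota",
    split = c(lactate = 0.60, acetate = 0.40)),  # 3:2 molar
  Enterobacteriaceae = list(
    genus = "Escherichia", phylum = "Pseudomonadota",
    split = c(acetate = 0.35, lactate = 0.20, formate = 0.30,
              succinate = 0.15)),
  Ruminococcaceae = list(
    genus = "Faecalibacterium", phylum = "Bacillota",
    split = c(acetate = 0.40, butyrate = 0.35, formate = 0.25))
)

#' Simulate strain rate profiles for the major gut families
#'
#' Draws per-strain profiles around the community-typical magnitudes — a
#' hexose demand of ~13 mmol/g dry biomass and a total excretion of
#' ~29 mmol/g, each varying about +/-30% between strains — while
#' constraining every strain's carbon balance (excreted product carbon over
#' sugar carbon taken up) to `balance_range`, mirroring the near-unity
#' balances of fermentative metabolism. The product split follows the
#' family archetype: Bacteroidaceae acetate/propionate/succinate,
#' Lachnospiraceae butyrate/acetate, Bifidobacteriaceae lactate/acetate at
#' 3:2, Enterobacteriaceae mixed-acid, Ruminococcaceae butyrate/acetate/
#' formate.
#'
#' @param n_per_family Strains per family (default 4, giving 20 strains
#'   across the five families).
#' @param seed Integer seed.
#' @param u_hexose_mean Mean hexose uptake, mmol/g.
#' @param cv Between-strain coefficient of variation of uptake (default 0.3,
#'   truncated at +/- 2 CV).
#' @param balance_range Carbon-balance interval the draws are confined to.
#' @param families Families to include (subset of the five archetypes).
#' @param rate_sd_frac Within-strain replicate SD recorded on each rate, as
#'   a fraction of the rate.
#' @return List of [strain_rate_profile()] objects.
#' @export
gen_strain_archetypes <- function(n_per_family = 4, seed = 20250730,
                                  u_hexose_mean = 13, cv = 0.3,
                                  balance_range = c(0.90, 1.05),
                                  families = names(.family_archetypes),
                                  rate_sd_frac = 0.1) {
  unknown <- setdiff(families, names(.family_archetypes))
  abort_if(length(unknown) > 0,
           paste("unknown families:", paste(unknown, collapse = ", ")),
           "gh_config_error")
  with_stream(seed, "strain_archetypes", {
    purrr::flatten(purrr::map(families, function(fam) {
      arch <- .family_archetypes[[fam]]
      purrr::map(seq_len(n_per_family), function(i) {
        # truncated lognormal-ish variation around the community mean
        f <- exp(pmin(pmax(stats::rnorm(1, 0, cv), -2 * cv), 2 * cv))
        u_hex <- u_hexose_mean * f
        ratio <- stats::runif(1, balance_range[1], balance_range[2])
        carbon_out <- ratio * 6 * u_hex  # mmol C/g excreted as products
        split <- canonical_products(arch$split)
        mean_c <- sum(split * carbon_atoms_default[names(split)])
        eps <- carbon_out / mean_c       # total mmol products/g
        e <- split * eps
        sds <- c(u = u_hex * rate_sd_frac,
                 canonical_products(e * rate_sd_frac))
        strain_rate_profile(
          strain_id = sprintf("%s_sp%02d", arch$genus, i),
          u = u_hex, e = e, sugar = "glucose",
          lineage = c(phylum = arch$phylum, family = fam,
                      genus = arch$genus,
                      species = sprintf("%s_sp%02d", arch$genus, i)),
          medium = "YCA", sds = sds, n_replicates = 3L
        )
      })
    }))
  })
}

# base measure over genera for the Dirichlet composition generator: the five
# characterized genera dominate, a tail of uncharacterized genera follows
.default_genus_weights <- function(n_genera) {
  core <- c(Bacteroides = 0.30, Blautia = 0.25, Faecalibacterium = 0.20,
            Bifidobacterium = 0.10, Escherichia = 0.05)
  n_other <- max(n_genera - length(core), 0)
  other <- 0.10 * (seq_len(n_other)^-1.2)
  other <- other / sum(other) * 0.10
  names(other) <- sprintf("OtherGenus%02d", seq_len(n_other))
  c(core, other)
}

.genus_lineage <- function(genus) {
  phyla <- c(Bacteroides = "Bacteroidota", Blautia = "Bacillota",
             Faecalibacterium = "Bacillota", Bifidobacterium = "Actinomycetota",
             Escherichia = "Pseudomonadota")
  fams <- c(Bacteroides = "Bacteroidaceae", Blautia = "Lachnospiraceae",
            Faecalibacterium = "Ruminococcaceae",
            Bifidobacterium = "Bifidobacteriaceae",
            Escherichia = "Enterobacteriaceae")
  p <- ifelse(genus %in% names(phyla), phyla[genus], "Bacillota")
  f <- ifelse(genus %in% names(fams), fams[genus],
              paste0(genus, "_fam"))
  sprintf("k__Bacteria|p__%s|f__%s|g__%s", p, f, genus)
}

#' Simulate a cohort of microbiome composition samples
#'
#' Dirichlet draws over genera with an uneven base measure (a few dominant
#' characterized genera plus a power-law tail of others), emulating the
#' compositional variation of healthy-adult fecal metagenomes. Lower
#' `concentration` gives stronger between-sample variation.
#'
#' @param n_samples Number of samples (cohort default 219).
#' @param n_genera Number of genera (default 60).
#' @param concentration Dirichlet concentration parameter (> 0; the base
#'   measure is multiplied by this).
#' @param seed Integer seed.
#' @return An [abundance_table()] at genus level with lineage-string rows.
#' @export
gen_abundance_samples <- function(n_samples = 219, n_genera = 60,
                                  concentration = 50, seed = 20250730) {
  abort_if(concentration <= 0, "concentration must be positive",
           "gh_config_error")
  w <- .default_genus_weights(n_genera)
  alpha <- w * concentration
  with_stream(seed, "abundance_samples", {
    draws <- matrix(stats::rgamma(n_samples * length(alpha),
                                  shape = rep(alpha, n_samples)),
                    nrow = length(alpha))
    draws <- sweep(draws, 2, colSums(draws), "/")
    colnames(draws) <- sprintf("sample_%03d", seq_len(n_samples))
    abundance_table(.genus_lineage(names(w)), draws, level = "genus")
  })
}

#' Simulate diet cohorts
#'
#' Three cohort kinds with the statistical structure the framework assumes:
#' * `"reference"`: a single 1970s-British-style record (fiber 32 g/day,
#'   starch 155 g/day, sugar 100 g/day, protein 80 g/day) whose
#'   medium-scenario MAC is ~36 g/day;
#' * `"us"`: right-skewed lognormal fiber/starch intakes with medians below
#'   the reference (median fiber ~15 g/day, starch ~120 g/day);
#' * `"hadza_seasonal"`: 12 monthly records with a sinusoidal carbohydrate
#'   cycle well above the reference (fiber 80-150 g/day), emulating strong
#'   wet/dry-season alternation.
#'
#' @param kind `"reference"`, `"us"` or `"hadza_seasonal"`.
#' @param n Number of records (`us` only; the others have fixed sizes).
#' @param seed Integer seed.
#' @return List of [diet_record()] objects.
#' @export
gen_diet_cohort <- function(kind = c("reference", "us", "hadza_seasonal"),
                            n = 219, seed = 20250730) {
  kind <- match.arg(kind)
  if (kind == "reference") {
    return(list(diet_record(fiber_g = 32, starch_g = 155, sugar_g = 100,
                            protein_g = 80, id = "british_reference")))
  }
  with_stream(seed, paste0("diet_", kind), {
    if (kind == "us") {
      fiber <- stats::rlnorm(n, log(15), 0.45)
      starch <- stats::rlnorm(n, log(120), 0.35)
      sugar <- stats::rlnorm(n, log(110), 0.35)
      protein <- stats::rlnorm(n, log(85), 0.25)
      purrr::map(seq_len(n), function(i)
        diet_record(fiber[i], starch[i], sugar[i], protein[i],
                    id = sprintf("us_%03d", i)))
    } else {
      month <- 1:12
      season <- sin(2 * pi * (month - 3) / 12)
      fiber <- 115 + 35 * season + stats::rnorm(12, 0, 8)
      starch <- 180 + 40 * season + stats::rnorm(12, 0, 10)
      sugar <- pmax(60 + 30 * season + stats::rnorm(12, 0, 8), 5)
      purrr::map(month, function(m)
        diet_record(pmax(fiber[m], 20), pmax(starch[m], 40), sugar[m],
                    protein_g = 90, id = sprintf("month_%02d", m)))
    }
  })
}

#' Simulate fecal wet-weight cohorts
#'
#' `"british"` draws the narrow 1970s UK distribution (normal around
#' 110 g/day, SD 25, truncated at 40 g/day); `"global"` draws a broad
#' right-skewed lognormal (median ~150 g/day) whose upper tail reaches
#' several times the British mean, emulating the span from Western to
#' high-fiber non-Western populations.
#'
#' @param kind `"british"` or `"global"`.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Numeric vector of wet weights, g/day.
#' @export
gen_fecal_cohort <- function(kind = c("british", "global"), n = 219,
                             seed = 20250730) {
  kind <- match.arg(kind)
  with_stream(seed, paste0("fecal_", kind), {
    if (kind == "british") {
      pmax(stats::rnorm(n, 110, 25), 40)
    } else {
      pmin(pmax(stats::rlnorm(n, log(150), 0.6), 30), 600)
    }
  })
}
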