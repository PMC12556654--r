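#' Construct a growth experiment
#'
#' Bundles the time series of one batch-culture replicate: optical density
#' (OD600) and metabolite concentrations sampled during exponential growth.
#' Samples are stored as a tibble with one row per time point and one column
#' per measured metabolite (mM).
#'
#' @param strain_id Strain identifier.
#' @param samples Data frame with columns `time_h`, `od600`, and one numeric
#'   column per metabolite (concentrations in mM).
#' @param medium Growth medium label (e.g. `"YCA"`, `"BHIS"`).
#' @param ph Culture pH, or `NA` if not controlled.
#' @param replicate_id Biological replicate identifier.
#' @param sugar Carbon source, `"glucose"` or `"maltose"`.
#' @return An object of class `growth_experiment`.
#' @examples
#' tb <- tibble::tibble(time_h = 0:5, od600 = 0.04 * 2^(0:5),
#'                      glucose = 20 - 8 * 0.04 * 2^(0:5))
#' growth_experiment("B_theta", tb, sugar = "glucose")
#' @export
growth_experiment <- function(strain_id, samples, medium = "YCA", ph = NA_real_,
                              replicate_id = "r1", sugar = "glucose") {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("time_h", "od600") %in% names(samples)))
  abort_if(any(diff(samples$time_h) <= 0),
           "sample times must be strictly increasing", "gh_domain_error")
  abort_if(any(samples$od600 <= 0),
           "all od600 values must be positive", "gh_domain_error")
  metab <- setdiff(names(samples), c("time_h", "od600"))
  conc <- as.matrix(samples[metab])
  abort_if(length(metab) > 0 && any(conc < 0, na.rm = TRUE),
           "concentrations must be non-negative", "gh_domain_error")
  sugar <- match.arg(sugar, .sugars)
  structure(
    list(strain_id = strain_id, medium = medium, ph = ph,
         replicate_id = replicate_id, sugar = sugar, samples = samples),
    class = "growth_experiment"
  )
}

#' @export
print.growth_experiment <- function(x, ...) {
  cat(sprintf("<growth_experiment> %s [%s, rep %s, pH %s], %d samples\n",
              x$strain_id, x$medium, x$replicate_id,
              ifelse(is.na(x$ph), "n/a", format(x$ph)), nrow(x$samples)))
  invisible(x)
}

# summary.lm warns on noiseless (zero-residual) fits; those are routine for
# synthetic round-trip data, so muffle just that warning
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# restrict an experiment to the OD window of steady exponential growth
window_samples <- function(exp, od_window) {
  keep <- exp$samples$od600 >= od_window[1] & exp$samples$od600 <= od_window[2]
  exp$samples[keep, , drop = FALSE]
}

#' Fit the exponential growth rate from OD600 data
#'
#' The growth rate is the slope of an ordinary least squares regression of
#' log-transformed OD600 against time; its standard error is the standard
#' error of that slope.
#'
#' @param exp A [growth_experiment()].
#' @param od_window Numeric length-2; only samples with OD600 inside this
#'   window are used (steady exponential growth). Default `c(0.04, 0.5)`.
#' @return A list with `mu` (1/h), `mu_sd`, `r_squared`, `n`, and `growing`
#'   (`FALSE` when the fitted slope is not positive).
#' @examples
#' tb <- tibble::tibble(time_h = 0:5, od600 = 0.04 * 2^(0:5))
#' fit_growth_rate(growth_experiment("s", tb))$mu # log(2)
#' @export
fit_growth_rate <- function(exp, od_window = c(0.04, 0.5)) {
  stopifnot(inherits(exp, "growth_experiment"))
  s <- window_samples(exp, od_window)
  abort_if(nrow(s) < 3, "need at least 3 OD points inside the OD window",
           "gh_insufficient_data")
  fit <- stats::lm(log(od600) ~ time_h, data = s)
  sm <- quiet_summary(fit)
  mu <- unname(stats::coef(fit)[["time_h"]])
  list(
    mu = mu,
    mu_sd = unname(sm$coefficients["time_h", "Std. Error"]),
    r_squared = sm$r.squared,
    n = nrow(s),
    growing = mu > 1e-9
  )
}

#' Fit concentration-versus-OD slopes for all metabolites
#'
#' During steady exponential growth each metabolite concentration changes
#' linearly with biomass, so the OLS slope of concentration (mM) against
#' OD600 captures the per-biomass exchange rate up to the OD-to-dry-weight
#' conversion. Negative slopes indicate net uptake, positive net excretion.
#'
#' @inheritParams fit_growth_rate
#' @return Tibble with columns `metabolite`, `slope` (mM per OD unit),
#'   `slope_sd`, `n`.
#' @export
fit_concentration_slopes <- function(exp, od_window = c(0.04, 0.5)) {
  stopifnot(inherits(exp, "growth_experiment"))
  s <- window_samples(exp, od_window)
  metab <- setdiff(names(s), c("time_h", "od600"))
  abort_if(length(metab) == 0, "experiment has no metabolite columns",
           "gh_domain_error")
  abort_if(nrow(s) < 3, "need at least 3 paired (OD, concentration) points",
           "gh_insufficient_data")
  abort_if(stats::sd(s$od600) == 0,
           "all OD values identical: slope vs OD is undefined",
           "gh_degenerate_design")
  purrr::map_dfr(metab, function(m) {
    fit <- stats::lm(stats::reformulate("od600", m), data = s)
    sm <- quiet_summary(fit)
    tibble::tibble(
      metabolite = m,
      slope = unname(stats::coef(fit)[["od600"]]),
      slope_sd = unname(sm$coefficients["od600", "Std. Error"]),
      n = nrow(s)
    )
  })
}
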