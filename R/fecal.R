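#' Default dry-fraction model coefficients
#'
#' Three empirical models for the fecal dry-mass fraction `alpha_dw` as a
#' function of daily fecal wet weight M (g/day):
#' * `constant`: a fixed fraction (default 30/110, reproducing ~30 g dry
#'   weight at the ~110 g/day British reference wet weight);
#' * `linear`: `alpha_dw = 1 - (a + b * M)`, dry fraction decreasing
#'   linearly with wet weight;
#' * `nonlinear`: `alpha_dw = 1 - (a + b * sqrt(M) - c * M)`, decreasing
#'   steeply at low wet weight and flattening at high wet weight (an upper
#'   bound on dry mass at high outputs).
#'
#' Coefficients are empirical fits valid on roughly 20-600 g/day; outside
#' the clamp bounds the evaluated fraction is clipped with a warning.
#'
#' @param model `"constant"`, `"linear"` or `"nonlinear"`.
#' @return Named numeric coefficient vector.
#' @export
dry_fraction_coefficients <- function(model = c("nonlinear", "linear",
                                                "constant")) {
  model <- match.arg(model)
  switch(model,
    constant  = c(fraction = 30 / 110),
    linear    = c(a = 0.69, b = 4.63e-4),
    nonlinear = c(a = 0.49, b = 0.03, c = 7e-4)
  )
}

#' Fecal dry-mass fraction
#'
#' Evaluates the chosen water-content model at a daily fecal wet weight.
#' Results are clamped to `clamp` (default [0.05, 0.6]) with a warning,
#' since the models are empirical fits that must not be extrapolated to
#' unphysical fractions.
#'
#' @param wet_g Fecal wet weight, g/day (> 0). Vectorized.
#' @param model `"constant"`, `"linear"` or `"nonlinear"`.
#' @param coefficients Optional coefficient override (see
#'   [dry_fraction_coefficients()]).
#' @param clamp Numeric length-2 bounds on the returned fraction.
#' @return Dry-mass fraction(s) in (0, 1).
#' @examples
#' dry_fraction(110, "constant")          # ~0.273
#' dry_fraction(c(100, 400), "nonlinear") # decreasing
#' @export
dry_fraction <- function(wet_g, model = c("nonlinear", "linear", "constant"),
                         coefficients = NULL, clamp = c(0.05, 0.6)) {
  model <- match.arg(model)
  abort_if(any(wet_g <= 0), "wet_g must be positive", "gh_domain_error")
  k <- coefficients %||% dry_fraction_coefficients(model)
  alpha <- switch(model,
    constant  = rep(k[["fraction"]], length(wet_g)),
    linear    = 1 - (k[["a"]] + k[["b"]] * wet_g),
    nonlinear = 1 - (k[["a"]] + k[["b"]] * sqrt(wet_g) - k[["c"]] * wet_g)
  )
  if (any(alpha < clamp[1] | alpha > clamp[2])) {
    warning(sprintf("dry fraction outside [%.2f, %.2f] for some wet weights; clamped",
                    clamp[1], clamp[2]))
    alpha <- pmin(pmax(alpha, clamp[1]), clamp[2])
  }
  alpha
}

#' Fecal bacterial biomass from wet weight
#'
#' Chains the dry-fraction model with a constant bacterial fraction of dry
#' weight: `dry = alpha_dw * wet`, `bacterial = alpha_bac * dry`. The
#' bacterial fraction defaults to 16/30 (16 g bacterial biomass in ~30 g
#' dry weight for the British reference) and is kept constant across fecal
#' mass for lack of data resolving its variation.
#'
#' @inheritParams dry_fraction
#' @param alpha_bac Bacterial fraction of dry weight, in [0, 1].
#' @param transit_k Optional transit constant passed to [transit_time()]
#'   (g·h); when given, the transit time is included in the output.
#' @return Object of class `fecal_output` with fields `wet_g`, `dry_g`,
#'   `alpha_dw`, `alpha_bac`, `bacterial_g`, `model`, `transit_h`.
#' @examples
#' bacterial_biomass(110, model = "constant")$bacterial_g # ~16 g/day
#' @export
bacterial_biomass <- function(wet_g, model = c("nonlinear", "linear",
                                               "constant"),
                              alpha_bac = 16 / 30, coefficients = NULL,
                              clamp = c(0.05, 0.6), transit_k = NULL) {
  model <- match.arg(model)
  abort_if(alpha_bac < 0 || alpha_bac > 1, "alpha_bac must be in [0, 1]",
           "gh_domain_error")
  alpha_dw <- dry_fraction(wet_g, model, coefficients, clamp)
  dry_g <- alpha_dw * wet_g
  structure(list(wet_g = wet_g, dry_g = dry_g, alpha_dw = alpha_dw,
                 alpha_bac = alpha_bac, bacterial_g = alpha_bac * dry_g,
                 model = model,
                 transit_h = if (!is.null(transit_k))
                   transit_time(wet_g, transit_k) else NA_real_),
            class = "fecal_output")
}

#' Construct a fecal output record directly
#'
#' For workflows that start from known dry or bacterial masses.
#'
#' @param wet_g Wet weight, g/day.
#' @param dry_g Dry weight, g/day (defaults to `alpha_dw * wet_g`).
#' @param alpha_dw Dry fraction (defaults to `dry_g / wet_g`).
#' @param alpha_bac Bacterial fraction of dry weight.
#' @param model Label recording how the record was obtained.
#' @return Object of class `fecal_output`.
#' @export
fecal_output <- function(wet_g, dry_g = NULL, alpha_dw = NULL,
                         alpha_bac = 16 / 30, model = "direct") {
  abort_if(is.null(dry_g) && is.null(alpha_dw),
           "give dry_g or alpha_dw", "gh_domain_error")
  if (is.null(dry_g)) dry_g <- alpha_dw * wet_g
  if (is.null(alpha_dw)) alpha_dw <- dry_g / wet_g
  abort_if(any(alpha_dw <= 0 | alpha_dw >= 1), "alpha_dw must be in (0, 1)",
           "gh_domain_error")
  abort_if(alpha_bac < 0 || alpha_bac > 1, "alpha_bac must be in [0, 1]",
           "gh_domain_error")
  structure(list(wet_g = wet_g, dry_g = dry_g, alpha_dw = alpha_dw,
                 alpha_bac = alpha_bac, bacterial_g = alpha_bac * dry_g,
                 model = model, transit_h = NA_real_),
            class = "fecal_output")
}

#' @export
print.fecal_output <- function(x, ...) {
  cat(sprintf("<fecal_output> wet %.1f g/day -> dry %.1f g/day (alpha_dw %.3f, %s) -> bacterial %.1f g/day (alpha_bac %.3f)\n",
              x$wet_g[1], x$dry_g[1], x$alpha_dw[1], x$model,
              x$bacterial_g[1], x$alpha_bac))
  invisible(x)
}

#' Whole-gut transit time from fecal wet weight
#'
#' Transit time is inversely proportional to fecal wet weight:
#' `tau = k / wet_g`.
#'
#' @param wet_g Fecal wet weight, g/day (> 0). Vectorized.
#' @param k Proportionality constant, g·h (default 6000, giving ~55 h at
#'   the ~110 g/day reference output).
#' @return Transit time(s), hours.
#' @export
transit_time <- function(wet_g, k = 6000) {
  abort_if(any(wet_g <= 0), "wet_g must be positive", "gh_domain_error")
  abort_if(k <= 0, "k must be positive", "gh_domain_error")
  k / wet_g
}

#' Refit dry-fraction model coefficients from paired wet/dry data
#'
#' Both the linear and the non-linear water-content models are linear in
#' their coefficients once `alpha_dw = dry/wet` is formed, so ordinary least
#' squares recovers them from any paired (wet, dry) table.
#'
#' @param wet_g,dry_g Paired observations, g/day.
#' @param model `"linear"` or `"nonlinear"`.
#' @return Named coefficient vector usable as `coefficients` in
#'   [dry_fraction()].
#' @export
fit_dry_fraction <- function(wet_g, dry_g, model = c("nonlinear", "linear")) {
  model <- match.arg(model)
  abort_if(length(wet_g) != length(dry_g) || length(wet_g) < 3,
           "need >= 3 paired (wet, dry) observations", "gh_insufficient_data")
  y <- 1 - dry_g / wet_g
  if (model == "linear") {
    fit <- stats::lm(y ~ wet_g)
    c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
  } else {
    s <- sqrt(wet_g)
    fit <- stats::lm(y ~ s + wet_g)
    c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
      c = -unname(stats::coef(fit)[3]))
  }
}

#' Read fecal records from CSV
#'
#' Columns: `cohort_id`, `individual_id`, `wet_g_per_day`, optional
#' `dry_g_per_day`.
#'
#' @param path CSV path.
#' @return Tibble of records.
#' @export
read_fecal_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  abort_if(!"wet_g_per_day" %in% names(tb),
           "fecal CSV needs a wet_g_per_day column", "gh_format_error")
  tb
}
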