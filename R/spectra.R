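# Cone spectral sensitivities from a shiftable photopigment nomogram.
#
# The engine is the Govardovskii et al. (2000) A1 visual-pigment template,
# evaluated once at a reference lambda-max of 500 nm and shifted rigidly in
# log-wavelength to any requested peak. Pre-receptoral filtering (lens +
# macular pigment) is folded into a single fixed transmittance curve.

# Govardovskii A1 template (alpha + beta band), absorbance, peak 1 at lmax.
govardovskii_a1 <- function(lambda, lmax) {
  x <- lmax / lambda
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha_band <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                       exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  b <- -40.5 + 0.195 * lmax
  beta_band <- 0.26 * exp(-((lambda - lmb) / b)^2)
  alpha_band + beta_band
}

# Reference absorbance template; all fundamentals are rigid log-wavelength
# shifts of this one curve, so shift invariance holds exactly.
.template_ref_lmax <- 500

template_absorbance <- function(lambda, lambda_max) {
  govardovskii_a1(lambda * .template_ref_lmax / lambda_max, .template_ref_lmax)
}

#' Pre-receptoral transmittance
#'
#' Fixed, stylized lens + macular pigment transmittance on an arbitrary
#' wavelength grid. Optical density is a short-wavelength exponential (lens)
#' plus a Gaussian centered at 460 nm (macular pigment); transmittance is
#' `10^-density`. The curve is an analytic stand-in with realistic shape and
#' scale, not a tabulated standard observer.
#'
#' @param lambda Wavelengths in nm.
#' @return Transmittance values in (0, 1].
#' @export
prereceptoral_transmittance <- function(lambda) {
  density <- 1.6 * exp(-(lambda - 400) / 55) + 0.35 * exp(-((lambda - 460) / 35)^2)
  10^(-density)
}

#' Cone spectral sensitivity for an arbitrary peak wavelength
#'
#' Builds a peak-normalized cone fundamental by shifting a photopigment
#' absorbance template rigidly in log-wavelength so that it peaks at
#' `lambda_max`, multiplying by the fixed pre-receptoral transmittance, and
#' sampling on the standard 400-720 nm grid.
#'
#' @param lambda_max Peak absorbance wavelength in nm; must lie in
#'   [400, 620], the documented validity window of the template on this grid.
#' @param filter Apply pre-receptoral filtering (default `TRUE`). Turning it
#'   off yields the bare absorbance template, used by unit tests.
#' @param wavelengths Wavelength grid (default [standard_wavelengths()]).
#' @return Object of class `cone_sensitivity`: list with `wavelengths`,
#'   `sensitivity` (unit peak), and `lambda_max`.
#' @export
cone_fundamental <- function(lambda_max, filter = TRUE,
                             wavelengths = standard_wavelengths()) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      lambda_max < 400 || lambda_max > 620) {
    cl_stop("conelearn_range_error",
            "lambda_max must be a single value in [400, 620] nm (got %s)",
            format(lambda_max))
  }
  sens <- template_absorbance(wavelengths, lambda_max)
  if (filter) sens <- sens * prereceptoral_transmittance(wavelengths)
  sens <- sens / max(sens)
  structure(list(wavelengths = wavelengths, sensitivity = sens,
                 lambda_max = lambda_max),
            class = "cone_sensitivity")
}

#' Standard L, M, S cone fundamentals
#'
#' Fundamentals for the typical human foveal cone classes: peaks at 558.9 nm
#' (L), 530 nm (M) and 420.7 nm (S).
#'
#' @param filter Apply pre-receptoral filtering (default `TRUE`).
#' @return Named list of three `cone_sensitivity` objects (`L`, `M`, `S`).
#' @export
standard_set <- function(filter = TRUE) {
  list(L = cone_fundamental(558.9, filter = filter),
       M = cone_fundamental(530,   filter = filter),
       S = cone_fundamental(420.7, filter = filter))
}

#' @export
print.cone_sensitivity <- function(x, ...) {
  cat(sprintf("cone sensitivity: lambda_max = %.1f nm, %d bands (%g-%g nm)\n",
              x$lambda_max, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}
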