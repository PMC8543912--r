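#' Forward signal equations for multi-b-value diffusion MRI
#'
#' Closed-form signal ratios \eqn{S_b/S_0} for the four diffusion models used
#' throughout the package: mono-exponential (ME), biexponential intravoxel
#' incoherent motion (IVIM), stretched exponential (SE) and diffusion kurtosis
#' (DKI).  All diffusivities are in mm\eqn{^2}/s and b-values in s/mm\eqn{^2},
#' so the product \eqn{b \cdot D} is dimensionless.  Every model returns
#' exactly 1 at \eqn{b = 0}.
#'
#' The four models are
#' \deqn{ME:   S_b/S_0 = \exp(-b \cdot ADC)}
#' \deqn{IVIM: S_b/S_0 = (1-f)\exp(-b D) + f \exp(-b D^*)}
#' \deqn{SE:   S_b/S_0 = \exp[-(b \cdot DDC)^\alpha]}
#' \deqn{DKI:  S_b/S_0 = \exp(-b D + b^2 D^2 K / 6)}
#'
#' IVIM reduces to ME at \eqn{f = 0}, SE at \eqn{\alpha = 1}, and DKI at
#' \eqn{K = 0}.  The DKI exponent is quadratic in b and turns upward at
#' \eqn{b = 3/(D K)}; the function evaluates the equation everywhere, but
#' fitting code caps predictions at that minimum (see [dki_b_max()]).
#'
#' @param adc Apparent diffusion coefficient, mm^2/s (>= 0).
#' @param b Diffusion weighting b-value(s), s/mm^2 (>= 0). Vectorised.
#' @return Numeric vector of signal ratios in (0, 1] (DKI may exceed 1 only
#'   beyond its validity bound).
#' @examples
#' me_signal(1e-3, c(0, 1000, 2500))
#' ivim_signal(D = 1e-3, Dstar = 8e-3, f = 0.1, b = 800)
#' @name signal_models
NULL

#' @rdname signal_models
#' @export
me_signal <- function(adc, b) {
  check_b(b)
  if (any(adc < 0)) stop("`adc` must be non-negative", call. = FALSE)
  exp(-b * adc)
}

#' @rdname signal_models
#' @param D True (tissue) diffusion coefficient, mm^2/s.
#' @param Dstar Pseudo-diffusion coefficient, mm^2/s; identifiability requires
#'   `D <= Dstar`.
#' @param f Perfusion fraction in \[0, 1\].
#' @export
ivim_signal <- function(D, Dstar, f, b) {
  check_b(b)
  if (any(f < 0 | f > 1)) stop("perfusion fraction `f` must lie in [0, 1]", call. = FALSE)
  if (any(D < 0)) stop("`D` must be non-negative", call. = FALSE)
  if (any(Dstar < D)) stop("`Dstar` must be >= `D` (IVIM identifiability)", call. = FALSE)
  (1 - f) * exp(-b * D) + f * exp(-b * Dstar)
}

#' @rdname signal_models
#' @param DDC Distributed diffusion coefficient, mm^2/s.
#' @param alpha Intravoxel heterogeneity index in (0, 1]; 1 is
#'   mono-exponential decay, smaller values mean broader intravoxel
#'   distributions of diffusion rates.
#' @export
se_signal <- function(DDC, alpha, b) {
  check_b(b)
  if (any(DDC < 0)) stop("`DDC` must be non-negative", call. = FALSE)
  if (any(alpha <= 0 | alpha > 1)) {
    stop("heterogeneity index `alpha` must lie in (0, 1]", call. = FALSE)
  }
  exp(-(b * DDC)^alpha)
}

#' @rdname signal_models
#' @param K Excess kurtosis of the diffusion displacement distribution
#'   (>= 0); 0 for perfectly Gaussian diffusion.
#' @export
dki_signal <- function(D, K, b) {
  check_b(b)
  if (any(D < 0)) stop("`D` must be non-negative", call. = FALSE)
  if (any(K < 0)) stop("kurtosis `K` must be non-negative", call. = FALSE)
  exp(-b * D + b^2 * D^2 * K / 6)
}

#' Validity bound of the kurtosis signal equation
#'
#' The DKI log-signal is quadratic in b and reaches its minimum at
#' \eqn{b = 3/(D K)}; beyond it the equation predicts nonphysical signal
#' re-growth.  Fitting code evaluates the model with predictions capped at
#' this minimum.
#'
#' @inheritParams signal_models
#' @param D Kurtosis-corrected diffusivity, mm^2/s.
#' @param K Kurtosis.
#' @return The bound in s/mm^2 (`Inf` when `D * K == 0`).
#' @export
dki_b_max <- function(D, K) {
  ifelse(D * K > 0, 3 / (D * K), Inf)
}

# DKI forward model with the prediction held flat beyond the b = 3/(DK)
# minimum; used by the fitter, never for user-facing signal evaluation.
dki_signal_capped <- function(D, K, b) {
  bcap <- pmin(b, dki_b_max(D, K))
  exp(-bcap * D + bcap^2 * D^2 * K / 6)
}

check_b <- function(b) {
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("b-values must be finite and non-negative (s/mm^2)", call. = FALSE)
  }
  invisible(b)
}

#' Default multi-b-value acquisition scheme
#'
#' A 13-b-value scheme spanning 0 to 2500 s/mm^2, dense at low b (to resolve
#' the perfusion compartment) and extending to 2500 (to resolve kurtosis).
#' This is a configurable stand-in for a clinical multi-b protocol, not a
#' fixed acquisition standard; any strictly increasing scheme containing 0
#' may be supplied wherever a scheme is accepted.
#'
#' @return Integer-valued numeric vector of 13 b-values (s/mm^2).
#' @examples
#' default_bvalues()
#' @export
default_bvalues <- function() {
  c(0, 10, 30, 50, 100, 150, 200, 500, 800, 1000, 1500, 2000, 2500)
}

#' Validate a b-value scheme
#'
#' A valid scheme is non-negative, strictly increasing and contains b = 0.
#'
#' @param bvalues Numeric vector of b-values, s/mm^2.
#' @return The scheme, invisibly, after validation.
#' @export
validate_bvalues <- function(bvalues) {
  if (!is.numeric(bvalues) || length(bvalues) < 2) {
    stop("a b-value scheme needs at least two numeric entries", call. = FALSE)
  }
  check_b(bvalues)
  if (any(diff(bvalues) <= 0)) stop("b-values must be strictly increasing", call. = FALSE)
  if (bvalues[1] != 0) stop("the scheme must contain b = 0", call. = FALSE)
  invisible(bvalues)
}
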