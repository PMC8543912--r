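#' Coefficient of determination of a voxel fit
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} between observed and predicted signals.
#' A perfect fit returns 1.  When the observed signal has zero variance the
#' statistic is defined as 1 if the residuals are zero and `NA` otherwise.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return A scalar R-squared (<= 1, possibly negative for fits worse than
#'   the mean).
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("`observed` and `predicted` must have equal length >= 2", call. = FALSE)
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    return(if (ss_res == 0) 1 else NA_real_)
  }
  1 - ss_res / ss_tot
}

# Physiological parameter bounds used by all bounded fits (mm^2/s where
# dimensional).  Diffusivities capped at free-water-like 4e-3; D* up to 0.5
# covers capillary pseudo-diffusion; K up to 3.
fit_bounds <- function() {
  list(
    adc = c(1e-6, 4e-3), D = c(1e-6, 4e-3), DDC = c(1e-6, 4e-3),
    Dstar = c(1e-6, 0.5), f = c(0, 1), alpha = c(0.01, 1), K = c(0, 3)
  )
}

#' Fit one diffusion model to a single voxel's multi-b signal
#'
#' Bounded nonlinear least-squares estimation of one of the four signal
#' models, with the b = 0 scale \eqn{S_0} as a free per-voxel parameter so
#' noise in the measured b = 0 volume does not bias the diffusion
#' parameters.  Fits are seeded from a log-linear mono-exponential
#' regression; the IVIM fit is seeded by the segmented two-step estimate by
#' default (see Details).
#'
#' @details
#' IVIM fitting modes:
#' \describe{
#'   \item{`"segmented"`}{(default) the two-step estimate: `D` and the
#'     extrapolated intercept from a log-linear fit on b >= `b_split`,
#'     then `f` and `D*` fitted over all b with `D` frozen.  Stable under
#'     noise (the usual clinical default), at the cost of a small
#'     perfusion-contamination bias in `D` (about 1% at typical breast
#'     parameters).}
#'   \item{`"full"`}{simultaneous bounded four-parameter fit, seeded from
#'     the segmented estimate; exact on noise-free model data but noisier
#'     at clinical SNR because `D`, `D*` and `f` are estimated jointly.}
#' }
#' DKI predictions are capped at the model's validity bound
#' `b = 3/(D K)` (see [dki_b_max()]); with b <= 2500 and physiological
#' parameters the cap is rarely active.
#'
#' @param signal Numeric vector of signal intensities, one per b-value.
#' @param bvalues The b-value scheme matching `signal`.
#' @param model One of `"me"`, `"ivim"`, `"se"`, `"dki"`.
#' @param b_subset Optional subset of b-values to fit on (e.g. `c(0, 1000)`
#'   for the two-point ADC); default uses all.
#' @param ivim_mode IVIM strategy, see Details.
#' @param b_split Mono-exponential regime threshold for segmented IVIM
#'   fitting, s/mm^2.
#' @return A list with class `dwi_fit`: `params` (named estimates), `s0`
#'   (fitted scale), `r2`, `model`, `valid`.
#' @examples
#' b <- default_bvalues()
#' s <- 100 * ivim_signal(1e-3, 8e-3, 0.12, b)
#' fit_voxel(s, b, "ivim")$params
#' @export
fit_voxel <- function(signal, bvalues, model = c("me", "ivim", "se", "dki"),
                      b_subset = NULL,
                      ivim_mode = c("segmented", "full"),
                      b_split = 200) {
  model <- match.arg(model)
  ivim_mode <- match.arg(ivim_mode)
  validate_bvalues(bvalues)
  if (length(signal) != length(bvalues)) {
    stop("`signal` and `bvalues` lengths differ", call. = FALSE)
  }
  if (!is.null(b_subset)) {
    keep <- bvalues %in% b_subset
    if (!any(bvalues[keep] == 0)) stop("`b_subset` must retain b = 0", call. = FALSE)
    signal <- signal[keep]
    bvalues <- bvalues[keep]
  }
  # minimum points: free parameters + 1, except the conventional two-point
  # ADC where S_0 is pinned to the measured b = 0 signal (exact closed form)
  n_min <- c(me = 2, ivim = 5, se = 4, dki = 4)[[model]]
  if (length(bvalues) < n_min) {
    stop(sprintf("model '%s' needs at least %d b-values", model, n_min),
         call. = FALSE)
  }
  if (all(signal <= 0) || signal[bvalues == 0][1] <= 0) {
    return(invalid_fit(model))
  }
  fit <- switch(model,
    me   = fit_me(signal, bvalues),
    ivim = fit_ivim(signal, bvalues, ivim_mode, b_split),
    se   = fit_se(signal, bvalues),
    dki  = fit_dki(signal, bvalues)
  )
  fit$model <- model
  fit$valid <- TRUE
  class(fit) <- "dwi_fit"
  fit
}

invalid_fit <- function(model) {
  structure(list(params = NULL, s0 = NA_real_, r2 = NA_real_,
                 model = model, valid = FALSE),
            class = "dwi_fit")
}

#' @export
print.dwi_fit <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<dwi_fit> %s: invalid voxel\n", x$model))
    return(invisible(x))
  }
  cat(sprintf("<dwi_fit> %s: %s; s0 = %.4g, R^2 = %.4f\n", x$model,
              paste(names(x$params), signif(x$params, 5), sep = " = ",
                    collapse = ", "), x$s0, x$r2))
  invisible(x)
}

# Log-linear mono-exponential regression, weighted by squared signal so it
# approximates signal-domain least squares.  Returns c(s0, adc), unbounded.
loglin_me <- function(signal, bvalues) {
  ok <- signal > 0
  if (sum(ok) < 2) return(c(s0 = max(signal), adc = 1e-3))
  y <- log(signal[ok])
  w <- signal[ok]^2
  fit <- stats::lm.wfit(cbind(1, -bvalues[ok]), y, w)
  c(s0 = exp(fit$coefficients[[1]]), adc = fit$coefficients[[2]])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bounded Levenberg-Marquardt wrapper; returns coefficients at the seed if
# the optimiser fails outright.
nls_fit <- function(signal, bvalues, predict_fun, start, lower, upper) {
  df <- data.frame(s = signal, b = bvalues)
  start <- as.list(pmin(pmax(unlist(start), lower), upper))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) signal - do.call(predict_fun, c(list(b = bvalues), p)),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 100, ptol = 1e-12,
                                           ftol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(unlist(start))
  unlist(fit$par)
}

fit_me <- function(signal, bvalues) {
  bnd <- fit_bounds()
  seed <- loglin_me(signal, bvalues)
  adc0 <- clamp(seed[["adc"]], bnd$adc[1], bnd$adc[2])
  if (length(bvalues) == 2) {
    # two-point fit is exact in closed form
    adc <- clamp(log(signal[1] / signal[2]) / (bvalues[2] - bvalues[1]),
                 bnd$adc[1], bnd$adc[2])
    pred <- signal[1] * me_signal(adc, bvalues)
    return(list(params = c(ADC = adc), s0 = signal[1],
                r2 = goodness_of_fit(signal, pred)))
  }
  p <- nls_fit(signal, bvalues,
               function(b, s0, adc) s0 * me_signal(adc, b),
               list(s0 = seed[["s0"]], adc = adc0),
               lower = c(1e-9, bnd$adc[1]), upper = c(Inf, bnd$adc[2]))
  pred <- p[["s0"]] * me_signal(p[["adc"]], bvalues)
  list(params = c(ADC = unname(p[["adc"]])), s0 = unname(p[["s0"]]),
       r2 = goodness_of_fit(signal, pred))
}

fit_ivim <- function(signal, bvalues, mode, b_split) {
  bnd <- fit_bounds()
  s0_obs <- signal[bvalues == 0][1]
  hi <- bvalues >= b_split
  if (sum(hi) < 2) hi <- rep(TRUE, length(bvalues))
  # step 1: tissue compartment from the high-b mono-exponential regime
  seed_hi <- loglin_me(signal[hi], bvalues[hi])
  D1 <- clamp(seed_hi[["adc"]], bnd$D[1], bnd$D[2])
  f1 <- clamp(1 - seed_hi[["s0"]] / s0_obs, 0.01, 0.6)

  step2 <- function(D, f_init, Ds_init) {
    nls_fit(signal, bvalues,
            function(b, s0, f, Ds) s0 * ((1 - f) * exp(-b * D) + f * exp(-b * Ds)),
            list(s0 = s0_obs, f = f_init, Ds = Ds_init),
            lower = c(1e-9, bnd$f[1], max(D, bnd$Dstar[1])),
            upper = c(Inf, bnd$f[2], bnd$Dstar[2]))
  }

  if (mode == "full") {
    p2 <- step2(D1, f1, 0.01)
    seed <- list(s0 = p2[["s0"]], f = p2[["f"]], D = D1, Ds = p2[["Ds"]])
    p <- nls_fit(signal, bvalues,
                 function(b, s0, f, D, Ds) {
                   s0 * ((1 - f) * exp(-b * D) + f * exp(-b * Ds))
                 },
                 seed,
                 lower = c(1e-9, bnd$f[1], bnd$D[1], bnd$Dstar[1]),
                 upper = c(Inf, bnd$f[2], bnd$D[2], bnd$Dstar[2]))
    # enforce the D <= D* identifiability convention on the labelled output
    D <- min(p[["D"]], p[["Ds"]]); Ds <- max(p[["D"]], p[["Ds"]])
    f <- if (Ds == p[["Ds"]]) p[["f"]] else 1 - p[["f"]]
    s0 <- p[["s0"]]
  } else {
    # step 2: perfusion compartment with D frozen at the step-1 estimate
    p2 <- step2(D1, f1, 0.01)
    D <- D1; Ds <- p2[["Ds"]]; f <- p2[["f"]]; s0 <- p2[["s0"]]
    if (Ds < D) { tmp <- D; D <- Ds; Ds <- tmp; f <- 1 - f }
  }
  pred <- s0 * ((1 - f) * exp(-bvalues * D) + f * exp(-bvalues * Ds))
  list(params = c(D = unname(D), Dstar = unname(Ds), f = unname(f)),
       s0 = unname(s0),
       r2 = goodness_of_fit(signal, pred))
}

fit_se <- function(signal, bvalues) {
  bnd <- fit_bounds()
  seed <- loglin_me(signal, bvalues)
  p <- nls_fit(signal, bvalues,
               function(b, s0, DDC, alpha) s0 * exp(-(b * DDC)^alpha),
               list(s0 = seed[["s0"]],
                    DDC = clamp(seed[["adc"]], bnd$DDC[1], bnd$DDC[2]),
                    alpha = 0.9),
               lower = c(1e-9, bnd$DDC[1], bnd$alpha[1]),
               upper = c(Inf, bnd$DDC[2], bnd$alpha[2]))
  pred <- p[["s0"]] * exp(-(bvalues * p[["DDC"]])^p[["alpha"]])
  list(params = c(DDC = unname(p[["DDC"]]), alpha = unname(p[["alpha"]])),
       s0 = unname(p[["s0"]]),
       r2 = goodness_of_fit(signal, pred))
}

fit_dki <- function(signal, bvalues) {
  bnd <- fit_bounds()
  # the DKI log-signal is exactly quadratic in b, so a weighted quadratic
  # regression gives a near-exact seed on clean data
  seed <- loglin_me(signal, bvalues)
  D0 <- clamp(seed[["adc"]], bnd$D[1], bnd$D[2])
  K0 <- 0.5
  ok <- signal > 0
  if (sum(ok) >= 3) {
    qf <- stats::lm.wfit(cbind(1, -bvalues[ok], bvalues[ok]^2),
                         log(signal[ok]), signal[ok]^2)
    Dq <- qf$coefficients[[2]]
    if (is.finite(Dq) && Dq > 0) {
      D0 <- clamp(Dq, bnd$D[1], bnd$D[2])
      K0 <- clamp(6 * qf$coefficients[[3]] / Dq^2, bnd$K[1], bnd$K[2])
      seed[["s0"]] <- exp(qf$coefficients[[1]])
    }
  }
  p <- nls_fit(signal, bvalues,
               function(b, s0, D, K) s0 * dki_signal_capped(D, K, b),
               list(s0 = seed[["s0"]], D = D0, K = K0),
               lower = c(1e-9, bnd$D[1], bnd$K[1]),
               upper = c(Inf, bnd$D[2], bnd$K[2]))
  pred <- p[["s0"]] * dki_signal_capped(p[["D"]], p[["K"]], bvalues)
  list(params = c(D = unname(p[["D"]]), K = unname(p[["K"]])),
       s0 = unname(p[["s0"]]),
       r2 = goodness_of_fit(signal, pred))
}

#' Fit all models voxel-wise and assemble the nine-map suite
#'
#' Runs the voxel-wise fits over a volume (optionally restricted to a mask)
#' and returns the nine standard quantitative maps — ME `ADC_all-b` and
#' `ADC_0-1000`, IVIM `D`, `D*`, `f`, SE `DDC` and `alpha`, DKI `K` and
#' `D_kurt` — together with a per-model R-squared quality map.  Voxels
#' where the fit is invalid (zero signal) are `NA` in every map.
#'
#' @param volume A [dwi_volume()]; pre-smooth with [gaussian_presmooth()]
#'   first if desired.
#' @param mask Optional logical 3D array restricting the fitted region
#'   (strongly recommended at cohort scale).
#' @param models Character subset of `c("me", "ivim", "se", "dki")`; the
#'   full default yields the nine maps.
#' @param ivim_mode,b_split Passed to [fit_voxel()].
#' @param adc_bvalues The b-subset for the two-point ADC map (requires both
#'   values in the scheme).
#' @return A list of class `map_suite` with elements `maps` (named list of
#'   [parameter_map()]s) and `quality` (named list of `fit_quality` objects,
#'   one per fitted model, each holding `r2_map` and `mean_r2` over the
#'   fitted region).
#' @export
generate_map_suite <- function(volume, mask = NULL,
                               models = c("me", "ivim", "se", "dki"),
                               ivim_mode = "segmented", b_split = 200,
                               adc_bvalues = c(0, 1000)) {
  stopifnot(inherits(volume, "dwi_volume"))
  models <- match.arg(models, c("me", "ivim", "se", "dki"), several.ok = TRUE)
  b <- volume$bvalues
  d3 <- dim(volume$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d3)
  if (!all(dim(mask) == d3)) stop("mask and volume dimensions differ", call. = FALSE)
  if ("me" %in% models && !all(adc_bvalues %in% b)) {
    stop(sprintf("scheme lacks b = {%s} needed for the two-point ADC map",
                 paste(adc_bvalues, collapse = ", ")), call. = FALSE)
  }
  idx <- which(mask)
  nvox <- prod(d3)
  sig <- matrix(volume$data, nrow = nvox)[idx, , drop = FALSE]

  wanted_models <- models
  maps <- list()
  quality <- list()
  alloc <- function() array(NA_real_, d3)

  store <- list()
  for (m in wanted_models) {
    npar <- c(me = 1, ivim = 3, se = 2, dki = 2)[[m]]
    store[[m]] <- list(par = matrix(NA_real_, length(idx),
                                    if (m == "me") 2 else npar),
                       r2 = rep(NA_real_, length(idx)))
  }
  for (v in seq_along(idx)) {
    s <- sig[v, ]
    for (m in wanted_models) {
      if (m == "me") {
        f_all <- fit_voxel(s, b, "me")
        f_two <- fit_voxel(s, b, "me", b_subset = adc_bvalues)
        if (f_all$valid) {
          store$me$par[v, ] <- c(f_all$params[["ADC"]], f_two$params[["ADC"]])
          store$me$r2[v] <- f_all$r2
        }
      } else {
        ft <- fit_voxel(s, b, m, ivim_mode = ivim_mode, b_split = b_split)
        if (ft$valid) {
          store[[m]]$par[v, ] <- ft$params
          store[[m]]$r2[v] <- ft$r2
        }
      }
    }
  }

  put_map <- function(vals_col, model, mapname, parameter, units) {
    a <- alloc()
    a[idx] <- vals_col
    maps[[mapname]] <<- parameter_map(a, model, parameter, units, volume$spacing)
  }
  if ("me" %in% wanted_models) {
    put_map(store$me$par[, 1], "ME", "ADC_all-b", "ADC", "mm^2/s")
    put_map(store$me$par[, 2], "ME", "ADC_0-1000", "ADC", "mm^2/s")
    quality$ME <- fit_quality(store$me$r2, idx, d3, "ME")
  }
  if ("ivim" %in% wanted_models) {
    put_map(store$ivim$par[, 1], "BE_IVIM", "D", "D", "mm^2/s")
    put_map(store$ivim$par[, 2], "BE_IVIM", "D*", "Dstar", "mm^2/s")
    put_map(store$ivim$par[, 3], "BE_IVIM", "f", "f", "1")
    quality$BE_IVIM <- fit_quality(store$ivim$r2, idx, d3, "BE_IVIM")
  }
  if ("se" %in% wanted_models) {
    put_map(store$se$par[, 1], "SE", "DDC", "DDC", "mm^2/s")
    put_map(store$se$par[, 2], "SE", "alpha", "alpha", "1")
    quality$SE <- fit_quality(store$se$r2, idx, d3, "SE")
  }
  if ("dki" %in% wanted_models) {
    put_map(store$dki$par[, 2], "DKI", "K", "K", "1")
    put_map(store$dki$par[, 1], "DKI", "D_kurt", "D", "mm^2/s")
    quality$DKI <- fit_quality(store$dki$r2, idx, d3, "DKI")
  }
  # order maps canonically
  want <- map_names()$map
  maps <- maps[intersect(want, names(maps))]
  structure(list(maps = maps, quality = quality, models = wanted_models),
            class = "map_suite")
}

fit_quality <- function(r2_vec, idx, dims, model) {
  r2_map <- array(NA_real_, dims)
  r2_map[idx] <- r2_vec
  structure(list(r2_map = r2_map, mean_r2 = mean(r2_vec, na.rm = TRUE),
                 model = model),
            class = "fit_quality")
}

#' @export
print.map_suite <- function(x, ...) {
  cat(sprintf("<map_suite> %d maps: %s\n", length(x$maps),
              paste(names(x$maps), collapse = ", ")))
  for (q in x$quality) {
    cat(sprintf("  %-8s mean R^2 = %.4f\n", q$model, q$mean_r2))
  }
  invisible(x)
}

#' Lesion-level quality-control decision on fit goodness
#'
#' A lesion is excluded when the mean R-squared of a diffusion model fit
#' over the lesion mask falls below the threshold (default 0.8); the
#' comparison is a strict less-than, so a mean of exactly 0.8 is kept.
#'
#' @param quality A `fit_quality`, a `map_suite`, or a list of
#'   `fit_quality` objects (one row per model in the output).
#' @param mask Logical 3D array; mean R-squared is recomputed over
#'   `mask` voxels with a finite R-squared.
#' @param threshold QC threshold in (0, 1\].
#' @return A tibble with columns `model`, `mean_r2`, `keep`; the lesion
#'   passes QC when every row has `keep == TRUE` (see [qc_keep()]).
#' @export
qc_filter_lesion <- function(quality, mask, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (!any(mask)) stop("QC mask is empty", call. = FALSE)
  qlist <- if (inherits(quality, "fit_quality")) list(quality)
           else if (inherits(quality, "map_suite")) quality$quality
           else quality
  purrr::map_dfr(qlist, function(q) {
    r2 <- q$r2_map[mask]
    m <- mean(r2[is.finite(r2)])
    tibble::tibble(model = q$model, mean_r2 = m, keep = !(m < threshold))
  })
}

#' @rdname qc_filter_lesion
#' @param qc_table Output of [qc_filter_lesion()].
#' @export
qc_keep <- function(qc_table) all(qc_table$keep)
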