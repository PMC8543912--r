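# Synthetic lesion phantoms and cohorts.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: multi-b acquisitions of an ellipsoidal lesion embedded in a body
# compartment surrounded by air, class-conditional diffusion parameters
# (malignant lesions with lower diffusivity, higher kurtosis and more
# intra-lesion heterogeneity than benign), spatially correlated intra-lesion
# texture, and seeded Rician magnitude noise.

# Run code under a temporarily seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Class-conditional ground-truth parameter distributions
#'
#' Subject-level lesion means are drawn from these distributions.  The
#' malignant/benign separation (lower `D`, slightly higher `f` and `D*`,
#' more intra-lesion heterogeneity for malignant lesions) is synthetic by
#' construction, chosen from the range reported across the breast-DWI
#' literature; it is a tuning knob of the generator, not a measured
#' population.  Because signals are generated from the biexponential
#' mixture, fitted kurtosis and heterogeneity-index maps inherit class
#' contrast (malignant: higher apparent K, lower alpha) from these draws.
#'
#' @param label `"benign"` or `"malignant"`.
#' @return A list of `c(mean, sd)` pairs for `D`, `Dstar`, `f`
#'   (diffusivities in mm^2/s) plus the relative intra-lesion heterogeneity
#'   `het`.
#' @export
class_parameter_defaults <- function(label = c("benign", "malignant")) {
  label <- match.arg(label)
  if (label == "malignant") {
    list(D = c(0.95e-3, 0.15e-3), Dstar = c(9e-3, 2e-3),
         f = c(0.10, 0.03), het = 0.12)
  } else {
    list(D = c(1.55e-3, 0.20e-3), Dstar = c(8e-3, 2e-3),
         f = c(0.08, 0.03), het = 0.06)
  }
}

#' Specify a single lesion phantom
#'
#' @param label Lesion class, `"benign"` or `"malignant"`.
#' @param semi_axes_mm Ellipsoid semi-axes in mm.
#' @param irregularity Relative amplitude of smooth boundary irregularity
#'   (0 = exact ellipsoid).
#' @param matrix_size Voxel matrix `c(nx, ny, nz)`.
#' @param spacing Voxel size in mm per axis.
#' @param params Lesion-mean parameter list with entries `D`, `Dstar`, `f`
#'   (scalars); defaults to the class-distribution means.
#' @param het Relative SD of the intra-lesion parameter fields.
#' @param corr_mm Spatial correlation length of the texture fields, mm.
#' @param s0_lesion,s0_body b = 0 signal of lesion and body compartments
#'   (arbitrary units).
#' @param body_params Background-tissue parameters.
#' @return A `lesion_phantom_spec` list.
#' @export
lesion_phantom_spec <- function(label = "benign",
                                semi_axes_mm = c(5, 4, 3),
                                irregularity = 0.15,
                                matrix_size = c(24, 24, 12),
                                spacing = c(1.5, 1.5, 2),
                                params = NULL,
                                het = NULL,
                                corr_mm = 2.5,
                                s0_lesion = 100,
                                s0_body = 50,
                                body_params = list(D = 1.3e-3, Dstar = 8e-3,
                                                   f = 0.05)) {
  label <- match.arg(label, c("benign", "malignant"))
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be positive", call. = FALSE)
  cls <- class_parameter_defaults(label)
  if (is.null(params)) {
    params <- list(D = cls$D[1], Dstar = cls$Dstar[1], f = cls$f[1])
  }
  if (is.null(het)) het <- cls$het
  structure(list(label = label, semi_axes_mm = semi_axes_mm,
                 irregularity = irregularity, matrix_size = matrix_size,
                 spacing = spacing, params = params, het = het,
                 corr_mm = corr_mm, s0_lesion = s0_lesion, s0_body = s0_body,
                 body_params = body_params),
            class = "lesion_phantom_spec")
}

# Biexponential IVIM forward model, vectorised over parameter arrays.
phantom_signal <- function(D, Dstar, f, b) {
  (1 - f) * exp(-b * D) + f * exp(-b * Dstar)
}

#' Generate a noiseless lesion phantom
#'
#' Builds a 4D multi-b DWI volume from ground-truth parameter fields: an
#' ellipsoidal lesion (optionally with smooth boundary irregularity) inside
#' a homogeneous-mean body compartment, surrounded by signal-free air.
#' Intra-lesion heterogeneity is injected as spatially correlated Gaussian
#' random fields on each parameter.  Signals are generated from the
#' biexponential IVIM model on the ground-truth `(D, D*, f)` fields; the
#' two-compartment mixture deviates from a single exponential, so stretched
#' exponential and kurtosis fits are well-posed on the same decay (with
#' apparent K > 0 and alpha < 1 that increase with compartment contrast).
#'
#' @param spec A [lesion_phantom_spec()].
#' @param bvalues B-value scheme.
#' @param seed RNG seed (NULL = use current stream).
#' @return A list: `volume` (noiseless [dwi_volume()]), `mask` (logical 3D
#'   lesion mask with spacing attribute), `body` (body-compartment mask),
#'   `truth` (named list of ground-truth [parameter_map()]s for `D`, `D*`,
#'   `f`, NA in air), and `spec`.
#' @export
make_lesion_phantom <- function(spec, bvalues = default_bvalues(), seed = NULL) {
  stopifnot(inherits(spec, "lesion_phantom_spec"))
  validate_bvalues(bvalues)
  with_local_seed(seed, {
    dims <- spec$matrix_size
    sp <- spec$spacing
    fov <- dims * sp
    if (any(2 * spec$semi_axes_mm > 0.7 * fov)) {
      stop("lesion does not fit inside the matrix", call. = FALSE)
    }
    ctr <- (dims + 1) / 2
    ax <- lapply(1:3, function(i) ((1:dims[i]) - ctr[i]) * sp[i])
    X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
    u <- (X / spec$semi_axes_mm[1])^2 + (Y / spec$semi_axes_mm[2])^2 +
      (Z / spec$semi_axes_mm[3])^2
    thresh <- if (spec$irregularity > 0) {
      (1 + spec$irregularity * correlated_field(dims, sp, 2 * spec$corr_mm))^2
    } else 1
    mask <- u <= thresh
    if (!any(mask)) stop("lesion mask is empty", call. = FALSE)

    # air shell: outer ~18% of the field of view on each axis, deep enough
    # for automatic background boxes
    marg <- pmax(2L, round(0.18 * dims))
    body <- array(FALSE, dims)
    body[(marg[1] + 1):(dims[1] - marg[1]),
         (marg[2] + 1):(dims[2] - marg[2]),
         (marg[3] + 1):(dims[3] - marg[3])] <- TRUE
    body <- body | mask

    field <- function(mean_les, mean_body, lo, hi, body_het = 0.04) {
      f <- array(NA_real_, dims)
      f[body] <- mean_body * (1 + body_het * correlated_field(dims, sp, spec$corr_mm)[body])
      if (spec$het > 0) {
        g <- correlated_field(dims, sp, spec$corr_mm)
        f[mask] <- mean_les * (1 + spec$het * g[mask])
      } else {
        f[mask] <- mean_les
      }
      pmin(pmax(f, lo), hi)
    }
    Df  <- field(spec$params$D, spec$body_params$D, 0.2e-3, 3.5e-3)
    Dsf <- field(spec$params$Dstar, spec$body_params$Dstar, 3e-3, 40e-3)
    Dsf <- pmax(Dsf, 1.2 * Df)
    ff  <- field(spec$params$f, spec$body_params$f, 0.005, 0.45)
    S0  <- array(0, dims)
    S0[body] <- spec$s0_body
    S0[mask] <- spec$s0_lesion

    data <- array(0, c(dims, length(bvalues)))
    inb <- which(body)
    for (i in seq_along(bvalues)) {
      vol <- array(0, dims)
      vol[inb] <- S0[inb] * phantom_signal(Df[inb], Dsf[inb], ff[inb],
                                           bvalues[i])
      data[, , , i] <- vol
    }
    attr(mask, "spacing") <- sp
    truth <- list(
      D = parameter_map(Df, "BE_IVIM", "D", "mm^2/s", sp),
      `D*` = parameter_map(Dsf, "BE_IVIM", "Dstar", "mm^2/s", sp),
      f = parameter_map(ff, "BE_IVIM", "f", "1", sp)
    )
    list(volume = dwi_volume(data, bvalues, sp), mask = mask, body = body,
         truth = truth, spec = spec)
  })
}

#' Add seeded Rician noise to a DWI volume
#'
#' Each voxel signal S is replaced by \eqn{\sqrt{(S+n_1)^2 + n_2^2}} with
#' independent zero-mean Gaussians of standard deviation `sigma`, the
#' magnitude-MR noise model (Rayleigh in signal-free background).  When
#' `sigma` is not given it is set to `mean(reference signal) / snr`, the
#' reference being the lesion-mask mean of the `reference_b` volume (or the
#' whole-volume positive-signal mean if no mask is supplied).
#'
#' @param volume A [dwi_volume()].
#' @param snr Target signal-to-noise ratio (> 0) defining `sigma` from the
#'   reference signal.
#' @param seed RNG seed (NULL = current stream).
#' @param mask Optional lesion mask for the reference mean.
#' @param reference_b Which b-value's volume provides the reference signal.
#' @param sigma Gaussian noise SD, overriding `snr` if given.
#' @return A noisy [dwi_volume()]; the applied `sigma` is attached as
#'   attribute `"sigma"`.
#' @export
add_rician_noise <- function(volume, snr = 30, seed = NULL, mask = NULL,
                             reference_b = 0, sigma = NULL) {
  stopifnot(inherits(volume, "dwi_volume"))
  if (is.null(sigma)) {
    if (!is.finite(snr) || snr <= 0) stop("`snr` must be > 0", call. = FALSE)
    ref <- b_volume(volume, reference_b)
    ref_mean <- if (is.null(mask)) mean(ref[ref > 0]) else mean(ref[mask])
    sigma <- ref_mean / snr
  }
  with_local_seed(seed, {
    n <- length(volume$data)
    noisy <- sqrt((volume$data + stats::rnorm(n, 0, sigma))^2 +
                    stats::rnorm(n, 0, sigma)^2)
    dim(noisy) <- dim(volume$data)
    out <- dwi_volume(noisy, volume$bvalues, volume$spacing)
    attr(out, "sigma") <- sigma
    out
  })
}

#' Specify a synthetic labelled cohort
#'
#' Defaults mirror a 542-lesion cohort with 333 malignant and 209 benign
#' cases and a measured lesion SNR of about 30 on the highest-b volume.
#'
#' @param n_subjects,n_malignant Cohort size and exact malignant count.
#' @param snr Target signal-to-noise ratio: the expected lesion-mean signal
#'   on the `snr_reference` volume divided by the background magnitude-noise
#'   SD.
#' @param seed Cohort RNG seed; every draw descends from it.
#' @param bvalues B-value scheme.
#' @param matrix_size,spacing Phantom geometry per subject.
#' @param irregularity,corr_mm Passed to [lesion_phantom_spec()].
#' @param snr_reference `"bmax"` (default; matches how lesion SNR is
#'   measured on the heavily weighted volume) or `"b0"`.
#' @param class_params Optional named list `list(benign = ..., malignant
#'   = ...)` of [class_parameter_defaults()]-shaped distributions
#'   overriding the defaults (e.g. to vary class separation).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 542, n_malignant = 333, snr = 30,
                        seed = 1, bvalues = default_bvalues(),
                        matrix_size = c(24, 24, 12),
                        spacing = c(1.5, 1.5, 2),
                        irregularity = 0.15, corr_mm = 2.5,
                        snr_reference = c("bmax", "b0"),
                        class_params = NULL) {
  if (n_malignant > n_subjects || n_malignant < 0 || n_subjects < 1) {
    stop("need 0 <= n_malignant <= n_subjects", call. = FALSE)
  }
  if (is.null(class_params)) {
    class_params <- list(benign = class_parameter_defaults("benign"),
                         malignant = class_parameter_defaults("malignant"))
  }
  structure(list(n_subjects = n_subjects, n_malignant = n_malignant,
                 snr = snr, seed = seed, bvalues = bvalues,
                 matrix_size = matrix_size, spacing = spacing,
                 irregularity = irregularity, corr_mm = corr_mm,
                 snr_reference = match.arg(snr_reference),
                 class_params = class_params),
            class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Draws exactly `n_malignant` malignant and `n_subjects - n_malignant`
#' benign subjects in seeded random order.  Each subject's lesion-mean
#' parameters come from [class_parameter_defaults()], its lesion size from
#' mild uniform jitter around 5 x 4 x 3 mm semi-axes, and its volume gets
#' seeded Rician noise.  With `snr_reference = "bmax"` the noise SD is set
#' so that the measured SNR — lesion mean over background magnitude SD on
#' the highest-b volume — targets `spec$snr` (the Rayleigh SD of the air
#' background is \eqn{\sigma\sqrt{2 - \pi/2}}).
#'
#' @param spec A [cohort_spec()].
#' @param out_dir If non-NULL, volumes/masks/ground truth are written there
#'   as NIfTI + bval sidecars with a `manifest.csv`, and the manifest tibble
#'   (with file paths) is returned instead of in-memory objects.
#' @param keep_truth Keep ground-truth maps in the in-memory result.
#' @return A tibble with one row per subject: `subject_id`, `label`, the
#'   true lesion-mean parameters (`true_D`, `true_Dstar`, `true_f`), and (in-memory form) list-columns `volume`, `mask`, `truth`.
#' @export
make_cohort <- function(spec = cohort_spec(), out_dir = NULL,
                        keep_truth = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  labels <- with_local_seed(spec$seed, {
    sample(rep(c("malignant", "benign"), c(spec$n_malignant, n - spec$n_malignant)))
  })
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rayleigh_sd <- sqrt(2 - pi / 2)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- (spec$seed * 1000L + i) %% .Machine$integer.max
    row <- with_local_seed(sseed, {
      cls <- spec$class_params[[labels[i]]]
      draw <- function(ms, lo, hi) clamp(stats::rnorm(1, ms[1], ms[2]), lo, hi)
      D <- draw(cls$D, 0.3e-3, 3e-3)
      Ds <- max(draw(cls$Dstar, 3e-3, 30e-3), 2 * D)
      f <- draw(cls$f, 0.01, 0.35)
      axes <- c(5, 4, 3) * stats::runif(3, 0.8, 1.2)
      ph_spec <- lesion_phantom_spec(
        label = labels[i], semi_axes_mm = axes,
        irregularity = spec$irregularity,
        matrix_size = spec$matrix_size, spacing = spec$spacing,
        params = list(D = D, Dstar = Ds, f = f),
        het = cls$het,
        corr_mm = spec$corr_mm
      )
      ph <- make_lesion_phantom(ph_spec, spec$bvalues, seed = NULL)
      les_ref <- if (spec$snr_reference == "bmax") {
        mean(b_volume(ph$volume, max(spec$bvalues))[ph$mask])
      } else {
        mean(b_volume(ph$volume, 0)[ph$mask])
      }
      sigma <- if (spec$snr_reference == "bmax") {
        les_ref / (spec$snr * rayleigh_sd)
      } else {
        les_ref / spec$snr
      }
      noisy <- add_rician_noise(ph$volume, sigma = sigma, seed = NULL)
      list(volume = noisy, mask = ph$mask, truth = ph$truth,
           means = c(D = D, Dstar = Ds, f = f))
    })
    sid <- sprintf("sub-%04d", i)
    if (is.null(out_dir)) {
      rows[[i]] <- tibble::tibble(
        subject_id = sid, label = labels[i],
        true_D = row$means[["D"]], true_Dstar = row$means[["Dstar"]],
        true_f = row$means[["f"]],
        volume = list(row$volume), mask = list(row$mask),
        truth = list(if (keep_truth) row$truth else NULL)
      )
    } else {
      dwi_f <- file.path(out_dir, paste0(sid, "_dwi.nii.gz"))
      bval_f <- file.path(out_dir, paste0(sid, ".bval"))
      mask_f <- file.path(out_dir, paste0(sid, "_mask.nii.gz"))
      write_dwi(row$volume, dwi_f, bval_f)
      write_mask(row$mask, mask_f, spec$spacing)
      if (keep_truth) {
        for (nm in names(row$truth)) {
          write_parameter_map(row$truth[[nm]],
                              file.path(out_dir, paste0(sid, "_truth_",
                                                        gsub("\\*", "star", nm),
                                                        ".nii.gz")))
        }
      }
      rows[[i]] <- tibble::tibble(
        subject_id = sid, label = labels[i],
        true_D = row$means[["D"]], true_Dstar = row$means[["Dstar"]],
        true_f = row$means[["f"]],
        dwi = dwi_f, bvals = bval_f, mask = mask_f
      )
    }
  }
  cohort <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    utils::write.csv(cohort, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  cohort
}

#' Morphologically jitter a lesion mask (synthetic second reader)
#'
#' Produces an overlapping alternative segmentation by adding a smooth
#' random field to the Gaussian-softened mask indicator and re-thresholding,
#' emulating inter-reader boundary disagreement.  Magnitude 0 returns the
#' mask unchanged; the default magnitude keeps Dice overlap >= 0.8 on
#' typical lesion sizes.
#'
#' @param mask Logical 3D array (spacing attribute used if present).
#' @param magnitude Perturbation amplitude (>= 0), roughly the boundary
#'   displacement in units of the indicator gradient.
#' @param seed RNG seed.
#' @param spacing Voxel spacing (mm) if not attached to the mask.
#' @return A perturbed logical mask of the same shape.
#' @export
perturb_mask <- function(mask, magnitude = 0.1, seed = NULL,
                         spacing = attr(mask, "spacing")) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (magnitude < 0) stop("`magnitude` must be >= 0", call. = FALSE)
  if (magnitude == 0) return(mask)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  with_local_seed(seed, {
    # a half-voxel kernel softens only the boundary, so thresholding at 0.5
    # reproduces the mask when magnitude = 0 noise is added
    soft <- gaussian_smooth_3d(array(as.numeric(mask), dim(mask)), rep(0.5, 3))
    g <- correlated_field(dim(mask), spacing, 2.5)
    # restrict to the softened support so the jitter stays at the boundary
    out <- (soft + magnitude * g) >= 0.5 & soft > 0.01
    if (!any(out)) stop("perturbation emptied the mask", call. = FALSE)
    attr(out, "spacing") <- spacing
    out
  })
}

#' Dice overlap of two masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient \eqn{2|A \cap B|/(|A|+|B|)}.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
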