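test_that("two-point ADC fit recovers the closed form exactly", {
  b <- c(0, 1000)
  s <- c(250, 250 * exp(-1.3))
  ft <- fit_voxel(s, b, "me")
  expect_equal(ft$params[["ADC"]], 1.3e-3, tolerance = 1e-12)
  expect_equal(ft$r2, 1.0)
  # same via b_subset on a full scheme
  bf <- default_bvalues()
  sf <- 250 * me_signal(1.3e-3, bf)
  ft2 <- fit_voxel(sf, bf, "me", b_subset = c(0, 1000))
  expect_equal(ft2$params[["ADC"]], 1.3e-3, tolerance = 1e-12)
})

test_that("noiseless generate-then-fit round trips recover parameters", {
  b <- default_bvalues()
  # reference operating points
  f1 <- fit_voxel(100 * ivim_signal(1e-3, 8e-3, 0.12, b), b, "ivim",
                  ivim_mode = "full")
  expect_equal(unname(f1$params), c(1e-3, 8e-3, 0.12), tolerance = 1e-4)
  expect_equal(f1$r2, 1.0, tolerance = 1e-9)
  f2 <- fit_voxel(80 * dki_signal(1.2e-3, 0.9, b), b, "dki")
  expect_equal(unname(f2$params), c(1.2e-3, 0.9), tolerance = 1e-4)
  expect_equal(f2$r2, 1.0, tolerance = 1e-9)
  f3 <- fit_voxel(90 * se_signal(1.1e-3, 0.75, b), b, "se")
  expect_equal(unname(f3$params), c(1.1e-3, 0.75), tolerance = 1e-4)
  # random physiological draws
  set.seed(42)
  for (i in 1:10) {
    D <- runif(1, 0.5e-3, 2e-3)
    fm <- fit_voxel(120 * me_signal(D, b), b, "me")
    expect_equal(fm$params[["ADC"]], D, tolerance = 1e-6)
    Ds <- runif(1, 6e-3, 25e-3); f <- runif(1, 0.03, 0.25)
    fi <- fit_voxel(100 * ivim_signal(D, Ds, f, b), b, "ivim", ivim_mode = "full")
    expect_equal(unname(fi$params), c(D, Ds, f), tolerance = 1e-4)
    a <- runif(1, 0.55, 0.95)
    fs <- fit_voxel(100 * se_signal(D, a, b), b, "se")
    expect_equal(unname(fs$params), c(D, a), tolerance = 1e-4)
    K <- runif(1, 0.2, min(1.5, 0.9 * 3 / (2500 * D)))
    fk <- fit_voxel(100 * dki_signal(D, K, b), b, "dki")
    expect_equal(unname(fk$params), c(D, K), tolerance = 1e-4)
  }
})

test_that("segmented IVIM carries only a small contamination bias on clean data", {
  b <- default_bvalues()
  ft <- fit_voxel(100 * ivim_signal(1e-3, 9e-3, 0.1, b), b, "ivim")
  expect_equal(ft$params[["D"]], 1e-3, tolerance = 0.03)
  expect_equal(ft$params[["f"]], 0.1, tolerance = 0.15)
  expect_true(ft$params[["D"]] <= ft$params[["Dstar"]])
})

test_that("goodness of fit follows the R-squared definition", {
  obs <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(goodness_of_fit(obs, obs), 1.0)
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 8)), 0.0)
  set.seed(5)
  for (i in 1:20) {
    o <- rnorm(10); p <- rnorm(10)
    # independent two-pass computation
    oracle <- 1 - sum((o - p)^2) / sum((o - mean(o))^2)
    expect_equal(goodness_of_fit(o, p), oracle)
  }
  expect_equal(goodness_of_fit(rep(2, 4), rep(2, 4)), 1)
  expect_true(is.na(goodness_of_fit(rep(2, 4), rep(3, 4))))
  expect_error(goodness_of_fit(1:3, 1:4), "equal length")
})

test_that("degenerate voxels and schemes are rejected or flagged", {
  b <- default_bvalues()
  ft <- fit_voxel(rep(0, 13), b, "ivim")
  expect_false(ft$valid)
  expect_true(is.na(ft$r2))
  expect_error(fit_voxel(c(100, 50), c(0, 1000), "ivim"), "at least")
  expect_error(fit_voxel(100 * me_signal(1e-3, b), b, "me",
                         b_subset = c(500, 1000)), "b = 0")
})

test_that("the map suite yields exactly the nine named maps", {
  ph <- make_lesion_phantom(
    lesion_phantom_spec("benign", het = 0, irregularity = 0),
    seed = 7
  )
  suite <- suppressWarnings(generate_map_suite(ph$volume, mask = ph$mask))
  expect_length(suite$maps, 9)
  expect_identical(names(suite$maps), map_names()$map)
  expect_setequal(names(suite$quality), c("ME", "BE_IVIM", "SE", "DKI"))
  # homogeneous noiseless lesion: spatially constant maps
  for (nm in c("ADC_all-b", "D", "DDC", "K")) {
    v <- suite$maps[[nm]]$values[ph$mask]
    expect_lt(stats::sd(v) / abs(mean(v)), 0.01)
  }
  # IVIM truth is recovered exactly (noise-free, full mode equivalence here
  # is not required: segmented bias stays within a few percent)
  expect_equal(mean(suite$maps$D$values[ph$mask]),
               mean(ph$truth$D$values[ph$mask]), tolerance = 0.03)
  # missing b = 1000 breaks the two-point ADC map
  b2 <- c(0, 200, 500, 800, 1500, 2500)
  v2 <- dwi_volume(ph$volume$data[, , , match(b2, ph$volume$bvalues)],
                   b2, ph$volume$spacing)
  expect_error(generate_map_suite(v2, mask = ph$mask), "b = \\{0, 1000\\}")
})

test_that("lesion QC applies a strict less-than 0.8 rule per model", {
  dims <- c(4, 4, 2)
  mask <- array(TRUE, dims)
  fq <- function(r2) {
    structure(list(r2_map = array(r2, dims), mean_r2 = r2, model = "SE"),
              class = "fit_quality")
  }
  expect_true(qc_filter_lesion(fq(0.95), mask)$keep)
  expect_false(qc_filter_lesion(fq(0.79), mask)$keep)
  expect_true(qc_filter_lesion(fq(0.80), mask)$keep)   # exactly 0.8 passes
  tab <- qc_filter_lesion(list(fq(0.95), fq(0.5)), mask)
  expect_equal(tab$keep, c(TRUE, FALSE))
  expect_false(qc_keep(tab))
  expect_error(qc_filter_lesion(fq(0.9), array(FALSE, dims)), "empty")
  expect_error(qc_filter_lesion(fq(0.9), mask, threshold = 0), "threshold")
})

test_that("noisy recovery through the processing chain stays under 5%", {
  # homogeneous lesion, Rician noise at SNR 30 (b = 0 referenced), the
  # standard 3 mm pre-smoothing, then voxel-wise fitting; median relative
  # error of ME-ADC and IVIM-D over an interior ROI of >= 20 voxels
  spec <- lesion_phantom_spec("malignant", semi_axes_mm = c(6, 5, 4),
                              het = 0, irregularity = 0)
  ph <- make_lesion_phantom(spec, seed = 5)
  noisy <- add_rician_noise(ph$volume, snr = 30, mask = ph$mask,
                            reference_b = 0, seed = 21)
  sm <- gaussian_presmooth(noisy, 3)
  m <- ph$mask; d <- dim(m); interior <- m
  for (ax in 1:3) for (s in c(-1, 1)) {
    sh <- array(FALSE, d)
    idx <- seq_len(d[ax]) + s; ok <- idx >= 1 & idx <= d[ax]
    if (ax == 1) sh[ok, , ] <- m[idx[ok], , ]
    if (ax == 2) sh[, ok, ] <- m[, idx[ok], ]
    if (ax == 3) sh[, , ok] <- m[, , idx[ok]]
    interior <- interior & sh
  }
  expect_gte(sum(interior), 20)
  suite <- suppressWarnings(
    generate_map_suite(sm, mask = interior, models = c("me", "ivim"))
  )
  ref <- suppressWarnings(
    generate_map_suite(ph$volume, mask = interior, models = "me")
  )
  adc_true <- mean(ref$maps$`ADC_all-b`$values[interior])
  d_err <- abs(suite$maps$D$values[interior] / 0.95e-3 - 1)
  a_err <- abs(suite$maps$`ADC_all-b`$values[interior] / adc_true - 1)
  expect_lt(median(d_err), 0.05)
  expect_lt(median(a_err), 0.05)
})

test_that("model fit beats a b-label shuffle in R-squared", {
  b <- default_bvalues()
  set.seed(31)
  s <- 100 * me_signal(1.2e-3, b)
  noisy <- sqrt((s + rnorm(13, 0, 3))^2 + rnorm(13, 0, 3)^2)
  r2_true <- fit_voxel(noisy, b, "me")$r2
  r2_shuf <- fit_voxel(sample(noisy), b, "me")$r2
  expect_gte(r2_true, r2_shuf)
})
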