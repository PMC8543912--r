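textured_map <- function(seed = 42) {
  ph <- make_lesion_phantom(lesion_phantom_spec("malignant"), seed = seed)
  list(map = ph$truth$D, mask = ph$mask)
}

test_that("every extraction yields 100 features in the fixed group partition", {
  tm <- textured_map()
  fv <- extract_features(tm$map, tm$mask)
  expect_equal(nrow(fv), 100)
  expect_equal(as.list(table(fv$group)),
               list(firstorder = 18L, glcm = 22L, gldm = 14L,
                    glrlm = 16L, glszm = 16L, shape = 14L))
  expect_true(all(is.finite(fv$value)))
  # deterministic for fixed input
  expect_identical(fv, extract_features(tm$map, tm$mask))
})

test_that("constant maps collapse the intensity features to the constant", {
  tm <- textured_map()
  cm <- tm$map
  cm$values[] <- 2e-3
  fv <- extract_features(cm, tm$mask)
  val <- function(g, f) fv$value[fv$group == g & fv$feature == f]
  expect_equal(val("firstorder", "Mean"), 2e-3)
  expect_equal(val("firstorder", "Median"), 2e-3)
  expect_equal(val("firstorder", "10Percentile"), 2e-3)
  expect_equal(val("firstorder", "Variance"), 0)
  expect_equal(val("firstorder", "Uniformity"), 1)
  expect_equal(val("firstorder", "Entropy"), 0)
  expect_equal(val("glcm", "Contrast"), 0)
  expect_equal(val("glcm", "MaximumProbability"), 1)
  expect_equal(val("glszm", "ZonePercentage"), 1 / sum(tm$mask))
})

test_that("texture matrices match hand-computed values on a 4-voxel line", {
  arr <- array(NA_real_, c(4, 1, 1))
  arr[] <- c(1, 1, 2, 2)
  mask <- array(TRUE, c(4, 1, 1))
  fv <- extract_features(arr, mask, spacing = c(1, 1, 1), bin_width = 1)
  val <- function(g, f) fv$value[fv$group == g & fv$feature == f]
  # GLCM (x-offset only): symmetric counts [[2,1],[1,2]] -> p/6
  expect_equal(val("glcm", "Contrast"), 2 / 6)
  expect_equal(val("glcm", "JointEnergy"), 10 / 36)
  expect_equal(val("glcm", "MaximumProbability"), 2 / 6)
  # GLRLM averaged over 13 directions: x gives 2 runs of length 2,
  # the other 12 give 4 runs of length 1
  expect_equal(val("glrlm", "RunPercentage"), (50 / 13) / 4)
  expect_equal(val("glrlm", "ShortRunEmphasis"), (48 / 13 + (2 / 13) / 4) / (50 / 13))
  # GLSZM: two 2-voxel zones
  expect_equal(val("glszm", "ZonePercentage"), 0.5)
  expect_equal(val("glszm", "SmallAreaEmphasis"), 0.25)
  expect_equal(val("glszm", "LargeAreaEmphasis"), 4)
  # GLDM (alpha = 0): every voxel has exactly one equal neighbour -> k = 2
  expect_equal(val("gldm", "SmallDependenceEmphasis"), 0.25)
  expect_equal(val("gldm", "DependenceEntropy"), 1)
})

test_that("sphere sphericity approaches 1 with increasing radius", {
  sphere_mask <- function(r, margin = 4) {
    n <- 2 * r + 2 * margin + 1
    ctr <- (n + 1) / 2
    g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
    m <- array((g$i - ctr)^2 + (g$j - ctr)^2 + (g$k - ctr)^2 <= r^2, c(n, n, n))
    m
  }
  sph <- function(r) {
    fv <- extract_features(array(1, dim(sphere_mask(r))) + 0, sphere_mask(r),
                           spacing = c(1, 1, 1), bin_width = 1)
    fv$value[fv$feature == "Sphericity"]
  }
  s10 <- sph(10)
  expect_lt(abs(s10 - 1), 0.05)
  expect_lt(abs(sph(14) - 1), abs(sph(6) - 1) + 1e-9)
})

test_that("degenerate masks are rejected with informative errors", {
  tm <- textured_map()
  one <- array(FALSE, dim(tm$mask)); one[10, 10, 5] <- TRUE
  expect_error(extract_features(tm$map, one), "shape and texture")
  expect_error(extract_features(tm$map, array(FALSE, dim(tm$mask))), "empty")
  expect_error(extract_features(tm$map, array(TRUE, c(2, 2, 2))), "dimensions")
  expect_error(mean_metric(tm$map, array(FALSE, dim(tm$mask))), "empty")
})

test_that("mean metrics equal lesion means and the first-order Mean", {
  tm <- textured_map()
  cm <- tm$map; cm$values[] <- 3.3e-4
  expect_equal(mean_metric(cm, tm$mask), 3.3e-4)
  two <- array(FALSE, dim(tm$mask)); two[c(5, 6), 5, 5] <- TRUE
  tv <- tm$map
  tv$values[5, 5, 5] <- 1; tv$values[6, 5, 5] <- 3
  expect_equal(mean_metric(tv, two), 2)
  fv <- extract_features(tm$map, tm$mask)
  fo_mean <- fv$value[fv$group == "firstorder" & fv$feature == "Mean"]
  expect_equal(mean_metric(tm$map, tm$mask), fo_mean, tolerance = 1e-12)
})

test_that("features are invariant to whole-voxel translation", {
  tm <- textured_map()
  d <- dim(tm$mask)
  m2 <- array(FALSE, d); v2 <- array(NA_real_, d)
  m2[2:d[1], , ] <- tm$mask[1:(d[1] - 1), , ]
  v2[2:d[1], , ] <- tm$map$values[1:(d[1] - 1), , ]
  map2 <- parameter_map(v2, tm$map$model, tm$map$parameter, tm$map$units,
                        tm$map$spacing)
  f1 <- extract_features(tm$map, tm$mask)
  f2 <- extract_features(map2, m2)
  expect_equal(f1$value, f2$value, tolerance = 1e-12)
})

test_that("the nine-map stack yields 900 named feature columns", {
  ph <- make_lesion_phantom(lesion_phantom_spec("malignant"), seed = 9)
  suite <- suppressWarnings(generate_map_suite(ph$volume, mask = ph$mask))
  long <- extract_map_features(suite, ph$mask)
  expect_equal(nrow(long), 900)
  long$subject_id <- "sub-0001"
  wide <- feature_matrix(long)
  expect_equal(ncol(wide) - 1, 900)
  expect_true(all(grepl("^[^_]+.*__(firstorder|shape|glcm|glrlm|glszm|gldm)__",
                        setdiff(names(wide), "subject_id"))))
})

test_that("ICC(2,1) behaves at its anchors and matches variance components", {
  set.seed(77)
  n <- 200
  subj <- rnorm(n, sd = 2)
  a <- tibble::tibble(subject_id = sprintf("s%03d", 1:n), f1 = subj + rnorm(n, sd = 0))
  # identical readings -> ICC 1
  expect_equal(icc(a, a)$icc, 1, tolerance = 1e-12)
  # independent noise -> ICC ~ 0
  b <- a; b$f1 <- rnorm(n)
  expect_lt(abs(icc(a, b)$icc), 0.15)
  # zero between-subject variance -> flagged NA
  z <- a; z$f1 <- rep(1, n)
  out <- icc(z, z)
  expect_true(is.na(out$icc))
  expect_false(out$reproducible)
  # large-sample agreement with the population variance decomposition:
  # sigma_s^2 = 4, rater shift 0.5 (var 0.0625 across the 2 raters),
  # sigma_e^2 = 1 -> ICC = 4 / (4 + 0.0625 + 1)
  set.seed(78)
  n2 <- 4000
  s <- rnorm(n2, sd = 2)
  r1 <- s + rnorm(n2) - 0.25
  r2 <- s + rnorm(n2) + 0.25
  expect_equal(icc21(r1, r2), 4 / (4 + 0.0625 + 1), tolerance = 0.04)
  # reproducibility threshold flag
  rr <- icc(a, tibble::tibble(subject_id = a$subject_id, f1 = a$f1 + rnorm(n, sd = 0.1)))
  expect_true(rr$reproducible)
})
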