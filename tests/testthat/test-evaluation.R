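# Brute-force oracle: count concordant pairs, ties as half.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == "malignant"]
  neg <- scores[labels != "malignant"]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

test_that("AUC equals the concordant-pair count at its anchors", {
  lab <- rep(c("malignant", "benign"), each = 5)
  expect_equal(roc_auc(c(6:10, 1:5), lab), 1.0)
  expect_equal(roc_auc(rep(3, 10), lab), 0.5)
  expect_error(roc_auc(1:4, rep("malignant", 4)), "both classes")
})

test_that("AUC matches the pair-enumeration oracle on random instances", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(3:10, 1); n0 <- 20 - n1
    sc <- round(rnorm(20), 1)            # rounding induces ties
    lab <- sample(rep(c("malignant", "benign"), c(n1, n0)))
    expect_equal(roc_auc(sc, lab), auc_pair_oracle(sc, lab))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(27)
  for (i in 1:10) {
    sc <- rnorm(40)
    lab <- sample(rep(c("malignant", "benign"), c(18, 22)))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = lab, predictor = sc, levels = c("benign", "malignant"),
      direction = "<", quiet = TRUE
    )))
    expect_equal(roc_auc(sc, lab), ref)
  }
})

test_that("AUC complement identity holds for tie-free scores", {
  set.seed(22)
  sc <- rnorm(30)
  lab <- sample(rep(c("malignant", "benign"), c(14, 16)))
  expect_equal(roc_auc(sc, lab) + roc_auc(-sc, lab), 1.0)
})

test_that("bootstrap CI brackets the point estimate and saturates at 1", {
  set.seed(23)
  lab <- rep(c("malignant", "benign"), each = 40)
  sep <- c(rnorm(40, 5), rnorm(40))
  ci <- auc_ci(sep, lab, n_boot = 300, seed = 1)
  expect_equal(ci$auc, 1.0)
  expect_equal(ci$upper, 1.0)
  mixed <- c(rnorm(40, 0.8), rnorm(40))
  ci2 <- auc_ci(mixed, lab, n_boot = 300, seed = 2)
  expect_true(ci2$lower <= ci2$auc && ci2$auc <= ci2$upper)
  expect_warning(
    auc_ci(rnorm(7), rep(c("malignant", "benign"), c(3, 4)), n_boot = 50),
    "fewer than 5"
  )
})

test_that("the Youden operating point reproduces hand-counted rates", {
  lab <- rep(c("malignant", "benign"), each = 10)
  # one unavoidable error on each side: one benign above every other score,
  # one malignant below every other score
  sc <- c(0.9, 0.86, 0.82, 0.78, 0.74, 0.7, 0.66, 0.62, 0.6, 0.05,
          0.95, 0.5, 0.45, 0.4, 0.35, 0.3, 0.25, 0.2, 0.15, 0.1)
  op <- operating_point(sc, lab)
  expect_equal(op$sensitivity, 0.9)
  expect_equal(op$specificity, 0.9)
  # Bayes identity: PPV/NPV from sens/spec and prevalence match direct counts
  prev <- 0.5
  ppv <- op$sensitivity * prev /
    (op$sensitivity * prev + (1 - op$specificity) * (1 - prev))
  npv <- op$specificity * (1 - prev) /
    (op$specificity * (1 - prev) + (1 - op$sensitivity) * prev)
  expect_equal(op$ppv, ppv)
  expect_equal(op$npv, npv)
  perfect <- operating_point(c(2:11, -(1:10)), lab)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
})

test_that("McNemar P values match the binomial tail-sum oracle", {
  # oracle: two-sided exact binomial tail sum
  binom_oracle <- function(b, c_) {
    n <- b + c_
    k <- min(b, c_)
    min(1, 2 * sum(choose(n, 0:k) * 0.5^n))
  }
  make_preds <- function(b, c_, n_agree = 10) {
    lab <- rep("malignant", b + c_ + n_agree)
    pa <- c(rep(TRUE, b), rep(FALSE, c_), rep(TRUE, n_agree))
    pb <- c(rep(FALSE, b), rep(TRUE, c_), rep(TRUE, n_agree))
    list(pa = pa, pb = pb, lab = lab)
  }
  x <- make_preds(12, 2)
  expect_equal(mcnemar_paired(x$pa, x$pb, x$lab), 0.012939, tolerance = 1e-4)
  for (bc in list(c(0, 0), c(1, 0), c(5, 5), c(9, 3), c(13, 12))) {
    x <- make_preds(bc[1], bc[2])
    expect_equal(mcnemar_paired(x$pa, x$pb, x$lab),
                 if (sum(bc) == 0) 1 else binom_oracle(bc[1], bc[2]))
  }
  # identical predictions
  expect_equal(mcnemar_paired(x$pa, x$pa, x$lab), 1.0)
  # large discordant counts: continuity-corrected chi-squared, cross-checked
  # against the standard implementation
  x <- make_preds(40, 18)
  expect_equal(
    mcnemar_paired(x$pa, x$pb, x$lab),
    stats::mcnemar.test(matrix(c(10, 18, 40, 0), 2), correct = TRUE)$p.value
  )
})

test_that("Bonferroni thresholds are exact divisions", {
  expect_equal(bonferroni_alpha(0.05, 23), 0.05 / 23)
  expect_equal(signif(bonferroni_alpha(0.05, 23), 3), 0.00217)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("image-quality metrics follow their defining arithmetic", {
  # lesion mean 100, background mean 20, background SD 10
  d <- c(10, 10, 4)
  arr <- array(0, c(d, 2))
  mask <- array(FALSE, d); mask[4:6, 4:6, 2:3] <- TRUE
  bg <- array(FALSE, d); bg[9:10, , ] <- TRUE
  arr[, , , 2][mask] <- 100
  # deterministic positive background with exact mean 20 and SD 10
  bgv <- seq_len(sum(bg))
  bgv <- (bgv - mean(bgv)) / sd(bgv) * 10 + 20
  stopifnot(all(bgv > 0))
  arr[, , , 2][bg] <- bgv
  vol <- dwi_volume(arr, c(0, 2500))
  iq <- image_quality(vol, mask, background = bg, b = 2500)
  expect_equal(iq$snr, 10)
  expect_equal(iq$cnr, 8)
  expect_equal(iq$contrast, 5)
  # noiseless background: SNR undefined
  arr[, , , 2][bg] <- 20
  expect_error(image_quality(dwi_volume(arr, c(0, 2500)), mask,
                             background = bg, b = 2500), "SNR undefined")
  expect_error(image_quality(vol, mask, background = mask, b = 2500),
               "overlaps")
})

test_that("automatic background boxes land in air and recover generator SNR", {
  sp <- cohort_spec(n_subjects = 6, n_malignant = 3, snr = 30, seed = 30)
  co <- make_cohort(sp)
  iq <- purrr::map_dfr(seq_len(nrow(co)), function(i) {
    image_quality(co$volume[[i]], co$mask[[i]])
  })
  expect_true(all(grepl("^face-", iq$background_origin)))
  expect_equal(mean(iq$snr), 30, tolerance = 0.2)
})

test_that("repeated McNemar comparisons aggregate into a mean P value", {
  set.seed(25)
  lab <- rep(c("malignant", "benign"), each = 40)
  sa <- c(rnorm(40, 2), rnorm(40))
  sb <- c(rnorm(40, 0.2), rnorm(40))
  cmp <- compare_methods_mcnemar(sa, sb, lab, n_runs = 50, seed = 3)
  expect_length(cmp$p_values, 50)
  expect_equal(cmp$p_value, mean(cmp$p_values))
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  one <- compare_methods_mcnemar(sa, sb, lab, n_runs = 1)
  expect_length(one$p_values, 1)
})

test_that("evaluation reports carry AUC, CI and operating rates per score set", {
  set.seed(26)
  scores <- dplyr::bind_rows(
    tibble::tibble(map = "D", method = "rf",
                   subject_id = sprintf("s%02d", 1:40),
                   label = rep(c("malignant", "benign"), each = 20),
                   score = c(rnorm(20, 1.5), rnorm(20))),
    tibble::tibble(map = "D", method = "mean_metric",
                   subject_id = sprintf("s%02d", 1:40),
                   label = rep(c("malignant", "benign"), each = 20),
                   score = c(rnorm(20, 0.8), rnorm(20)))
  )
  rep_ <- eval_report(scores, n_boot = 200, seed = 4)
  expect_s3_class(rep_, "eval_report")
  expect_equal(nrow(rep_), 2)
  expect_true(all(rep_$auc_lower <= rep_$auc & rep_$auc <= rep_$auc_upper))
  expect_true(all(rep_$sensitivity >= 0 & rep_$sensitivity <= 1))
  expect_true(all(c("ppv", "npv") %in% names(rep_)))
})
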