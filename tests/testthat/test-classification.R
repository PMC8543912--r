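# Synthetic feature matrices with a known signal, used across classifier
# tests.
toy_features <- function(n = 120, p = 20, shift = 1.2, n_mal = NULL,
                         seed = 1) {
  withr::local_seed(seed)
  if (is.null(n_mal)) n_mal <- n %/% 2
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c("malignant", "benign"), c(n_mal, n - n_mal))
  x[y == "malignant", 1:3] <- x[y == "malignant", 1:3] + shift
  feats <- tibble::as_tibble(as.data.frame(x))
  names(feats) <- paste0("D__glcm__f", seq_len(p))
  dplyr::mutate(feats, subject_id = sprintf("s%03d", seq_len(n)),
                label = y, .before = 1)
}

test_that("stratified splitting preserves counts and class ratios", {
  cohort <- tibble::tibble(
    subject_id = sprintf("p%03d", 1:542),
    label = rep(c("malignant", "benign"), c(333, 209))
  )
  sp <- stratified_split(cohort, fraction = 0.5, seed = 11)
  expect_length(sp$train_ids, 271)
  expect_length(sp$test_ids, 271)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  tr_lab <- cohort$label[cohort$subject_id %in% sp$train_ids]
  expect_true(sum(tr_lab == "malignant") %in% c(166, 167))
  # deterministic given the seed
  sp2 <- stratified_split(cohort, fraction = 0.5, seed = 11)
  expect_identical(sp$train_ids, sp2$train_ids)
  expect_false(identical(
    sp$train_ids, stratified_split(cohort, fraction = 0.5, seed = 12)$train_ids
  ))
  # 2+2 toy: one of each class per half
  mini <- tibble::tibble(subject_id = letters[1:4],
                         label = c("malignant", "malignant", "benign", "benign"))
  spm <- stratified_split(mini, 0.5, seed = 1)
  expect_equal(sum(mini$label[mini$subject_id %in% spm$train_ids] == "malignant"), 1)
  expect_error(stratified_split(tibble::tibble(subject_id = letters[1:3],
                                               label = rep("benign", 3))),
               "class")
})

test_that("all four classifiers separate a separable toy set perfectly in training", {
  feats <- toy_features(n = 60, shift = 6, seed = 2)
  for (kind in c("rf", "l1r", "pca", "svm")) {
    fit <- train_classifier(classifier_spec(kind, seed = 3), feats)
    sc <- predict_scores(fit, feats)
    expect_equal(roc_auc(sc$score, feats$label), 1.0,
                 tolerance = 1e-9, label = kind)
  }
})

test_that("label shuffling destroys held-out performance", {
  feats <- toy_features(n = 200, shift = 1.5, seed = 4)
  sp <- stratified_split(feats, 0.5, seed = 5)
  tr <- feats[feats$subject_id %in% sp$train_ids, ]
  te <- feats[feats$subject_id %in% sp$test_ids, ]
  fit_true <- train_classifier(classifier_spec("rf", seed = 7), tr)
  auc_true <- roc_auc(predict_scores(fit_true, te)$score, te$label)
  # average over several shuffles so the control estimate is stable
  auc_shuf <- mean(vapply(1:5, function(s) {
    withr::local_seed(600 + s)
    tr_shuf <- dplyr::mutate(tr, label = sample(.data$label))
    fit_shuf <- train_classifier(classifier_spec("rf", seed = 7), tr_shuf)
    roc_auc(predict_scores(fit_shuf, te)$score, te$label)
  }, numeric(1)))
  expect_lt(abs(auc_shuf - 0.5), 0.1)
  expect_gt(auc_true - auc_shuf, 0.2)
})

test_that("degenerate classifier inputs are rejected", {
  feats <- toy_features(n = 20, seed = 8)
  one_class <- dplyr::mutate(feats, label = "benign")
  expect_error(train_classifier(classifier_spec("rf"), one_class), "single class")
  with_na <- feats; with_na[[3]][2] <- NA
  expect_error(train_classifier(classifier_spec("l1r"), with_na), "missing")
})

test_that("repeated CV is stratified, bounded and bookkept", {
  feats <- toy_features(n = 40, shift = 2, seed = 9)
  cv <- repeated_cv(classifier_spec("l1r", seed = 1), feats, k = 5,
                    repeats = 3, seed = 10)
  expect_equal(nrow(cv$folds), 15)
  # fold sizes differ by at most 1 within each repeat
  for (r in 1:3) {
    sizes <- cv$folds$n_val[cv$folds$repeat_ == r]
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # selection frequency table matches a recount from the stored sets
  ff <- feature_frequency(cv)
  recount <- table(unlist(cv$selected))
  expect_equal(ff$n_selected[match(names(recount), ff$feature)],
               as.integer(recount))
  expect_true(all(ff$frequency <= 1))
  # degenerate leave-one-out runs
  tiny <- toy_features(n = 8, shift = 3, seed = 11)
  cv1 <- repeated_cv(classifier_spec("rf", seed = 1), tiny, k = 8,
                     repeats = 1, seed = 2)
  expect_equal(sum(cv1$folds$n_val), 8)
  expect_error(repeated_cv(classifier_spec("rf"), tiny, k = 50), "exceed")
})

test_that("forest importance is normalised, ranked and signal-seeking", {
  withr::local_seed(12)
  n <- 500; p <- 15
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c("malignant", "benign"), each = n / 2)
  x[y == "malignant", 7] <- x[y == "malignant", 7] + 2   # planted signal
  feats <- tibble::as_tibble(as.data.frame(x))
  names(feats) <- paste0("D__firstorder__f", seq_len(p))
  feats <- dplyr::mutate(feats, subject_id = sprintf("s%03d", seq_len(n)),
                         label = y, .before = 1)
  fit <- train_classifier(classifier_spec("rf", seed = 13), feats)
  imp <- feature_importance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_true(all(diff(imp$importance) <= 1e-12))
  expect_identical(imp$feature[1], "D__firstorder__f7")
  expect_equal(nrow(feature_importance(fit, top_n = 5)), 5)
  fit_svm <- train_classifier(classifier_spec("svm", seed = 1),
                              toy_features(n = 30, seed = 14))
  expect_error(feature_importance(fit_svm), "random forest")
})

test_that("training artifacts are identical with or without a test set present", {
  feats <- toy_features(n = 80, seed = 15)
  sp <- stratified_split(feats, 0.5, seed = 16)
  tr <- feats[feats$subject_id %in% sp$train_ids, ]
  fit_a <- train_classifier(classifier_spec("rf", seed = 17), tr)
  # deleting the test half cannot change anything fitted on the train half
  rm(feats)
  fit_b <- train_classifier(classifier_spec("rf", seed = 17), tr)
  expect_identical(feature_importance(fit_a), feature_importance(fit_b))
  expect_identical(predict_scores(fit_a, tr), predict_scores(fit_b, tr))
})

test_that("held-out RF AUC rises monotonically with generator class separation", {
  # three nested separations of the malignant D distribution; median over
  # 10 seeds of the held-out AUC on ground-truth D-map radiomics
  base_b <- class_parameter_defaults("benign")
  seps <- c(1.45e-3, 1.25e-3, 0.95e-3)   # malignant mean D, benign at 1.55e-3
  med_auc <- vapply(seps, function(mD) {
    aucs <- vapply(1:10, function(s) {
      mal <- class_parameter_defaults("malignant")
      mal$D[1] <- mD
      sp <- cohort_spec(n_subjects = 40, n_malignant = 20, seed = 100 + s,
                        matrix_size = c(16, 16, 10),
                        class_params = list(benign = base_b, malignant = mal))
      co <- make_cohort(sp)
      long <- purrr::map_dfr(seq_len(nrow(co)), function(i) {
        fv <- extract_features(co$truth[[i]]$D, co$mask[[i]])
        dplyr::mutate(fv, map = "D", subject_id = co$subject_id[i], .before = 1)
      })
      wide <- feature_matrix(long)
      wide <- dplyr::left_join(dplyr::select(co, "subject_id", "label"),
                               wide, by = "subject_id")
      spl <- stratified_split(wide, 0.5, seed = 200 + s)
      tr <- wide[wide$subject_id %in% spl$train_ids, ]
      te <- wide[wide$subject_id %in% spl$test_ids, ]
      fit <- train_classifier(classifier_spec("rf", seed = 300 + s), tr)
      roc_auc(predict_scores(fit, te)$score, te$label)
    }, numeric(1))
    median(aucs)
  }, numeric(1))
  expect_true(all(diff(med_auc) >= 0))
})
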