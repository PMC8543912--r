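# Four-classifier benign/malignant benchmark: stratified splitting,
# repeated stratified k-fold cross-validation on the training half, and
# held-out scoring.  All four classifiers consume the same feature matrix
# and split, so AUC comparisons are paired by construction.

positive_class <- "malignant"

#' Stratified train/test split of a labelled cohort
#'
#' Splits subjects so each half preserves the cohort's class ratio to
#' integer rounding (largest-remainder apportionment with a deterministic
#' tie-break toward the positive class); a 542-subject cohort with a 0.5
#' fraction yields a 271-subject training set.
#'
#' @param cohort A tibble (or data.frame) with columns `subject_id` and
#'   `label` (`"benign"`/`"malignant"`).
#' @param fraction Training fraction.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return A list of class `cohort_split` with `train_ids`, `test_ids`,
#'   `fraction`, `seed`.
#' @export
stratified_split <- function(cohort, fraction = 0.5, seed = 1) {
  labels <- cohort$label
  classes <- unique(labels)
  if (length(classes) < 2) stop("both classes must be present", call. = FALSE)
  if (any(table(labels) < 2)) stop("need >= 2 subjects per class", call. = FALSE)
  n_target <- round(fraction * nrow(cohort))
  exact <- fraction * as.numeric(table(labels)[classes])
  base <- floor(exact)
  rem <- exact - base
  extra <- n_target - sum(base)
  # deterministic apportionment: largest remainder, positive class first
  ord <- order(-rem, classes != positive_class)
  take <- base
  if (extra > 0) take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  names(take) <- classes
  train_ids <- with_local_seed(seed, {
    unlist(lapply(classes, function(cl) {
      ids <- cohort$subject_id[labels == cl]
      sample(ids, take[[cl]])
    }), use.names = FALSE)
  })
  structure(list(
    train_ids = sort(train_ids),
    test_ids = sort(setdiff(cohort$subject_id, train_ids)),
    fraction = fraction, seed = seed
  ), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> train %d / test %d (seed %s)\n",
              length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Specify one of the four benchmark classifiers
#'
#' @param kind `"rf"` (random forest, 100 trees of maximum depth 3),
#'   `"l1r"` (L1-regularised linear classifier; sparsity weight selected by
#'   seeded internal cross-validation unless `lambda` is given), `"pca"`
#'   (univariate prefilter to the 100 lowest rank-test P values, 10
#'   principal components, linear model), or `"svm"` (RBF kernel; `cost`
#'   and `gamma` tuned by seeded grid search on the training data unless
#'   fixed).
#' @param seed Seed for any internal randomness (forest growth, internal
#'   CV folds, tuning).
#' @param n_trees,max_depth Random-forest size.
#' @param lambda Optional fixed L1 penalty.
#' @param prefilter_n,n_components PCA pipeline sizes.
#' @param cost_grid,gamma_scale_grid SVM tuning grids (`gamma` grid is in
#'   multiples of 1/p).
#' @return A `classifier_spec` list; hyperparameters are carried verbatim
#'   into fitted models and reports.
#' @export
classifier_spec <- function(kind = c("rf", "l1r", "pca", "svm"), seed = 1,
                            n_trees = 100, max_depth = 3,
                            lambda = NULL,
                            prefilter_n = 100, n_components = 10,
                            cost_grid = c(0.1, 1, 10),
                            gamma_scale_grid = c(0.5, 1, 2)) {
  structure(list(kind = match.arg(kind), seed = seed,
                 n_trees = n_trees, max_depth = max_depth, lambda = lambda,
                 prefilter_n = prefilter_n, n_components = n_components,
                 cost_grid = cost_grid, gamma_scale_grid = gamma_scale_grid),
            class = "classifier_spec")
}

#' Names of the feature columns of a wide feature matrix
#'
#' Everything except the `subject_id` / `label` bookkeeping columns.
#'
#' @param features A wide feature tibble (see [feature_matrix()]).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(features) {
  setdiff(names(features), c("subject_id", "label"))
}

as_xy <- function(features, labels = NULL) {
  x <- as.matrix(features[, feature_cols(features), drop = FALSE])
  storage.mode(x) <- "double"
  if (is.null(labels)) labels <- features$label
  y <- factor(labels, levels = c("benign", "malignant"))
  list(x = x, y = y)
}

#' Train one classifier on a feature matrix
#'
#' Standardisation (training-set mean/SD) is applied for the L1, PCA and
#' SVM models; trees are scale-invariant so the random forest takes raw
#' features.  The fitted object scores new subjects with a continuous
#' malignancy score via [predict_scores()].
#'
#' @param spec A [classifier_spec()].
#' @param features Wide tibble with `subject_id` and feature columns (no
#'   missing values).
#' @param labels Class labels aligned with `features` rows (or a `label`
#'   column in `features`).
#' @return A fitted model of class `dwi_classifier`.
#' @export
train_classifier <- function(spec, features, labels = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  xy <- as_xy(features, labels)
  if (length(unique(xy$y)) < 2) stop("training labels contain a single class", call. = FALSE)
  if (anyNA(xy$x)) stop("features contain missing values", call. = FALSE)
  scaler <- NULL
  x <- xy$x
  if (spec$kind != "rf") {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    scaler <- list(mu = mu, sd = sdv)
    x <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  }
  fit <- with_local_seed(spec$seed, switch(spec$kind,
    rf = ranger::ranger(
      x = x, y = xy$y, num.trees = spec$n_trees, max.depth = spec$max_depth,
      probability = TRUE, importance = "impurity",
      num.threads = 1, seed = spec$seed
    ),
    l1r = fit_l1r(x, xy$y, spec),
    pca = fit_pca_lr(x, xy$y, spec),
    svm = fit_svm_rbf(x, xy$y, spec)
  ))
  structure(list(spec = spec, fit = fit, scaler = scaler,
                 features = feature_cols(features)),
            class = "dwi_classifier")
}

fit_l1r <- function(x, y, spec) {
  if (is.null(spec$lambda)) {
    # internal CV needs every fold to hold both classes; tiny training sets
    # fall back to a fixed moderate penalty
    k <- min(5, min(table(y)))
    if (k >= 3) {
      foldid <- stratified_folds(y, k = k)
      cv <- suppressWarnings(
        glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = FALSE)
      )
      lambda <- cv$lambda.min
    } else {
      lambda <- 0.05
    }
  } else {
    lambda <- spec$lambda
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  list(model = fit, lambda = lambda)
}

fit_pca_lr <- function(x, y, spec) {
  # univariate two-sample rank-test prefilter on the training data only
  pvals <- apply(x, 2, function(col) {
    if (stats::sd(col) == 0) return(1)
    suppressWarnings(stats::wilcox.test(col[y == positive_class],
                                        col[y != positive_class])$p.value)
  })
  keep <- order(pvals)[seq_len(min(spec$prefilter_n, ncol(x)))]
  pca <- stats::prcomp(x[, keep, drop = FALSE], center = FALSE, scale. = FALSE)
  ncomp <- min(spec$n_components, ncol(pca$x))
  z <- pca$x[, seq_len(ncomp), drop = FALSE]
  df <- data.frame(y = as.integer(y == positive_class), z)
  # separation warnings are expected on easy folds; the linear score is
  # still a valid ROC input
  lm_fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = list(maxit = 50))
  )
  list(keep = keep, rotation = pca$rotation[, seq_len(ncomp), drop = FALSE],
       model = lm_fit, pvals = pvals)
}

fit_svm_rbf <- function(x, y, spec) {
  p <- ncol(x)
  grid <- expand.grid(cost = spec$cost_grid,
                      gamma = spec$gamma_scale_grid / p)
  best <- NULL
  if (nrow(grid) > 1) {
    foldid <- stratified_folds(y, k = 3)
    score <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(sort(unique(foldid)), function(fd) {
        tr <- foldid != fd
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) return(NA_real_)
        m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g], scale = FALSE)
        dv <- attr(stats::predict(m, x[!tr, , drop = FALSE],
                                  decision.values = TRUE), "decision.values")
        sc <- orient_decision_values(dv, m)
        roc_auc(sc, y[!tr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- grid[which.max(score), ]
  } else {
    best <- grid[1, ]
  }
  m <- e1071::svm(x, y, kernel = "radial", cost = best$cost,
                  gamma = best$gamma, scale = FALSE)
  list(model = m, cost = best$cost, gamma = best$gamma)
}

# e1071 decision values are signed w.r.t. the first class seen in training;
# orient them so larger = more malignant.
orient_decision_values <- function(dv, model) {
  dv <- as.numeric(dv)
  lab <- colnames(attr(stats::predict(model, model$SV[1, , drop = FALSE],
                                      decision.values = TRUE),
                       "decision.values"))
  if (length(lab) && grepl("^benign/", lab[1])) dv <- -dv
  dv
}

#' Score subjects with a fitted classifier
#'
#' @param object A `dwi_classifier` from [train_classifier()].
#' @param features Wide feature tibble (same columns as at training).
#' @return A tibble `subject_id`, `score` (continuous malignancy score:
#'   class probability for the forest, linear predictor / decision value
#'   for the others).
#' @export
predict_scores <- function(object, features) {
  stopifnot(inherits(object, "dwi_classifier"))
  x <- as.matrix(features[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  if (!is.null(object$scaler)) {
    x <- sweep(sweep(x, 2, object$scaler$mu), 2, object$scaler$sd, `/`)
  }
  spec <- object$spec
  score <- switch(spec$kind,
    rf = stats::predict(object$fit, data = x,
                        num.threads = 1)$predictions[, positive_class],
    l1r = as.numeric(stats::predict(object$fit$model, newx = x, type = "link")),
    pca = {
      z <- x[, object$fit$keep, drop = FALSE] %*% object$fit$rotation
      df <- as.data.frame(z)
      as.numeric(stats::predict(object$fit$model, newdata = df, type = "link"))
    },
    svm = {
      dv <- attr(stats::predict(object$fit$model, x, decision.values = TRUE),
                 "decision.values")
      orient_decision_values(dv, object$fit$model)
    }
  )
  tibble::tibble(subject_id = features$subject_id, score = score)
}

#' @export
print.dwi_classifier <- function(x, ...) {
  cat(sprintf("<dwi_classifier> %s on %d features\n", x$spec$kind,
              length(x$features)))
  invisible(x)
}

# Stratified fold ids (1..k) balanced within each class; uses the current
# RNG stream.
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Repeated stratified k-fold cross-validation
#'
#' Repeats a stratified k-fold split of the training subjects with a fresh
#' seeded fold assignment each repeat, trains the classifier on each fold
#' complement (all preprocessing refitted inside the fold) and scores the
#' held-out fold.
#'
#' @param spec A [classifier_spec()].
#' @param features,labels Training feature matrix and labels.
#' @param k Folds (default 10); must not exceed the training size.
#' @param repeats Number of repeats (100 at full scale).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @return A list of class `cv_result`: `folds` (tibble repeat/fold/
#'   validation AUC/n), `selected` (per-repeat selected-feature list for
#'   sparse/prefiltered models), `spec`, plus `feature_frequency()` support.
#' @export
repeated_cv <- function(spec, features, labels = NULL, k = 10, repeats = 10,
                        seed = 1) {
  xy <- as_xy(features, labels)
  n <- length(xy$y)
  if (k > n) stop("`k` must not exceed the number of subjects", call. = FALSE)
  rows <- list()
  selected <- list()
  for (r in seq_len(repeats)) {
    foldid <- with_local_seed(seed + r, stratified_folds(xy$y, k))
    sel_r <- character(0)
    for (fd in sort(unique(foldid))) {
      tr <- foldid != fd
      if (length(unique(xy$y[tr])) < 2) next
      fit <- train_classifier(
        spec, features[tr, , drop = FALSE], labels = as.character(xy$y[tr])
      )
      sel_r <- union(sel_r, selected_features(fit))
      val_idx <- which(!tr)
      sc <- predict_scores(fit, features[val_idx, , drop = FALSE])
      auc <- if (length(unique(xy$y[val_idx])) == 2) {
        roc_auc(sc$score, xy$y[val_idx])
      } else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        repeat_ = r, fold = fd, n_val = length(val_idx), auc = auc
      )
    }
    selected[[r]] <- sel_r
  }
  structure(list(folds = dplyr::bind_rows(rows), selected = selected,
                 spec = spec, k = k, repeats = repeats, seed = seed),
            class = "cv_result")
}

# Features a fitted model actively uses: nonzero L1 coefficients, the PCA
# prefilter set, or positive-importance forest features.
selected_features <- function(object) {
  spec <- object$spec
  switch(spec$kind,
    l1r = {
      co <- as.matrix(stats::coef(object$fit$model))
      object$features[co[-1, 1] != 0]
    },
    pca = object$features[object$fit$keep],
    rf = object$features[ranger::importance(object$fit) > 0],
    svm = object$features
  )
}

#' Selection frequency of features across CV repeats
#'
#' @param cv A `cv_result`.
#' @return Tibble `feature`, `n_selected`, `frequency` (fraction of
#'   repeats), descending.
#' @export
feature_frequency <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  tab <- table(unlist(cv$selected))
  tibble::tibble(
    feature = names(tab), n_selected = as.integer(tab),
    frequency = as.integer(tab) / cv$repeats
  ) |> dplyr::arrange(dplyr::desc(.data$n_selected))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %d repeats x %d folds, mean val AUC %.3f\n",
              x$spec$kind, x$repeats, x$k, mean(x$folds$auc, na.rm = TRUE)))
  invisible(x)
}

#' Random-forest feature importance (mean decrease in impurity)
#'
#' Importances are normalised to sum to 1 and returned in descending
#' order; the top of this ranking is the "most important feature" of a
#' radiomics model.
#'
#' @param object A `dwi_classifier` of kind `"rf"`.
#' @param top_n Optionally keep only the leading features.
#' @return Tibble `feature`, `importance` (non-negative, summing to 1
#'   before any `top_n` cut), descending.
#' @export
feature_importance <- function(object, top_n = NULL) {
  stopifnot(inherits(object, "dwi_classifier"))
  if (object$spec$kind != "rf") {
    stop("impurity importance is defined for the random forest only", call. = FALSE)
  }
  imp <- ranger::importance(object$fit)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  out <- tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  if (!is.null(top_n)) out <- dplyr::slice_head(out, n = top_n)
  out
}
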