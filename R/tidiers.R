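#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a voxel fit into a term/estimate table
#'
#' @param x A `dwi_fit` from [fit_voxel()].
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @exportS3Method tidy dwi_fit
tidy.dwi_fit <- function(x, ...) {
  if (!x$valid) return(tibble::tibble(term = character(), estimate = numeric()))
  tibble::tibble(term = c(names(x$params), "s0"),
                 estimate = c(unname(x$params), x$s0))
}

#' @rdname tidy.dwi_fit
#' @exportS3Method glance dwi_fit
glance.dwi_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r2 = x$r2, valid = x$valid)
}

#' Tidy a map suite into per-map summaries
#'
#' @param x A `map_suite`.
#' @param mask Optional mask over which map summaries are taken.
#' @param ... Unused.
#' @return Tibble with map identity, units, voxel count, mean and SD.
#' @exportS3Method tidy map_suite
tidy.map_suite <- function(x, mask = NULL, ...) {
  purrr::map_dfr(names(x$maps), function(nm) {
    m <- x$maps[[nm]]
    v <- if (is.null(mask)) m$values else m$values[mask]
    v <- v[is.finite(v)]
    tibble::tibble(map = nm, model = m$model, parameter = m$parameter,
                   units = m$units, n_voxels = length(v),
                   mean = mean(v), sd = stats::sd(v))
  })
}

#' @rdname tidy.map_suite
#' @exportS3Method glance map_suite
glance.map_suite <- function(x, ...) {
  purrr::map_dfr(x$quality, function(q) {
    tibble::tibble(model = q$model, mean_r2 = q$mean_r2)
  })
}

#' Tidy a fitted classifier
#'
#' Random forests yield normalised impurity importances; L1 models their
#' nonzero coefficients; PCA models their component coefficients; SVMs
#' their tuned hyperparameters.
#'
#' @param x A `dwi_classifier`.
#' @param ... Unused.
#' @return A tibble whose shape depends on the classifier kind.
#' @exportS3Method tidy dwi_classifier
tidy.dwi_classifier <- function(x, ...) {
  switch(x$spec$kind,
    rf = feature_importance(x),
    l1r = {
      co <- as.matrix(stats::coef(x$fit$model))
      tibble::tibble(feature = rownames(co), coefficient = co[, 1]) |>
        dplyr::filter(.data$coefficient != 0)
    },
    pca = {
      co <- stats::coef(x$fit$model)
      tibble::tibble(term = names(co), coefficient = unname(co))
    },
    svm = tibble::tibble(parameter = c("cost", "gamma"),
                         value = c(x$fit$cost, x$fit$gamma))
  )
}

#' @rdname tidy.dwi_classifier
#' @exportS3Method glance dwi_classifier
glance.dwi_classifier <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind, n_features = length(x$features),
                 seed = x$spec$seed)
}

#' Tidy repeated-CV results
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-repeat, per-fold validation table.
#' @exportS3Method tidy cv_result
tidy.cv_result <- function(x, ...) x$folds

#' @rdname tidy.cv_result
#' @exportS3Method glance cv_result
glance.cv_result <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind, k = x$k, repeats = x$repeats,
                 mean_auc = mean(x$folds$auc, na.rm = TRUE),
                 sd_auc = stats::sd(x$folds$auc, na.rm = TRUE))
}

#' Tidy a cohort split into a subject/set table
#'
#' @param x A `cohort_split`.
#' @param ... Unused.
#' @return Tibble `subject_id`, `set`.
#' @exportS3Method tidy cohort_split
tidy.cohort_split <- function(x, ...) {
  tibble::tibble(
    subject_id = c(x$train_ids, x$test_ids),
    set = rep(c("train", "test"), c(length(x$train_ids), length(x$test_ids)))
  )
}
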