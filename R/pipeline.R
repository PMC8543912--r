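# End-to-end orchestration: simulate -> fit -> features -> classify ->
# evaluate, under one config with a single seed from which every random
# draw descends.  Stage outputs are plain CSV/JSON files so each stage is
# independently inspectable and re-runnable.

#' Build a pipeline configuration
#'
#' All knobs of the five stages in one serialisable list.  Every random
#' draw in a run descends from `seed`.
#'
#' @param out_dir Run directory for stage outputs.
#' @param seed Master seed.
#' @param n_subjects,n_malignant,snr,matrix_size,spacing Cohort generator
#'   settings (see [cohort_spec()]).
#' @param bvalues Acquisition scheme.
#' @param fwhm_mm Gaussian pre-smoothing FWHM in mm (NULL disables).
#' @param models Models to fit per subject.
#' @param ivim_mode IVIM strategy (see [fit_voxel()]).
#' @param qc_threshold Lesion QC threshold on mean R-squared.
#' @param n_bins Gray-level bins for radiomics.
#' @param feature_maps Maps whose radiomics feed classifiers (default: all
#'   maps produced by `models`).
#' @param classifiers Subset of `c("rf", "l1r", "pca", "svm")`.
#' @param split_fraction,folds,repeats Split and CV settings.
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @param m_comparisons Bonferroni comparison count (default 23).
#' @param mcnemar_runs Repetitions of the paired McNemar comparison.
#' @param run_cv Whether to run repeated CV (stability reporting) in
#'   addition to the refit-on-full-training-half test-set evaluation.
#' @return A `pipeline_config` list with a content hash.
#' @export
pipeline_config <- function(out_dir = tempfile("mbdwi_run_"), seed = 1,
                            n_subjects = 40, n_malignant = 24, snr = 30,
                            matrix_size = c(24, 24, 12),
                            spacing = c(1.5, 1.5, 2),
                            bvalues = default_bvalues(),
                            fwhm_mm = 3,
                            models = c("me", "ivim", "se", "dki"),
                            ivim_mode = "segmented",
                            qc_threshold = 0.8,
                            n_bins = 25,
                            feature_maps = NULL,
                            classifiers = c("rf", "l1r", "pca", "svm"),
                            split_fraction = 0.5, folds = 10, repeats = 2,
                            n_boot = 500, m_comparisons = 23,
                            mcnemar_runs = 100, run_cv = FALSE) {
  # canonical types so the content hash survives YAML round trips
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_malignant = as.integer(n_malignant), snr = as.numeric(snr),
    matrix_size = as.integer(matrix_size), spacing = as.numeric(spacing),
    bvalues = as.numeric(bvalues),
    fwhm_mm = if (is.null(fwhm_mm)) NULL else as.numeric(fwhm_mm),
    models = as.character(models), ivim_mode = as.character(ivim_mode),
    qc_threshold = as.numeric(qc_threshold), n_bins = as.integer(n_bins),
    feature_maps = if (is.null(feature_maps)) NULL else as.character(feature_maps),
    classifiers = as.character(classifiers),
    split_fraction = as.numeric(split_fraction), folds = as.integer(folds),
    repeats = as.integer(repeats), n_boot = as.integer(n_boot),
    m_comparisons = as.integer(m_comparisons),
    mcnemar_runs = as.integer(mcnemar_runs), run_cv = isTRUE(run_cv)
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write pipeline configs as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @name pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$hash <- NULL
  raw$matrix_size <- as.integer(raw$matrix_size)
  do.call(pipeline_config, raw)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[mbdwi] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes simulate, fit, features, classify and evaluate in order,
#' writing each stage's table to `out_dir` and returning everything
#' in-memory.  With `resume = TRUE`, stages whose output files already
#' exist under the same config hash are reloaded instead of recomputed
#' (fit/features stage granularity).
#'
#' @param config A [pipeline_config()].
#' @param resume Reload compatible stage outputs if present.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result`: `cohort` (labels and truth
#'   only), `qc`, `features` (wide), `mean_metrics`, `split`, `scores`,
#'   `report`, `comparisons`, `importance`, `cv`, `config`, `manifest`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()

  paths <- list(
    config = file.path(config$out_dir, "config.yaml"),
    qc = file.path(config$out_dir, "qc.csv"),
    features = file.path(config$out_dir, "features.csv"),
    means = file.path(config$out_dir, "mean_metrics.csv"),
    scores = file.path(config$out_dir, "scores.csv"),
    report = file.path(config$out_dir, "report.csv"),
    comparisons = file.path(config$out_dir, "comparisons.csv"),
    importance = file.path(config$out_dir, "importance.csv"),
    quality = file.path(config$out_dir, "image_quality.csv"),
    manifest = file.path(config$out_dir, "manifest.csv")
  )
  prior_hash <- if (file.exists(paths$config)) {
    tryCatch(yaml::read_yaml(paths$config)$hash, error = function(e) NULL)
  } else NULL
  can_resume <- isTRUE(resume) && identical(prior_hash, config$hash)
  write_pipeline_config(config, paths$config)

  # --- simulate ------------------------------------------------------------
  stage_log(quiet, "simulate: %d subjects (%d malignant), SNR %g",
            config$n_subjects, config$n_malignant, config$snr)
  cspec <- cohort_spec(
    n_subjects = config$n_subjects, n_malignant = config$n_malignant,
    snr = config$snr, seed = config$seed, bvalues = config$bvalues,
    matrix_size = config$matrix_size, spacing = config$spacing
  )

  if (can_resume && file.exists(paths$features) && file.exists(paths$means)) {
    stage_log(quiet, "fit/features: resuming from %s", config$out_dir)
    features <- tibble::as_tibble(utils::read.csv(paths$features, check.names = FALSE))
    means <- tibble::as_tibble(utils::read.csv(paths$means, check.names = FALSE))
    qc <- tibble::as_tibble(utils::read.csv(paths$qc))
    iq <- tibble::as_tibble(utils::read.csv(paths$quality))
    cohort_info <- dplyr::distinct(means, .data$subject_id, .data$label)
  } else {
    cohort <- make_cohort(cspec, keep_truth = FALSE)
    cohort_info <- dplyr::select(cohort, !dplyr::any_of(c("volume", "mask", "truth")))

    # --- fit + features ----------------------------------------------------
    stage_log(quiet, "fit: models {%s}, fwhm %s mm",
              paste(config$models, collapse = ","),
              ifelse(is.null(config$fwhm_mm), "none", config$fwhm_mm))
    qc_rows <- list(); feat_rows <- list(); mean_rows <- list(); iq_rows <- list()
    for (i in seq_len(nrow(cohort))) {
      vol <- cohort$volume[[i]]
      mask <- cohort$mask[[i]]
      sid <- cohort$subject_id[i]
      if (!is.null(config$fwhm_mm)) vol <- gaussian_presmooth(vol, config$fwhm_mm)
      suite <- suppressWarnings(generate_map_suite(
        vol, mask = mask, models = config$models, ivim_mode = config$ivim_mode
      ))
      qtab <- qc_filter_lesion(suite, mask, config$qc_threshold)
      qc_rows[[i]] <- dplyr::mutate(qtab, subject_id = sid, .before = 1)
      iq_rows[[i]] <- dplyr::mutate(image_quality(vol, mask),
                                    subject_id = sid, .before = 1)
      if (!qc_keep(qtab)) {
        stage_log(quiet, "  %s excluded by QC (mean R^2 < %g)", sid,
                  config$qc_threshold)
        next
      }
      mean_rows[[i]] <- dplyr::mutate(mean_metrics(suite, mask),
                                      subject_id = sid,
                                      label = cohort$label[i], .before = 1)
      fm <- config$feature_maps %||% names(suite$maps)
      sub_suite <- suite
      sub_suite$maps <- suite$maps[intersect(fm, names(suite$maps))]
      fv <- extract_map_features(sub_suite, mask, n_bins = config$n_bins)
      feat_rows[[i]] <- dplyr::mutate(fv, subject_id = sid, .before = 1)
    }
    qc <- dplyr::bind_rows(qc_rows)
    iq <- dplyr::bind_rows(iq_rows)
    means <- dplyr::bind_rows(mean_rows)
    features_long <- dplyr::bind_rows(feat_rows)
    features <- feature_matrix(features_long)
    features <- dplyr::left_join(
      dplyr::distinct(means, .data$subject_id, .data$label), features,
      by = "subject_id"
    )
    utils::write.csv(qc, paths$qc, row.names = FALSE)
    utils::write.csv(iq, paths$quality, row.names = FALSE)
    utils::write.csv(means, paths$means, row.names = FALSE)
    utils::write.csv(features, paths$features, row.names = FALSE)
  }

  n_excluded <- config$n_subjects - nrow(dplyr::distinct(means, .data$subject_id))
  stage_log(quiet, "features: %d subjects passed QC (%d excluded), %d feature columns",
            nrow(features), n_excluded,
            length(feature_cols(features)))

  # --- classify ------------------------------------------------------------
  split <- stratified_split(features, fraction = config$split_fraction,
                            seed = config$seed + 101)
  tr <- features[features$subject_id %in% split$train_ids, ]
  te <- features[features$subject_id %in% split$test_ids, ]
  mean_tr <- means[means$subject_id %in% split$train_ids, ]
  mean_te <- means[means$subject_id %in% split$test_ids, ]
  stage_log(quiet, "classify: train %d / test %d, classifiers {%s}",
            nrow(tr), nrow(te), paste(config$classifiers, collapse = ","))

  all_cols <- feature_cols(features)
  fmap_of <- function(col) sub("__.*$", "", col)
  used_maps <- unique(fmap_of(all_cols))
  score_rows <- list(); imp_rows <- list(); cv_list <- list()
  fitted <- list()
  for (mp in used_maps) {
    cols <- all_cols[fmap_of(all_cols) == mp]
    tr_mp <- tr[, c("subject_id", "label", cols)]
    te_mp <- te[, c("subject_id", "label", cols)]
    for (cl in config$classifiers) {
      spec <- classifier_spec(cl, seed = config$seed + 997)
      fit <- train_classifier(spec, tr_mp)
      fitted[[paste(mp, cl, sep = "/")]] <- fit
      sc <- predict_scores(fit, te_mp)
      score_rows[[length(score_rows) + 1]] <- tibble::tibble(
        map = mp, method = cl, subject_id = sc$subject_id,
        label = te_mp$label, score = sc$score
      )
      if (cl == "rf") {
        imp_rows[[length(imp_rows) + 1]] <- dplyr::mutate(
          feature_importance(fit, top_n = 20), map = mp, .before = 1
        )
      }
      if (isTRUE(config$run_cv)) {
        cv_list[[paste(mp, cl, sep = "/")]] <- repeated_cv(
          spec, tr_mp, k = config$folds, repeats = config$repeats,
          seed = config$seed + 7919
        )
      }
    }
  }
  # univariate mean-metric scores, oriented on the training half
  mm_cols <- setdiff(names(means), c("subject_id", "label"))
  for (mc in mm_cols) {
    sgn <- if (roc_auc(mean_tr[[mc]], mean_tr$label) < 0.5) -1 else 1
    score_rows[[length(score_rows) + 1]] <- tibble::tibble(
      map = sub("^m", "", mc), method = "mean_metric",
      subject_id = mean_te$subject_id, label = mean_te$label,
      score = sgn * mean_te[[mc]]
    )
  }
  scores <- dplyr::bind_rows(score_rows)
  importance <- dplyr::bind_rows(imp_rows)
  utils::write.csv(scores, paths$scores, row.names = FALSE)
  utils::write.csv(importance, paths$importance, row.names = FALSE)

  # --- evaluate ------------------------------------------------------------
  stage_log(quiet, "evaluate: AUC/CI, operating points, paired McNemar")
  report <- eval_report(scores, n_boot = config$n_boot,
                        seed = config$seed + 31)
  alpha_adj <- bonferroni_alpha(0.05, config$m_comparisons)
  comp_rows <- list()
  for (mp in used_maps) {
    mm <- scores[scores$map == mp & scores$method == "mean_metric", ]
    rf <- scores[scores$map == mp & scores$method == "rf", ]
    if (!nrow(mm) || !nrow(rf)) next
    mm <- mm[match(rf$subject_id, mm$subject_id), ]
    cmp <- compare_methods_mcnemar(rf$score, mm$score, rf$label,
                                   n_runs = config$mcnemar_runs,
                                   seed = config$seed + 53)
    comp_rows[[mp]] <- tibble::tibble(
      map = mp, comparison = "radiomics_rf_vs_mean_metric",
      p_value = cmp$p_value, n_runs = cmp$n_runs,
      alpha_adjusted = alpha_adj,
      significant = cmp$p_value < alpha_adj
    )
  }
  comparisons <- dplyr::bind_rows(comp_rows)
  utils::write.csv(report, paths$report, row.names = FALSE)
  utils::write.csv(comparisons, paths$comparisons, row.names = FALSE)

  written <- unlist(paths[file.exists(unlist(paths))])
  manifest <- tibble::tibble(
    file = basename(written),
    path = unname(written),
    md5 = unname(tools::md5sum(written)),
    config_hash = config$hash
  )
  utils::write.csv(manifest, paths$manifest, row.names = FALSE)
  stage_log(quiet, "done in %.1f s -> %s",
            as.numeric(difftime(Sys.time(), t_start, units = "secs")),
            config$out_dir)

  structure(list(
    cohort = cohort_info, qc = qc, image_quality = iq, features = features,
    mean_metrics = means, split = split, scores = scores, report = report,
    comparisons = comparisons, importance = importance, cv = cv_list,
    fitted = fitted, config = config, manifest = manifest
  ), class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, %d maps, %d score sets\n",
              nrow(x$features), length(unique(x$report$map)), nrow(x$report)))
  print(x$report)
  invisible(x)
}
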