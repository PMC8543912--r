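# ROC/AUC evaluation, bootstrap confidence intervals, Youden operating
# points, paired McNemar comparisons under Bonferroni control, and
# image-quality metrics.

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    pos <- labels == positive_class
  } else {
    pos <- labels > 0
  }
  if (all(pos) || !any(pos)) stop("both classes must be present", call. = FALSE)
  pos
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney U statistic with midrank tie
#' handling: the probability that a random positive (malignant) subject
#' scores above a random negative one, counting ties as one half.
#'
#' @param scores Continuous malignancy scores (larger = more malignant).
#' @param labels Class labels (`"malignant"`/`"benign"`, logical or 0/1).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' Sensitivity/specificity at every distinct threshold (predict malignant
#' when score >= threshold).
#'
#' @inheritParams roc_auc
#' @return Tibble `threshold`, `sensitivity`, `specificity`, with the
#'   (0,0) and (1,1) endpoints included.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!pos] < t), numeric(1))
  tibble::tibble(
    threshold = c(Inf, th, -Inf),
    sensitivity = c(0, sens, 1),
    specificity = c(1, spec, 0)
  )
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval from class-stratified bootstrap resampling (both
#' classes resampled separately so every replicate keeps the class ratio).
#'
#' @inheritParams roc_auc
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed (NULL = current stream).
#' @return A list `auc`, `lower`, `upper`, `level`, `n_boot`; the interval
#'   is widened, if necessary, to contain the point estimate.
#' @export
auc_ci <- function(scores, labels, level = 0.95, n_boot = 2000, seed = NULL) {
  pos <- as_binary_labels(labels)
  if (min(sum(pos), sum(!pos)) < 5) {
    warning("fewer than 5 subjects in a class: bootstrap interval is unstable")
  }
  point <- roc_auc(scores, labels)
  ip <- which(pos); im <- which(!pos)
  reps <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bi <- c(sample(ip, length(ip), replace = TRUE),
              sample(im, length(im), replace = TRUE))
      roc_auc(scores[bi], pos[bi])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  list(auc = point, lower = min(q[1], point), upper = max(q[2], point),
       level = level, n_boot = n_boot)
}

#' Youden operating point and its diagnostic rates
#'
#' Chooses the threshold maximising the Youden index (sensitivity +
#' specificity - 1) on the supplied data and reports sensitivity,
#' specificity, PPV and NPV from the resulting confusion matrix.  Ties in
#' the Youden index are broken toward higher sensitivity.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `youden`.
#' @export
operating_point <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  rc <- roc_curve(scores, labels)
  rc <- rc[is.finite(rc$threshold), , drop = FALSE]
  yj <- rc$sensitivity + rc$specificity - 1
  best <- which(yj == max(yj))
  best <- best[which.max(rc$sensitivity[best])]
  t <- rc$threshold[best]
  pred <- scores >= t
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  tibble::tibble(
    threshold = t,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    youden = max(yj)
  )
}

#' Paired McNemar test between two classifiers
#'
#' Tests whether two methods' correctness patterns differ on the same
#' subjects, from the discordant pairs (one right where the other is
#' wrong).  Exact two-sided binomial when the discordant count is <= 25,
#' continuity-corrected chi-squared otherwise; zero discordant pairs give
#' P = 1.
#'
#' @param preds_a,preds_b Dichotomous predictions (logical or the label
#'   strings), aligned with `labels`.
#' @param labels True class labels.
#' @return Two-sided P value.
#' @export
mcnemar_paired <- function(preds_a, preds_b, labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  pos <- if (is.character(labels)) labels == positive_class else labels > 0
  pa <- if (is.logical(preds_a)) preds_a else preds_a == positive_class
  pb <- if (is.logical(preds_b)) preds_b else preds_b == positive_class
  if (length(pa) != length(pb) || length(pa) != length(pos)) {
    stop("predictions and labels must be aligned and equal length", call. = FALSE)
  }
  ca <- pa == pos
  cb <- pb == pos
  b <- sum(ca & !cb)
  c_ <- sum(!ca & cb)
  nd <- b + c_
  if (nd == 0) return(1)
  if (nd <= 25) {
    min(1, 2 * stats::pbinom(min(b, c_), nd, 0.5))
  } else {
    stat <- (abs(b - c_) - 1)^2 / nd
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 23)   # 0.00217
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 23) {
  if (!is.numeric(m) || m < 1) stop("`m` must be >= 1", call. = FALSE)
  alpha / m
}

#' Lesion image-quality metrics on a high-b volume
#'
#' SNR = mean lesion signal / SD of the background region; CNR = (mean
#' lesion - mean background) / SD background; lesion contrast = mean
#' lesion / mean background.  If no background region is supplied, an air
#' box is placed automatically: a slab of `slab_voxels` thickness along the
#' volume face with the lowest mean signal (so it lies outside the phantom
#' body); the choice is recorded in the output.
#'
#' @param volume A [dwi_volume()].
#' @param mask Lesion mask.
#' @param background Optional logical array of background voxels, disjoint
#'   from the lesion.
#' @param b Which b-value's volume to measure (default the highest).
#' @param slab_voxels Thickness of the automatic background slab.
#' @return A one-row tibble: `b`, `snr`, `cnr`, `contrast`, `lesion_mean`,
#'   `background_mean`, `background_sd`, `background_origin`.
#' @export
image_quality <- function(volume, mask, background = NULL,
                          b = max(volume$bvalues), slab_voxels = 2L) {
  stopifnot(inherits(volume, "dwi_volume"))
  vol <- b_volume(volume, b)
  if (!any(mask)) stop("lesion mask is empty", call. = FALSE)
  origin <- "supplied"
  if (is.null(background)) {
    d <- dim(vol)
    best <- NULL
    for (axis in 1:3) for (side in c("lo", "hi")) {
      sz <- min(slab_voxels, d[axis])
      idx <- if (side == "lo") 1:sz else (d[axis] - sz + 1):d[axis]
      box <- array(FALSE, d)
      if (axis == 1) box[idx, , ] <- TRUE
      if (axis == 2) box[, idx, ] <- TRUE
      if (axis == 3) box[, , idx] <- TRUE
      box <- box & !mask
      m <- mean(vol[box])
      if (is.null(best) || m < best$m) {
        best <- list(box = box, m = m, tag = paste0("face-", axis, "-", side))
      }
    }
    background <- best$box
    origin <- best$tag
  }
  if (any(background & mask)) stop("background overlaps the lesion", call. = FALSE)
  les <- vol[mask]
  bg <- vol[background]
  if (stats::sd(bg) == 0) {
    stop("background SD is zero (noiseless volume): SNR undefined", call. = FALSE)
  }
  tibble::tibble(
    b = b,
    snr = mean(les) / stats::sd(bg),
    cnr = (mean(les) - mean(bg)) / stats::sd(bg),
    contrast = mean(les) / mean(bg),
    lesion_mean = mean(les),
    background_mean = mean(bg),
    background_sd = stats::sd(bg),
    background_origin = origin
  )
}

#' Evaluate score tables into a performance report
#'
#' For each image set x method score table, computes the AUC with its
#' stratified-bootstrap CI and the Youden operating-point rates — the
#' standard per-map diagnostic performance summary.
#'
#' @param scores Tibble with columns `map`, `method`, `subject_id`,
#'   `label`, `score` (stacked test-set score tables).
#' @param level,n_boot,seed Passed to [auc_ci()].
#' @return A tibble of class `eval_report`, one row per (map, method):
#'   AUC, CI bounds, sensitivity, specificity, PPV, NPV.
#' @export
eval_report <- function(scores, level = 0.95, n_boot = 2000, seed = 1) {
  stopifnot(all(c("map", "method", "subject_id", "label", "score") %in% names(scores)))
  groups <- dplyr::distinct(scores, .data$map, .data$method)
  out <- purrr::pmap_dfr(groups, function(map, method) {
    sub <- scores[scores$map == map & scores$method == method, ]
    ci <- auc_ci(sub$score, sub$label, level = level, n_boot = n_boot,
                 seed = seed + nchar(map) * 131 + nchar(method))
    op <- operating_point(sub$score, sub$label)
    tibble::tibble(
      map = map, method = method, n = nrow(sub),
      auc = ci$auc, auc_lower = ci$lower, auc_upper = ci$upper,
      sensitivity = op$sensitivity, specificity = op$specificity,
      ppv = op$ppv, npv = op$npv
    )
  })
  class(out) <- c("eval_report", class(out))
  out
}

#' Paired comparison of two score sets by repeated McNemar tests
#'
#' Both score vectors are dichotomised at their own Youden thresholds and
#' compared by McNemar's test on the same subjects.  When `n_runs > 1`,
#' each run redraws a stratified bootstrap replicate of the subjects
#' (emulating repeated CV model draws) and the mean P value across runs is
#' reported.
#'
#' @param scores_a,scores_b Continuous scores on identical subjects.
#' @param labels True labels.
#' @param n_runs Number of repetitions (100 at full protocol scale).
#' @param seed RNG seed for the repetition resampling.
#' @return A list: `p_value` (mean over runs), `p_values` (per run),
#'   `n_runs`.
#' @export
compare_methods_mcnemar <- function(scores_a, scores_b, labels, n_runs = 100,
                                    seed = 1) {
  pos <- as_binary_labels(labels)
  ta <- operating_point(scores_a, labels)$threshold
  tb <- operating_point(scores_b, labels)$threshold
  one <- function(idx) {
    mcnemar_paired(scores_a[idx] >= ta, scores_b[idx] >= tb, pos[idx])
  }
  if (n_runs == 1) {
    p <- one(seq_along(pos))
    return(list(p_value = p, p_values = p, n_runs = 1))
  }
  ip <- which(pos); im <- which(!pos)
  ps <- with_local_seed(seed, {
    vapply(seq_len(n_runs), function(r) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(im, length(im), replace = TRUE))
      one(idx)
    }, numeric(1))
  })
  list(p_value = mean(ps), p_values = ps, n_runs = n_runs)
}
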