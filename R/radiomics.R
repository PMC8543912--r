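# Radiomics feature extraction: 100 features per (parameter map, lesion
# mask) pair, grouped as first-order (18), shape (14), GLCM (22), GLRLM
# (16), GLSZM (16) and GLDM (14), following the standard 3D definitions of
# the radiomics literature.  Gray-level discretisation uses a fixed bin
# width scaled to each map's physiological range (about 25 bins across the
# range), so feature values are comparable across subjects.

#' Default gray-level bin width for a parameter map
#'
#' Fixed bin width equal to 1/25 of the map's physiological range:
#' diffusivity-like maps (ADC, D, DDC, D_kurt) span 0-4e-3 mm^2/s, `D*`
#' 0-0.5 mm^2/s, `f` and `alpha` 0-1, and `K` 0-3.
#'
#' @param map A [parameter_map()] (or a map name from [map_names()]).
#' @param n_bins Nominal number of bins across the range.
#' @return A scalar bin width in the map's units.
#' @export
map_bin_width <- function(map, n_bins = 25) {
  par <- if (inherits(map, "parameter_map")) map$parameter else {
    nm <- map_names()
    nm$parameter[match(map, nm$map)]
  }
  range_hi <- switch(par,
    ADC = 4e-3, D = 4e-3, DDC = 4e-3, Dstar = 0.5,
    f = 1, alpha = 1, K = 3,
    stop(sprintf("no default range for parameter '%s'", par), call. = FALSE)
  )
  range_hi / n_bins
}

# Fixed-bin-width discretisation of the masked values; levels start at 1.
discretize_gl <- function(x, bin_width) {
  gl <- floor((x - min(x)) / bin_width) + 1L
  storage.mode(gl) <- "integer"
  gl
}

# The 13 unique 3D direction offsets (one per +/- pair of the 26-neighbourhood).
direction_offsets_13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  keep <- offs[, 3] > 0 |
    (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))
  offs[keep, , drop = FALSE]
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the 100-feature radiomics vector from one map and mask
#'
#' Computes 18 first-order, 14 shape, 22 GLCM, 16 GLRLM, 16 GLSZM and 14
#' GLDM features from the masked voxels of a quantitative parameter map.
#' Texture matrices are computed in 3D over the 13 unique direction offsets
#' and averaged across directions (GLCM, GLRLM); zones/dependences use the
#' full 26-neighbourhood.  Gray levels come from fixed-bin-width
#' discretisation (see [map_bin_width()]).
#'
#' @param map A [parameter_map()] or plain 3D array.
#' @param mask Logical 3D array, at least 2 voxels, inside map bounds;
#'   voxels with non-finite map values are dropped from the mask.
#' @param spacing Voxel spacing in mm (defaults to the map's).
#' @param bin_width Gray-level bin width; default from the map identity.
#' @return A tibble with 100 rows and columns `group`, `feature`, `value`.
#' @examples
#' ph <- make_lesion_phantom(lesion_phantom_spec(), seed = 1)
#' fv <- extract_features(ph$truth$D, ph$mask)
#' dplyr::count(fv, group)
#' @export
extract_features <- function(map, mask, spacing = NULL, bin_width = NULL) {
  if (inherits(map, "parameter_map")) {
    if (is.null(spacing)) spacing <- map$spacing
    if (is.null(bin_width)) bin_width <- map_bin_width(map)
    vals <- map$values
  } else {
    if (is.null(spacing)) spacing <- attr(mask, "spacing")
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(bin_width)) stop("`bin_width` required for a plain array", call. = FALSE)
    vals <- map
  }
  if (!all(dim(mask) == dim(vals))) stop("mask and map dimensions differ", call. = FALSE)
  mask <- mask & is.finite(vals)
  n <- sum(mask)
  if (n == 0) stop("mask is empty", call. = FALSE)
  if (n < 2) {
    stop("single-voxel mask: shape and texture features are undefined", call. = FALSE)
  }
  x <- vals[mask]
  gl_arr <- array(NA_integer_, dim(vals))
  gl_arr[mask] <- discretize_gl(x, bin_width)
  ng <- max(gl_arr, na.rm = TRUE)

  fo <- firstorder_features(x, gl_arr[mask], prod(spacing))
  sh <- shape_features(mask, spacing)
  glcm <- glcm_features(gl_arr, mask, ng)
  glrlm <- glrlm_features(gl_arr, mask, ng)
  glszm <- glszm_features(gl_arr, mask, ng)
  gldm <- gldm_features(gl_arr, mask, ng)

  out <- dplyr::bind_rows(
    tibble::tibble(group = "firstorder", feature = names(fo), value = unname(fo)),
    tibble::tibble(group = "shape", feature = names(sh), value = unname(sh)),
    tibble::tibble(group = "glcm", feature = names(glcm), value = unname(glcm)),
    tibble::tibble(group = "glrlm", feature = names(glrlm), value = unname(glrlm)),
    tibble::tibble(group = "glszm", feature = names(glszm), value = unname(glszm)),
    tibble::tibble(group = "gldm", feature = names(gldm), value = unname(gldm))
  )
  counts <- table(out$group)
  expect <- c(firstorder = 18, shape = 14, glcm = 22, glrlm = 16, glszm = 16, gldm = 14)
  stopifnot(nrow(out) == 100, all(counts[names(expect)] == expect))
  out
}

firstorder_features <- function(x, gl, voxel_vol) {
  n <- length(x)
  p <- tabulate(gl) / n
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  rob <- x[x >= q[1] & x <= q[5]]
  c(
    Energy = sum(x^2),
    TotalEnergy = voxel_vol * sum(x^2),
    Entropy = entropy2(p),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

# Surface area by the coarea formula: the mask indicator is softened with a
# one-voxel Gaussian and the surface integral estimated as the sum of the
# gradient magnitude (central differences in mm) times the voxel volume.
# Converges to within a few percent of the true area for blobs with radius
# of curvature of a few voxels or more.
surface_area_coarea <- function(mask, spacing) {
  d <- dim(mask)
  pad <- 4L
  big <- array(0, d + 2L * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- as.numeric(mask)
  soft <- gaussian_smooth_3d(big, rep(1, 3))
  grad2 <- array(0, dim(big))
  for (axis in 1:3) {
    dn <- dim(big)[axis]
    idx_p <- c(2:dn, dn)
    idx_m <- c(1, 1:(dn - 1))
    g <- switch(axis,
      (soft[idx_p, , ] - soft[idx_m, , ]),
      (soft[, idx_p, ] - soft[, idx_m, ]),
      (soft[, , idx_p] - soft[, , idx_m])
    ) / (2 * spacing[axis])
    grad2 <- grad2 + g^2
  }
  sum(sqrt(grad2)) * prod(spacing)
}

shape_features <- function(mask, spacing) {
  n <- sum(mask)
  vv <- prod(spacing)
  V <- n * vv
  A <- surface_area_coarea(mask, spacing)
  sph <- (36 * pi * V^2)^(1 / 3) / A

  co <- which(mask, arr.ind = TRUE)
  xyz <- sweep(co, 2, spacing, `*`)
  # boundary voxels (a 6-neighbour outside the mask) suffice for diameters
  d <- dim(mask)
  interior <- mask
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      src <- pmin(pmax(seq_len(d[axis]) + s, 1L), d[axis])
      valid <- seq_len(d[axis]) + s >= 1L & seq_len(d[axis]) + s <= d[axis]
      if (axis == 1) shifted[valid, , ] <- mask[src[valid], , ]
      if (axis == 2) shifted[, valid, ] <- mask[, src[valid], ]
      if (axis == 3) shifted[, , valid] <- mask[, , src[valid]]
      interior <- interior & shifted
    }
  }
  on_boundary <- (mask & !interior)[mask]
  bd <- xyz[on_boundary, , drop = FALSE]
  bco <- co[on_boundary, , drop = FALSE]
  max_pair <- function(pts) {
    if (nrow(pts) < 2) return(0)
    max(stats::dist(pts))
  }
  diam_plane <- function(fix_col, use_cols) {
    m <- 0
    for (lv in unique(bco[, fix_col])) {
      sel <- bco[, fix_col] == lv
      m <- max(m, max_pair(bd[sel, use_cols, drop = FALSE]))
    }
    m
  }
  ev <- if (n > 1) {
    eigen(stats::cov(xyz) * (n - 1) / n, symmetric = TRUE, only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)
  c(
    VoxelVolume = V,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = sph,
    SphericalDisproportion = 1 / sph,
    Maximum3DDiameter = max_pair(bd),
    Maximum2DDiameterSlice = diam_plane(3, 1:2),
    Maximum2DDiameterColumn = diam_plane(2, c(1, 3)),
    Maximum2DDiameterRow = diam_plane(1, 2:3),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}

# Pairs of co-occurring gray levels for one offset; returns the symmetric
# count matrix (ng x ng).
glcm_one_offset <- function(gl_arr, mask, ng, off) {
  d <- dim(gl_arr)
  if (any(d - abs(off) < 1)) return(NULL)   # offset exceeds the array
  x1 <- max(1, 1 - off[1]):min(d[1], d[1] - off[1])
  y1 <- max(1, 1 - off[2]):min(d[2], d[2] - off[2])
  z1 <- max(1, 1 - off[3]):min(d[3], d[3] - off[3])
  a <- gl_arr[x1, y1, z1, drop = FALSE]
  b <- gl_arr[x1 + off[1], y1 + off[2], z1 + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cm <- matrix(0, ng, ng)
  tab <- table(factor(a[ok], levels = 1:ng), factor(b[ok], levels = 1:ng))
  cm <- unclass(tab) + t(unclass(tab))
  cm
}

glcm_features <- function(gl_arr, mask, ng) {
  offs <- direction_offsets_13()
  mats <- list()
  for (k in seq_len(nrow(offs))) {
    m <- glcm_one_offset(gl_arr, mask, ng, offs[k, ])
    if (!is.null(m) && sum(m) > 0) mats[[length(mats) + 1]] <- m / sum(m)
  }
  if (!length(mats)) {
    p <- matrix(0, ng, ng); p[1, 1] <- 1
  } else {
    p <- Reduce(`+`, mats) / length(mats)
  }
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  sigma <- sqrt(sigma2)
  # difference and sum distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  hxy <- entropy2(p)
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- entropy2(pxpy)
  hx <- entropy2(px)
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  offdiag <- abs(i - j) > 0
  c(
    Autocorrelation = sum(i * j * p),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offdiag] / (i[offdiag] - j[offdiag])^2),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = entropy2(p_sum),
    SumSquares = sigma2
  )
}

# Run-length matrix for one direction (counts), rows = gray level, cols =
# run length.  Vectorised over run starts: each start walks forward in
# lock-step until its run breaks.
glrlm_one_direction <- function(gl_arr, ng, off) {
  d <- dim(gl_arr)
  idx <- which(!is.na(gl_arr), arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(0, ng, 1))
  lv <- gl_arr[idx]
  prev <- sweep(idx, 2, off, `-`)
  inb <- prev[, 1] >= 1 & prev[, 1] <= d[1] & prev[, 2] >= 1 &
    prev[, 2] <= d[2] & prev[, 3] >= 1 & prev[, 3] <= d[3]
  gprev <- rep(NA_integer_, nrow(idx))
  gprev[inb] <- gl_arr[prev[inb, , drop = FALSE]]
  is_start <- is.na(gprev) | gprev != lv
  starts <- idx[is_start, , drop = FALSE]
  lv0 <- lv[is_start]
  len <- rep(1L, nrow(starts))
  alive <- rep(TRUE, nrow(starts))
  w <- starts
  while (any(alive)) {
    w <- sweep(w, 2, off, `+`)
    inb <- w[, 1] >= 1 & w[, 1] <= d[1] & w[, 2] >= 1 & w[, 2] <= d[2] &
      w[, 3] >= 1 & w[, 3] <= d[3]
    g <- rep(NA_integer_, nrow(w))
    ok <- alive & inb
    g[ok] <- gl_arr[w[ok, , drop = FALSE]]
    alive <- ok & !is.na(g) & g == lv0
    len[alive] <- len[alive] + 1L
  }
  M <- matrix(0, ng, max(len))
  tab <- table(factor(lv0, levels = 1:ng), factor(len, levels = 1:max(len)))
  M[] <- unclass(tab)
  M
}

glrlm_features <- function(gl_arr, mask, ng) {
  offs <- direction_offsets_13()
  mats <- lapply(seq_len(nrow(offs)), function(k) {
    glrlm_one_direction(gl_arr, ng, offs[k, ])
  })
  rmax <- max(vapply(mats, ncol, integer(1)))
  P <- matrix(0, ng, rmax)
  for (m in mats) P[, seq_len(ncol(m))] <- P[, seq_len(ncol(m))] + m
  P <- P / length(mats)                       # direction-averaged counts
  np <- sum(mask)
  size_weighted_features(P, np, prefix = "Run",
    small = "ShortRunEmphasis", large = "LongRunEmphasis",
    sn_name = "RunLengthNonUniformity", pct_name = "RunPercentage",
    small_pref = "ShortRun", large_pref = "LongRun")
}

glszm_features <- function(gl_arr, mask, ng) {
  P <- zone_matrix(gl_arr, mask, ng)
  np <- sum(mask)
  size_weighted_features(P, np, prefix = "Zone",
    small = "SmallAreaEmphasis", large = "LargeAreaEmphasis",
    sn_name = "SizeZoneNonUniformity", pct_name = "ZonePercentage",
    small_pref = "SmallArea", large_pref = "LargeArea")
}

# Shared feature set for run-length and size-zone matrices: P[i, s], i gray
# level, s run length / zone size.
size_weighted_features <- function(P, np, prefix, small, large, sn_name,
                                   pct_name, small_pref, large_pref) {
  ns <- sum(P)
  if (ns == 0) { P[1, 1] <- 1; ns <- 1 }
  i <- row(P); s <- col(P)
  p <- P / ns
  pg <- rowSums(P)
  psz <- colSums(P)
  mu_g <- sum(row(P) * p)
  mu_s <- sum(col(P) * p)
  out <- c(
    sum(P / s^2) / ns,
    sum(P * s^2) / ns,
    sum(pg^2) / ns,
    sum(pg^2) / ns^2,
    sum(psz^2) / ns,
    sum(psz^2) / ns^2,
    ns / np,
    sum((i - mu_g)^2 * p),
    sum((s - mu_s)^2 * p),
    entropy2(p),
    sum(P / i^2) / ns,
    sum(P * i^2) / ns,
    sum(P / (i^2 * s^2)) / ns,
    sum(P * i^2 / s^2) / ns,
    sum(P * s^2 / i^2) / ns,
    sum(P * i^2 * s^2) / ns
  )
  names(out) <- c(
    small, large,
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    sn_name, paste0(sn_name, "Normalized"), pct_name,
    "GrayLevelVariance", paste0(prefix, "Variance"), paste0(prefix, "Entropy"),
    paste0("LowGrayLevel", prefix, "Emphasis"),
    paste0("HighGrayLevel", prefix, "Emphasis"),
    paste0(small_pref, "LowGrayLevelEmphasis"),
    paste0(small_pref, "HighGrayLevelEmphasis"),
    paste0(large_pref, "LowGrayLevelEmphasis"),
    paste0(large_pref, "HighGrayLevelEmphasis")
  )
  out
}

# Gray-level size-zone matrix: zones are 26-connected components of equal
# gray level within the mask.  Connected components by iterative minimum-
# label propagation over the 26 neighbour shifts.
zone_matrix <- function(gl_arr, mask, ng) {
  d <- dim(gl_arr)
  nbr <- rbind(direction_offsets_13(), -direction_offsets_13())
  lab <- array(NA_real_, d)
  inmask <- !is.na(gl_arr)
  lab[inmask] <- seq_len(sum(inmask))
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(nbr))) {
      off <- nbr[k, ]
      if (any(d - abs(off) < 1)) next
      x1 <- max(1, 1 - off[1]):min(d[1], d[1] - off[1])
      y1 <- max(1, 1 - off[2]):min(d[2], d[2] - off[2])
      z1 <- max(1, 1 - off[3]):min(d[3], d[3] - off[3])
      a_gl <- gl_arr[x1, y1, z1, drop = FALSE]
      b_gl <- gl_arr[x1 + off[1], y1 + off[2], z1 + off[3], drop = FALSE]
      a_lab <- lab[x1, y1, z1, drop = FALSE]
      b_lab <- lab[x1 + off[1], y1 + off[2], z1 + off[3], drop = FALSE]
      upd <- !is.na(a_gl) & !is.na(b_gl) & a_gl == b_gl & b_lab < a_lab
      if (any(upd)) {
        a_lab[upd] <- b_lab[upd]
        lab[x1, y1, z1] <- a_lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  zl <- lab[inmask]
  zg <- gl_arr[inmask]
  sizes <- table(zl)
  level_of <- tapply(zg, zl, function(v) v[1])
  M <- matrix(0, ng, max(sizes))
  for (q in seq_along(sizes)) {
    M[level_of[[q]], sizes[[q]]] <- M[level_of[[q]], sizes[[q]]] + 1
  }
  M
}

gldm_features <- function(gl_arr, mask, ng, alpha = 0) {
  d <- dim(gl_arr)
  nbr <- direction_offsets_13()
  nbr <- rbind(nbr, -nbr)
  idx <- which(!is.na(gl_arr), arr.ind = TRUE)
  dep <- integer(nrow(idx))
  lv <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    g0 <- gl_arr[v[1], v[2], v[3]]
    cnt <- 0L
    for (k in seq_len(nrow(nbr))) {
      w <- v + nbr[k, ]
      if (any(w < 1) || any(w > d)) next
      g <- gl_arr[w[1], w[2], w[3]]
      if (!is.na(g) && abs(g - g0) <= alpha) cnt <- cnt + 1L
    }
    dep[r] <- cnt + 1L      # 1-based dependence bin
    lv[r] <- g0
  }
  P <- matrix(0, ng, max(dep))
  for (r in seq_along(dep)) P[lv[r], dep[r]] <- P[lv[r], dep[r]] + 1
  nz <- sum(P)
  i <- row(P); k <- col(P)
  p <- P / nz
  pg <- rowSums(P)
  pd <- colSums(P)
  mu_g <- sum(i * p)
  mu_d <- sum(k * p)
  c(
    SmallDependenceEmphasis = sum(P / k^2) / nz,
    LargeDependenceEmphasis = sum(P * k^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum((i - mu_g)^2 * p),
    DependenceVariance = sum((k - mu_d)^2 * p),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * k^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / k^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * k^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * k^2) / nz
  )
}

#' Lesion-mean value of a parameter map
#'
#' The arithmetic mean over finite masked voxels — the "mean diffusion
#' metric" of each map (mADC, mD, mD*, mf, mDDC, m-alpha, mK).
#'
#' @param map A [parameter_map()] or 3D array.
#' @param mask Non-empty logical 3D array.
#' @return Scalar mean.
#' @export
mean_metric <- function(map, mask) {
  vals <- if (inherits(map, "parameter_map")) map$values else map
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- vals[mask]
  mean(v[is.finite(v)])
}

#' All nine lesion-mean diffusion metrics from a map suite
#'
#' @param suite A `map_suite` from [generate_map_suite()].
#' @param mask Lesion mask.
#' @return A one-row tibble with columns `mADC_all-b`, `mADC_0-1000`, `mD`,
#'   `mD*`, `mf`, `mDDC`, `malpha`, `mK`, `mD_kurt` (those present in the
#'   suite).
#' @export
mean_metrics <- function(suite, mask) {
  stopifnot(inherits(suite, "map_suite"))
  vals <- lapply(suite$maps, mean_metric, mask = mask)
  names(vals) <- paste0("m", sub("^alpha$", "alpha", names(vals)))
  tibble::as_tibble(vals)
}

#' Per-map feature extraction across a whole map suite
#'
#' @param suite A `map_suite`.
#' @param mask Lesion mask.
#' @param n_bins Bins for gray-level discretisation.
#' @return A long tibble with columns `map`, `group`, `feature`, `value`
#'   (100 rows per map).
#' @export
extract_map_features <- function(suite, mask, n_bins = 25) {
  stopifnot(inherits(suite, "map_suite"))
  purrr::map_dfr(names(suite$maps), function(nm) {
    fv <- extract_features(suite$maps[[nm]], mask,
                           bin_width = map_bin_width(suite$maps[[nm]], n_bins))
    dplyr::mutate(fv, map = nm, .before = 1)
  })
}

#' Widen long feature tables into a subject-by-feature matrix
#'
#' Column names follow `<map>__<group>__<feature>`.
#'
#' @param features_long Tibble with columns `subject_id`, `map`, `group`,
#'   `feature`, `value` (stack of [extract_map_features()] outputs).
#' @return A wide tibble, one row per subject.
#' @export
feature_matrix <- function(features_long) {
  wide <- tidyr::pivot_wider(
    features_long,
    id_cols = "subject_id",
    names_from = c("map", "group", "feature"),
    values_from = "value", names_sep = "__"
  )
  wide
}

#' Inter-reader reproducibility of radiomics features (ICC)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation — ICC(2,1) — per feature, between two feature matrices
#' extracted from the same subjects with two segmentations.
#'
#' @param readings_a,readings_b Wide feature tibbles from
#'   [feature_matrix()] with matching `subject_id` and feature columns.
#' @param threshold Reproducibility flag threshold (default 0.80).
#' @return A tibble with columns `feature`, `icc`, `reproducible`; features
#'   with zero between-subject variance get `NA` icc and are flagged
#'   non-reproducible.
#' @export
icc <- function(readings_a, readings_b, threshold = 0.80) {
  stopifnot(identical(readings_a$subject_id, readings_b$subject_id))
  feats <- setdiff(names(readings_a), "subject_id")
  stopifnot(all(feats %in% names(readings_b)))
  icc_vals <- vapply(feats, function(fc) {
    icc21(readings_a[[fc]], readings_b[[fc]])
  }, numeric(1))
  icc_vals <- unname(icc_vals)
  tibble::tibble(
    feature = feats, icc = icc_vals,
    reproducible = !is.na(icc_vals) & icc_vals > threshold
  )
}

#' @rdname icc
#' @param x,y Paired numeric readings (one per subject).
#' @export
icc21 <- function(x, y) {
  n <- length(x)
  k <- 2
  dat <- cbind(x, y)
  if (stats::var(rowMeans(dat)) < .Machine$double.eps) return(NA_real_)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
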