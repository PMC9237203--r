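# First-order features: 2 local-intensity + 18 intensity statistics +
# 23 intensity-histogram + 7 intensity-volume-histogram = 50 per region.
# Percentiles use R's default (type 7) quantile convention throughout.

moments_about_mean <- function(x) {
  m <- mean(x)
  c(m2 = mean((x - m)^2), m3 = mean((x - m)^3), m4 = mean((x - m)^4))
}

#' Intensity-based statistical features
#'
#' Eighteen statistics of the raw VOI intensities. Degenerate conventions
#' for constant input: skewness and (excess) kurtosis are 0; the
#' coefficient of variation is 0 when the mean is 0; the quartile
#' coefficient of dispersion is 0 when `p75 + p25 = 0`.
#'
#' @param x numeric vector of VOI intensities.
#' @return Named numeric of length 18 (tags `stat_*`).
#' @export
stat_features <- function(x) {
  m <- mean(x)
  mm <- moments_about_mean(x)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  rx <- x[x >= q[1] & x <= q[4]]
  c(stat_mean = m,
    stat_var = mm[["m2"]],
    stat_skew = if (mm[["m2"]] > 0) mm[["m3"]] / mm[["m2"]]^1.5 else 0,
    stat_kurt = if (mm[["m2"]] > 0) mm[["m4"]] / mm[["m2"]]^2 - 3 else 0,
    stat_median = median(x),
    stat_min = min(x),
    stat_p10 = q[1],
    stat_p90 = q[4],
    stat_max = max(x),
    stat_iqr = q[3] - q[2],
    stat_range = max(x) - min(x),
    stat_mad = mean(abs(x - m)),
    stat_rmad = mean(abs(rx - mean(rx))),
    stat_medad = mean(abs(x - median(x))),
    stat_cov = if (m != 0) sqrt(mm[["m2"]]) / m else 0,
    stat_qcod = if ((q[3] + q[2]) != 0) (q[3] - q[2]) / (q[3] + q[2]) else 0,
    stat_energy = sum(x^2),
    stat_rms = sqrt(mean(x^2)))
}

#' Intensity-histogram features
#'
#' Twenty-three features of the discretised grey levels (1..n_bins).
#' The mode takes the lowest level among ties; histogram gradients are
#' central differences with one-sided differences at the histogram ends.
#'
#' @param dvoi a `discretized_voi`.
#' @return Named numeric of length 23 (tags `ih_*`).
#' @export
ih_features <- function(dvoi) {
  d <- as.numeric(dvoi$levels)
  ng <- dvoi$n_bins
  h <- tabulate(dvoi$levels, nbins = ng)
  p <- h / sum(h)
  lev <- seq_len(ng)
  m <- sum(p * lev)
  mu2 <- sum(p * (lev - m)^2)
  mu3 <- sum(p * (lev - m)^3)
  mu4 <- sum(p * (lev - m)^4)
  q <- quantile(d, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  rd <- d[d >= q[1] & d <= q[4]]
  grad <- if (ng >= 2) {
    g <- (c(h[-1], 0) - c(0, h[-ng])) / 2
    g[1] <- h[2] - h[1]
    g[ng] <- h[ng] - h[ng - 1]
    g
  } else 0
  c(ih_mean = m,
    ih_var = mu2,
    ih_skew = if (mu2 > 0) mu3 / mu2^1.5 else 0,
    ih_kurt = if (mu2 > 0) mu4 / mu2^2 - 3 else 0,
    ih_median = median(d),
    ih_min = min(d),
    ih_p10 = q[1],
    ih_p90 = q[4],
    ih_max = max(d),
    ih_mode = which.max(h),
    ih_iqr = q[3] - q[2],
    ih_range = max(d) - min(d),
    ih_mad = mean(abs(d - mean(d))),
    ih_rmad = mean(abs(rd - mean(rd))),
    ih_medad = mean(abs(d - median(d))),
    ih_cov = if (m != 0) sqrt(mu2) / m else 0,
    ih_qcod = if ((q[3] + q[2]) != 0) (q[3] - q[2]) / (q[3] + q[2]) else 0,
    ih_entropy = -sum(p[p > 0] * log2(p[p > 0])),
    ih_uniformity = sum(p^2),
    ih_max_grad = max(grad),
    ih_max_grad_g = which.max(grad),
    ih_min_grad = min(grad),
    ih_min_grad_g = which.min(grad))
}

#' Intensity-volume-histogram features
#'
#' Computed on a 1000-point threshold grid between the VOI minimum and
#' maximum. `v10`/`v90` are the volume fractions with at least 10%/90%
#' fractional intensity; `i10`/`i90` are the lowest intensities covering at
#' most 10%/90% of the volume; `auc` is the mean volume fraction over the
#' grid. A constant VOI yields `v10 = v90 = 1` and `i10 = i90 = value`.
#'
#' @param x numeric vector of VOI intensities.
#' @param n_grid threshold-grid resolution.
#' @return Named numeric of length 7 (tags `ivh_*`).
#' @export
ivh_features <- function(x, n_grid = 1000L) {
  rng <- range(x)
  if (rng[2] <= rng[1])
    return(c(ivh_v10 = 1, ivh_v90 = 1, ivh_i10 = rng[1], ivh_i90 = rng[1],
             ivh_v10_minus_v90 = 0, ivh_i10_minus_i90 = 0, ivh_auc = 1))
  gam <- seq(rng[1], rng[2], length.out = n_grid)
  frac <- (gam - rng[1]) / (rng[2] - rng[1])
  xs <- sort(x)
  nu <- 1 - (findInterval(gam, xs, left.open = TRUE)) / length(x)
  v_at <- function(f) nu[which(frac >= f)[1]]
  i_at <- function(v) {
    k <- which(nu <= v)
    if (length(k) == 0L) rng[2] else gam[k[1]]
  }
  v10 <- v_at(0.10); v90 <- v_at(0.90)
  i10 <- i_at(0.10); i90 <- i_at(0.90)
  c(ivh_v10 = v10, ivh_v90 = v90, ivh_i10 = i10, ivh_i90 = i90,
    ivh_v10_minus_v90 = v10 - v90, ivh_i10_minus_i90 = i10 - i90,
    ivh_auc = mean(nu))
}

# Integer voxel offsets of the 1 cm^3 sphere (radius ~6.204 mm) in world
# units for the given spacing.
sphere_offsets <- function(spacing) {
  radius <- (3 / (4 * pi) * 1000)^(1 / 3)  # mm
  rv <- ceiling(radius / spacing)
  off <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2],
                               dz = -rv[3]:rv[3]))
  keep <- sqrt((off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
                 (off[, 3] * spacing[3])^2) <= radius
  off[keep, , drop = FALSE]
}

#' Local-intensity features
#'
#' Intensity peaks over a 1 cm^3 spherical neighbourhood. The local peak is
#' the highest sphere mean among voxels of maximal intensity; the global
#' peak is the maximum sphere mean over all VOI voxels. When the companion
#' volume is supplied, sphere means include voxels outside the VOI (IBSI
#' convention); otherwise only VOI voxels are available and the means are
#' over the in-VOI part of the sphere.
#'
#' @param voi a `voi_sample`.
#' @param volume optional companion [volume_grid] for context outside the
#'   VOI.
#' @return Named numeric of length 2 (tags `loc_*`).
#' @export
local_intensity_features <- function(voi, volume = NULL) {
  off <- sphere_offsets(voi$spacing)
  co <- voi$coords
  n <- nrow(co)
  if (is.null(volume)) {
    lo <- apply(co, 2, min); hi <- apply(co, 2, max)
    d <- hi - lo + 1L
    arr <- array(NA_real_, dim = d)
    arr[cbind(co[, 1], co[, 2], co[, 3]) - rep(lo, each = n) + 1L] <-
      voi$intensities
    base <- co - rep(lo, each = n)
  } else {
    arr <- volume$values
    d <- dim(arr)
    base <- co
  }
  acc <- numeric(n); cnt <- numeric(n)
  for (k in seq_len(nrow(off))) {
    xx <- base[, 1] + off[k, 1]; yy <- base[, 2] + off[k, 2]
    zz <- base[, 3] + off[k, 3]
    ok <- xx >= 0 & xx < d[1] & yy >= 0 & yy < d[2] & zz >= 0 & zz < d[3]
    v <- rep(NA_real_, n)
    v[ok] <- arr[cbind(xx[ok], yy[ok], zz[ok]) + 1L]
    use <- !is.na(v)
    acc[use] <- acc[use] + v[use]
    cnt[use] <- cnt[use] + 1
  }
  sm <- acc / cnt
  peak_global <- max(sm)
  at_max <- which(voi$intensities == max(voi$intensities))
  c(loc_peak_local = max(sm[at_max]), loc_peak_global = peak_global)
}

#' All first-order features for one VOI
#'
#' @param voi a `voi_sample`.
#' @param dvoi its `discretized_voi` (for the histogram family).
#' @param volume optional companion volume for local-intensity context.
#' @return Named numeric of length 50.
#' @export
intensity_features <- function(voi, dvoi, volume = NULL) {
  c(local_intensity_features(voi, volume),
    stat_features(voi$intensities),
    ih_features(dvoi),
    ivh_features(voi$intensities))
}
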