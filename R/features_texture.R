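# Texture features per IBSI definitions. GLCM and GLRLM are reported under
# two 3D aggregations — per-direction matrices with feature averaging
# (suffix `_3D_avg`) and a single merged matrix (`_3D_mrg`) — giving
# 25 x 2 = 50 GLCM and 16 x 2 = 32 GLRLM features. The zone, distance,
# grey-tone-difference and dependence families are single 3D matrices
# (suffix `_3D`).

GLCM_TAGS <- c("cm_joint_max", "cm_joint_avg", "cm_joint_var",
               "cm_joint_entr", "cm_diff_avg", "cm_diff_var", "cm_diff_entr",
               "cm_sum_avg", "cm_sum_var", "cm_sum_entr", "cm_energy",
               "cm_contrast", "cm_dissimilarity", "cm_inv_diff",
               "cm_inv_diff_norm", "cm_inv_diff_mom", "cm_inv_diff_mom_norm",
               "cm_inv_var", "cm_corr", "cm_auto_corr", "cm_clust_tend",
               "cm_clust_shade", "cm_clust_prom", "cm_info_corr1",
               "cm_info_corr2")

# cached level-index matrices per grey-level count
.glcm_cache <- new.env(parent = emptyenv())

glcm_geometry <- function(ng) {
  key <- as.character(ng)
  g <- .glcm_cache[[key]]
  if (is.null(g)) {
    I <- matrix(rep(seq_len(ng), ng), ng, ng)
    J <- t(I)
    g <- list(I = I, J = J, AD = abs(I - J), SU = I + J)
    .glcm_cache[[key]] <- g
  }
  g
}

# aggregate matrix weights by an integer grouping (values 1..nbins)
group_sums <- function(w, gidx, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, gidx)
  out[as.integer(rownames(agg))] <- agg
  out
}

glcm_features_one <- function(M) {
  tot <- sum(M)
  if (tot == 0) {
    out <- setNames(numeric(length(GLCM_TAGS)), GLCM_TAGS)
    out["cm_joint_max"] <- 1; out["cm_energy"] <- 1; out["cm_corr"] <- 1
    out["cm_inv_diff"] <- 1; out["cm_inv_diff_norm"] <- 1
    out["cm_inv_diff_mom"] <- 1; out["cm_inv_diff_mom_norm"] <- 1
    out["cm_info_corr2"] <- 0
    return(out)
  }
  ng <- nrow(M)
  P <- M / tot
  geo <- glcm_geometry(ng)
  I <- geo$I; J <- geo$J
  px <- rowSums(P)
  lev <- seq_len(ng)
  mu <- sum(lev * px)
  sig2 <- sum(lev^2 * px) - mu^2
  dk <- 0:(ng - 1)
  pd <- group_sums(c(P), c(geo$AD) + 1L, ng)
  sk <- 2:(2 * ng)
  ps <- group_sums(c(P), c(geo$SU) - 1L, 2 * ng - 1)
  da <- sum(dk * pd); sa <- sum(sk * ps)
  nz <- P > 0
  HXY <- -sum(P[nz] * log2(P[nz]))
  pxi <- px[I]; pxj <- px[J]
  ok <- nz & pxi > 0 & pxj > 0
  HXY1 <- -sum(P[ok] * log2(pxi[ok] * pxj[ok]))
  qq <- outer(px, px)
  qnz <- qq > 0
  HXY2 <- -sum(qq[qnz] * log2(qq[qnz]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  c(cm_joint_max = max(P),
    cm_joint_avg = sum(I * P),
    cm_joint_var = sum((I - mu)^2 * P),
    cm_joint_entr = HXY,
    cm_diff_avg = da,
    cm_diff_var = sum((dk - da)^2 * pd),
    cm_diff_entr = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    cm_sum_avg = sa,
    cm_sum_var = sum((sk - sa)^2 * ps),
    cm_sum_entr = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    cm_energy = sum(P^2),
    cm_contrast = sum((I - J)^2 * P),
    cm_dissimilarity = sum(abs(I - J) * P),
    cm_inv_diff = sum(P / (1 + abs(I - J))),
    cm_inv_diff_norm = sum(P / (1 + abs(I - J) / ng)),
    cm_inv_diff_mom = sum(P / (1 + (I - J)^2)),
    cm_inv_diff_mom_norm = sum(P / (1 + (I - J)^2 / ng^2)),
    cm_inv_var = sum(P[I != J] / (I[I != J] - J[I != J])^2),
    cm_corr = if (sig2 > 0) (sum(I * J * P) - mu^2) / sig2 else 1,
    cm_auto_corr = sum(I * J * P),
    cm_clust_tend = sum((I + J - 2 * mu)^2 * P),
    cm_clust_shade = sum((I + J - 2 * mu)^3 * P),
    cm_clust_prom = sum((I + J - 2 * mu)^4 * P),
    cm_info_corr1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    cm_info_corr2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))))
}

#' GLCM features (50)
#'
#' Twenty-five co-occurrence features under the direction-averaged and
#' merged-matrix 3D aggregations.
#'
#' @param dvoi a `discretized_voi`.
#' @return Named numeric of length 50.
#' @export
glcm_features <- function(dvoi) {
  A <- glcm_matrices(dvoi)
  per <- apply(A, 3, glcm_features_one)
  counts <- apply(A, 3, sum)
  use <- counts > 0
  avg <- if (any(use)) rowMeans(per[, use, drop = FALSE]) else per[, 1]
  merged <- glcm_features_one(rowSums(A, dims = 2))
  c(setNames(avg, paste0(GLCM_TAGS, "_3D_avg")),
    setNames(merged, paste0(GLCM_TAGS, "_3D_mrg")))
}

RLM_TAGS <- c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge",
              "lrhge", "glnu", "glnu_norm", "rlnu", "rlnu_norm", "r_perc",
              "gl_var", "rl_var", "rl_entr")

# Shared engine for the run-length-style families (runs / zone sizes /
# zone distances): matrix rows are grey levels, columns the size axis.
rl_style_features <- function(M, nv, prefix, axis_tags) {
  ns <- sum(M)
  ng <- nrow(M); nl <- ncol(M)
  g <- seq_len(ng); l <- seq_len(nl)
  rg <- rowSums(M); rl <- colSums(M)
  P <- M / ns
  mug <- sum(row(M) * P); mul <- sum(col(M) * P)
  vals <- c(
    sum(rl / l^2) / ns,
    sum(rl * l^2) / ns,
    sum(rg / g^2) / ns,
    sum(rg * g^2) / ns,
    sum(M / outer(g^2, l^2)) / ns,
    sum(M * outer(g^2, 1 / l^2)) / ns,
    sum(M * outer(1 / g^2, l^2)) / ns,
    sum(M * outer(g^2, l^2)) / ns,
    sum(rg^2) / ns,
    sum(rg^2) / ns^2,
    sum(rl^2) / ns,
    sum(rl^2) / ns^2,
    ns / nv,
    sum((row(M) - mug)^2 * P),
    sum((col(M) - mul)^2 * P),
    -sum(P[P > 0] * log2(P[P > 0])))
  setNames(vals, paste0(prefix, axis_tags))
}

#' GLRLM features (32)
#'
#' Sixteen run-length features under the direction-averaged and merged 3D
#' aggregations. Run percentage in the merged aggregation is normalised by
#' voxel count times the number of directions.
#'
#' @param dvoi a `discretized_voi`.
#' @return Named numeric of length 32.
#' @export
glrlm_features <- function(dvoi) {
  A <- glrlm_matrices(dvoi)
  nv <- length(dvoi$levels)
  per <- apply(A, 3, rl_style_features, nv = nv, prefix = "rlm_",
               axis_tags = RLM_TAGS)
  avg <- rowMeans(per)
  merged <- rl_style_features(rowSums(A, dims = 2), nv * dim(A)[3], "rlm_",
                              RLM_TAGS)
  c(setNames(avg, paste0("rlm_", RLM_TAGS, "_3D_avg")),
    setNames(merged, paste0("rlm_", RLM_TAGS, "_3D_mrg")))
}

SZM_TAGS <- c("sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge",
              "lzhge", "glnu", "glnu_norm", "zsnu", "zsnu_norm", "z_perc",
              "gl_var", "zs_var", "zs_entr")

#' GLSZM features (16)
#'
#' @param dvoi a `discretized_voi`.
#' @return Named numeric of length 16, suffix `_3D` (includes
#'   `szm_lzlge_3D`).
#' @export
glszm_features <- function(dvoi) {
  M <- glszm_matrix(dvoi)
  f <- rl_style_features(M, length(dvoi$levels), "szm_", SZM_TAGS)
  setNames(f, paste0("szm_", SZM_TAGS, "_3D"))
}

DZM_TAGS <- c("sde", "lde", "lgze", "hgze", "sdlge", "sdhge", "ldlge",
              "ldhge", "glnu", "glnu_norm", "zdnu", "zdnu_norm", "z_perc",
              "gl_var", "zd_var", "zd_entr")

#' GLDZM features (16)
#'
#' @param dvoi a `discretized_voi`.
#' @return Named numeric of length 16, suffix `_3D` (includes
#'   `dzm_zdnu_3D`).
#' @export
gldzm_features <- function(dvoi) {
  M <- gldzm_matrix(dvoi)
  f <- rl_style_features(M, length(dvoi$levels), "dzm_", DZM_TAGS)
  setNames(f, paste0("dzm_", DZM_TAGS, "_3D"))
}

#' NGTDM features (5)
#'
#' Coarseness is capped at 1e6 when the weighted sum of grey-tone
#' differences is zero (constant VOI); contrast, busyness and strength are
#' 0 in their degenerate cases.
#'
#' @param dvoi a `discretized_voi`.
#' @return Named numeric of length 5, suffix `_3D`.
#' @export
ngtdm_features <- function(dvoi) {
  tab <- ngtdm_table(dvoi)
  n <- tab$n; s <- tab$s
  N <- sum(n)
  p <- n / N
  pres <- which(p > 0)
  ngp <- length(pres)
  ps <- sum(p * s)
  i <- pres
  pij_d2 <- if (ngp > 1)
    sum(outer(p[i], p[i]) * outer(i, i, function(a, b) (a - b)^2)) else 0
  busy_den <- sum(abs(outer(i * p[i], i * p[i], `-`)))
  compl <- 0
  if (ngp >= 1) {
    pi_ <- p[i]; si_ <- s[i]
    A <- outer(pi_, pi_, `+`)
    B <- outer(pi_ * si_, pi_ * si_, `+`)
    W <- abs(outer(i, i, `-`))
    compl <- sum(W * B / A) / N
  }
  c(ngt_coarseness_3D = if (ps > 0) min(1 / ps, 1e6) else 1e6,
    ngt_contrast_3D = if (ngp > 1) pij_d2 / (ngp * (ngp - 1)) * sum(s) / N
    else 0,
    ngt_busyness_3D = if (busy_den > 0) ps / busy_den else 0,
    ngt_complexity_3D = compl,
    ngt_strength_3D = if (sum(s) > 0)
      sum(outer(p[i], p[i], `+`) * outer(i, i, function(a, b) (a - b)^2)) /
      sum(s) else 0)
}

NGL_TAGS <- c("lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge",
              "hdhge", "glnu", "glnu_norm", "dcnu", "dcnu_norm", "dc_perc",
              "gl_var", "dc_var", "dc_entr", "dc_energy")

#' NGLDM features (17)
#'
#' Dependence counts k = 0..26 enter the emphasis weights as j = k + 1
#' (so an isolated voxel has dependence index 1). Includes
#' `ngl_dcnu_3D` (dependence count non-uniformity, sum over dependence
#' columns of squared totals divided by voxel count) and its normalised
#' variant `ngl_dcnu_norm_3D` (divided by voxel count squared).
#'
#' @param dvoi a `discretized_voi`.
#' @param alpha dependence tolerance in grey levels.
#' @return Named numeric of length 17, suffix `_3D`.
#' @export
ngldm_features <- function(dvoi, alpha = 0L) {
  M <- ngldm_matrix(dvoi, alpha)
  ns <- sum(M)
  ng <- nrow(M)
  g <- seq_len(ng)
  j <- seq_len(ncol(M))  # dependence count + 1
  rg <- rowSums(M); cj <- colSums(M)
  P <- M / ns
  mug <- sum(row(M) * P); muj <- sum(col(M) * P)
  vals <- c(
    sum(cj / j^2) / ns,
    sum(cj * j^2) / ns,
    sum(rg / g^2) / ns,
    sum(rg * g^2) / ns,
    sum(M / outer(g^2, j^2)) / ns,
    sum(M * outer(1 / g^2, j^2)) / ns,
    sum(M * outer(g^2, 1 / j^2)) / ns,
    sum(M * outer(g^2, j^2)) / ns,
    sum(rg^2) / ns,
    sum(rg^2) / ns^2,
    sum(cj^2) / ns,
    sum(cj^2) / ns^2,
    ns / length(dvoi$levels),
    sum((row(M) - mug)^2 * P),
    sum((col(M) - muj)^2 * P),
    -sum(P[P > 0] * log2(P[P > 0])),
    sum(P^2))
  setNames(vals, paste0("ngl_", NGL_TAGS, "_3D"))
}
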