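# Texture-matrix construction. All families use 26-connectivity
# (Chebyshev distance 1). GLCM and GLRLM are built per direction over the
# 13 unique 3D direction vectors; the zone/neighbourhood families are
# single 3D matrices.

#' Grey-level co-occurrence matrices
#'
#' Counts symmetrised co-occurrences of grey-level pairs at Chebyshev
#' distance 1 along each of the 13 unique 3D directions.
#'
#' @param dvoi a `discretized_voi`.
#' @return Integer array `n_bins x n_bins x 13`; each slice is symmetric.
#' @export
glcm_matrices <- function(dvoi) {
  arr <- level_array(dvoi)
  cpp_glcm(as.integer(arr), dim(arr), dvoi$n_bins)
}

#' Grey-level run-length matrices
#'
#' Maximal runs of equal grey level along each of the 13 unique 3D
#' directions; a non-VOI voxel breaks a run. For every direction
#' `sum(counts * run_length)` equals the VOI voxel count.
#'
#' @param dvoi a `discretized_voi`.
#' @return Integer array `n_bins x max_run_length x 13`.
#' @export
glrlm_matrices <- function(dvoi) {
  arr <- level_array(dvoi)
  cpp_glrlm(as.integer(arr), dim(arr), dvoi$n_bins)
}

# 26-connected equal-level zones; returns per-voxel zone id on the
# bounding box (0 outside the VOI).
zone_label_array <- function(dvoi) {
  arr <- level_array(dvoi)
  cpp_zone_labels(as.integer(arr), dim(arr))
}

#' Grey-level size-zone matrix
#'
#' Zones are 26-connected components of equal grey level; entry (g, s) is
#' the number of zones of level g and size s voxels.
#'
#' @param dvoi a `discretized_voi`.
#' @return Integer matrix `n_bins x max_zone_size`.
#' @export
glszm_matrix <- function(dvoi) {
  arr <- level_array(dvoi)
  zl <- cpp_zone_labels(as.integer(arr), dim(arr))
  inv <- zl > 0
  zid <- zl[inv]
  glev <- arr[inv]
  zsize <- tabulate(zid)
  zlev <- glev[match(seq_along(zsize), zid)]
  M <- matrix(0L, dvoi$n_bins, max(zsize))
  for (i in seq_along(zsize))
    M[zlev[i], zsize[i]] <- M[zlev[i], zsize[i]] + 1L
  M
}

#' Grey-level distance-zone matrix
#'
#' Same zones as [glszm_matrix]; the distance of a zone is the minimum over
#' its voxels of the Chebyshev distance to the VOI border (voxels outside
#' the VOI or the image count as border; minimum distance 1). Entry (g, d)
#' counts zones of level g at distance d.
#'
#' @param dvoi a `discretized_voi`.
#' @return Integer matrix `n_bins x max_zone_distance`.
#' @export
gldzm_matrix <- function(dvoi) {
  arr <- level_array(dvoi)
  zl <- cpp_zone_labels(as.integer(arr), dim(arr))
  dist <- cpp_cheb_border_dist(as.integer(arr), dim(arr))
  inv <- zl > 0
  zid <- zl[inv]
  glev <- arr[inv]
  dv <- dist[inv]
  nz <- max(zid)
  zdist <- vapply(seq_len(nz), function(z) min(dv[zid == z]), numeric(1))
  zlev <- glev[match(seq_len(nz), zid)]
  M <- matrix(0L, dvoi$n_bins, max(zdist))
  for (i in seq_len(nz))
    M[zlev[i], zdist[i]] <- M[zlev[i], zdist[i]] + 1L
  M
}

#' Neighbourhood grey-tone difference accumulators
#'
#' For each grey level i: `n_i` = number of VOI voxels of level i that have
#' at least one in-VOI 26-neighbour, and `s_i` = sum over those voxels of
#' the absolute difference between i and the mean level of the in-VOI
#' neighbours.
#'
#' @param dvoi a `discretized_voi`.
#' @return List with numeric vectors `n` and `s` of length `n_bins`.
#' @export
ngtdm_table <- function(dvoi) {
  arr <- level_array(dvoi)
  cpp_ngtdm(as.integer(arr), dim(arr), dvoi$n_bins)
}

#' Neighbouring grey-level dependence matrix
#'
#' The dependence count of a voxel is the number of in-VOI 26-neighbours
#' whose level differs by at most `alpha` (coarseness parameter, default 0).
#' Entry (g, k+1) counts voxels of level g with dependence count k.
#'
#' @param dvoi a `discretized_voi`.
#' @param alpha dependence tolerance in grey levels.
#' @return Integer matrix `n_bins x 27` (dependence counts 0..26).
#' @export
ngldm_matrix <- function(dvoi, alpha = 0L) {
  arr <- level_array(dvoi)
  cpp_ngldm(as.integer(arr), dim(arr), dvoi$n_bins, as.integer(alpha))
}
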