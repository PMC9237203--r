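#' Radiomics configuration
#'
#' @param n_bins fixed-bin-number discretisation levels (default 64).
#' @param alpha NGLDM dependence tolerance in grey levels (default 0).
#' @param bilateral `"mean"` to average left/right feature values
#'   (default), `"pooled"` to merge L+R voxels into one VOI first.
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(n_bins = 64L, alpha = 0L,
                             bilateral = c("mean", "pooled")) {
  bilateral <- match.arg(bilateral)
  stopifnot(n_bins >= 2, alpha >= 0)
  structure(list(n_bins = as.integer(n_bins), alpha = as.integer(alpha),
                 bilateral = bilateral),
            class = "radiomics_config")
}

#' The 186 per-region feature tags, in canonical order
#'
#' @return Character vector of length 186.
#' @export
region_feature_tags <- function() {
  c("loc_peak_local", "loc_peak_global",
    paste0("stat_", c("mean", "var", "skew", "kurt", "median", "min", "p10",
                      "p90", "max", "iqr", "range", "mad", "rmad", "medad",
                      "cov", "qcod", "energy", "rms")),
    paste0("ih_", c("mean", "var", "skew", "kurt", "median", "min", "p10",
                    "p90", "max", "mode", "iqr", "range", "mad", "rmad",
                    "medad", "cov", "qcod", "entropy", "uniformity",
                    "max_grad", "max_grad_g", "min_grad", "min_grad_g")),
    paste0("ivh_", c("v10", "v90", "i10", "i90", "v10_minus_v90",
                     "i10_minus_i90", "auc")),
    paste0(rep(GLCM_TAGS, 2), rep(c("_3D_avg", "_3D_mrg"), each = 25)),
    paste0("rlm_", rep(RLM_TAGS, 2), rep(c("_3D_avg", "_3D_mrg"), each = 16)),
    paste0("szm_", SZM_TAGS, "_3D"),
    paste0("dzm_", DZM_TAGS, "_3D"),
    paste0("ngt_", c("coarseness", "contrast", "busyness", "complexity",
                     "strength"), "_3D"),
    paste0("ngl_", NGL_TAGS, "_3D"))
}

FEATURE_BLOCKS <- c("caudate", "putamen", "pallidum", "CRputamen",
                    "CRpallidum")

#' The full 930-name feature schema
#'
#' 186 tags for each of the caudate, putamen and pallidum blocks plus the
#' elementwise caudate/putamen and caudate/pallidum ratio blocks
#' (`CRputamen`, `CRpallidum`).
#'
#' @return Character vector of length 930 (`<tag>_<block>`).
#' @export
feature_vector_names <- function() {
  tags <- region_feature_tags()
  unlist(lapply(FEATURE_BLOCKS, function(b) paste0(tags, "_", b)),
         use.names = FALSE)
}

#' Block membership of feature names
#'
#' @param x feature names from the [feature_vector_names] schema.
#' @return Character vector: `"caudate"`, `"putamen"`, `"pallidum"`,
#'   `"CRputamen"` or `"CRpallidum"` per name.
#' @export
feature_block <- function(x) {
  out <- rep(NA_character_, length(x))
  for (b in c("CRputamen", "CRpallidum", "caudate", "putamen", "pallidum"))
    out[is.na(out) & endsWith(x, paste0("_", b))] <- b
  out
}

#' All 186 features for one VOI
#'
#' @param voi a `voi_sample`.
#' @param config a [radiomics_config].
#' @param volume optional companion [volume_grid] for local-intensity
#'   context.
#' @return Named numeric of length 186, in [region_feature_tags] order.
#' @export
region_features <- function(voi, config = radiomics_config(),
                            volume = NULL) {
  if (length(voi$intensities) == 0L) stop("empty VOI", call. = FALSE)
  dvoi <- discretize(voi, config$n_bins)
  out <- c(intensity_features(voi, dvoi, volume),
           glcm_features(dvoi),
           glrlm_features(dvoi),
           glszm_features(dvoi),
           gldzm_features(dvoi),
           ngtdm_features(dvoi),
           ngldm_features(dvoi, config$alpha))
  out[region_feature_tags()]
}

pool_vois <- function(a, b) {
  structure(list(region = a$region,
                 coords = rbind(a$coords, b$coords),
                 intensities = c(a$intensities, b$intensities),
                 spacing = a$spacing),
            class = "voi_sample")
}

#' The 930-dimensional per-subject feature vector
#'
#' For each striatal region the 186 features are computed per hemisphere
#' and combined bilaterally (feature-level mean of L and R by default);
#' the two ratio blocks are elementwise ratios of the bilateral caudate
#' block to the bilateral putamen and pallidum blocks. Ratio entries whose
#' denominator is within machine epsilon of zero are recorded as `NA`
#' (undefined) and excluded from downstream selection.
#'
#' @param subject a `subject_record` or [volume_grid].
#' @param atlas an [atlas_mask].
#' @param config a [radiomics_config].
#' @return Named numeric of length 930, in [feature_vector_names] order.
#' @export
feature_vector <- function(subject, atlas, config = radiomics_config()) {
  volume <- if (inherits(subject, "subject_record")) subject$volume else
    subject
  blocks <- lapply(c("caudate", "putamen", "pallidum"), function(rn) {
    l <- extract_voi(volume, atlas, paste0(rn, "_L"))
    r <- extract_voi(volume, atlas, paste0(rn, "_R"))
    if (config$bilateral == "mean") {
      (region_features(l, config, volume) +
         region_features(r, config, volume)) / 2
    } else {
      region_features(pool_vois(l, r), config, volume)
    }
  })
  names(blocks) <- c("caudate", "putamen", "pallidum")
  ratio <- function(num, den) {
    out <- num / den
    out[abs(den) < .Machine$double.eps] <- NA_real_
    out
  }
  vals <- c(blocks$caudate, blocks$putamen, blocks$pallidum,
            ratio(blocks$caudate, blocks$putamen),
            ratio(blocks$caudate, blocks$pallidum))
  setNames(vals, feature_vector_names())
}

#' Feature table for a cohort
#'
#' @param subjects list of `subject_record`s.
#' @param atlas an [atlas_mask].
#' @param config a [radiomics_config].
#' @param progress print one dot per subject.
#' @return data.frame with `id`, `group`, `scanner` and 930 feature
#'   columns.
#' @export
feature_table <- function(subjects, atlas, config = radiomics_config(),
                          progress = FALSE) {
  rows <- lapply(subjects, function(s) {
    if (progress) cat(".")
    fv <- feature_vector(s, atlas, config)
    cbind(data.frame(id = s$id, group = s$group, scanner = s$scanner),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  if (progress) cat("\n")
  do.call(rbind, rows)
}
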