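#' Striatum uptake ratio
#'
#' `SUR(%) = (C_striatum - C_background) / C_background * 100`, where the
#' background is the mean count of the occipital reference region. Negative
#' values are possible when a striatal mean falls below background.
#'
#' @param c_striatum mean striatal count.
#' @param c_background mean background count (must be positive).
#' @return SUR in percent.
#' @export
sur <- function(c_striatum, c_background) {
  if (any(c_background <= 0))
    stop("background mean must be positive", call. = FALSE)
  (c_striatum - c_background) / c_background * 100
}

#' Semi-quantitative index panel for one subject
#'
#' Computes per-hemisphere SURs for caudate, putamen and pallidum against
#' the shared occipital background, averages left and right arithmetically
#' (`bilateral = "mean"`) or pools the bilateral voxels before the ratio
#' (`bilateral = "pooled"`), and forms the caudate ratios
#' `CR_x = SUR_caudate / SUR_x` from the bilateral values. A zero SUR in a
#' CR denominator yields `NA` with a warning so the index can be excluded
#' downstream.
#'
#' @param subject a `subject_record` (or a [volume_grid]).
#' @param atlas an [atlas_mask] on the same grid.
#' @param bilateral `"mean"` (average of per-hemisphere SURs, default) or
#'   `"pooled"` (single SUR over the merged L+R VOI).
#' @return Named numeric: `SUR_caudate`, `SUR_putamen`, `SUR_pallidum`,
#'   `CR_putamen`, `CR_pallidum`.
#' @export
semiquant_panel <- function(subject, atlas, bilateral = c("mean", "pooled")) {
  bilateral <- match.arg(bilateral)
  volume <- if (inherits(subject, "subject_record")) subject$volume else
    subject
  bg <- mean(extract_voi(volume, atlas, "occipital")$intensities)
  surs <- vapply(c("caudate", "putamen", "pallidum"), function(rn) {
    l <- extract_voi(volume, atlas, paste0(rn, "_L"))$intensities
    r <- extract_voi(volume, atlas, paste0(rn, "_R"))$intensities
    if (bilateral == "mean") mean(c(sur(mean(l), bg), sur(mean(r), bg)))
    else sur(mean(c(l, r)), bg)
  }, numeric(1))
  cr <- function(x) {
    if (abs(x) < .Machine$double.eps) {
      warning("zero SUR in a caudate-ratio denominator; CR set to NA",
              call. = FALSE)
      return(NA_real_)
    }
    surs[["caudate"]] / x
  }
  c(SUR_caudate = surs[["caudate"]], SUR_putamen = surs[["putamen"]],
    SUR_pallidum = surs[["pallidum"]],
    CR_putamen = cr(surs[["putamen"]]),
    CR_pallidum = cr(surs[["pallidum"]]))
}

#' Semi-quantitative panel for a whole cohort
#'
#' @param subjects list of `subject_record`s.
#' @param atlas an [atlas_mask].
#' @inheritParams semiquant_panel
#' @return data.frame: `id`, `group`, `scanner`, and the five indices.
#' @export
semiquant_table <- function(subjects, atlas, bilateral = "mean") {
  rows <- lapply(subjects, function(s) {
    p <- semiquant_panel(s, atlas, bilateral = bilateral)
    cbind(data.frame(id = s$id, group = s$group, scanner = s$scanner),
          as.data.frame(as.list(p)))
  })
  do.call(rbind, rows)
}
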