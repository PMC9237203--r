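#' Fixed-bin-number grey-level discretisation
#'
#' Maps VOI intensities to integer grey levels `1..n_bins` by
#' `floor(n_bins * (x - min) / (max - min)) + 1`, capped at `n_bins`.
#' A constant VOI maps to level 1. Fixed bin number (FBN) is the
#' recommended choice for non-calibrated units such as SPECT counts, and
#' makes all discretised features invariant to positive affine intensity
#' transforms of the input.
#'
#' @param voi a `voi_sample` from [extract_voi].
#' @param n_bins number of grey levels (>= 2).
#' @return A `discretized_voi`: list with `coords`, `levels`, `n_bins`,
#'   `spacing`, `provenance`.
#' @export
discretize <- function(voi, n_bins = 64L) {
  stopifnot(inherits(voi, "voi_sample"), n_bins >= 2)
  x <- voi$intensities
  if (length(x) == 0L) stop("empty VOI", call. = FALSE)
  rng <- range(x)
  lev <- if (rng[2] > rng[1])
    pmin(as.integer(floor(n_bins * (x - rng[1]) / (rng[2] - rng[1]))) + 1L,
         as.integer(n_bins))
  else rep(1L, length(x))
  structure(list(coords = voi$coords, levels = lev,
                 n_bins = as.integer(n_bins), spacing = voi$spacing,
                 provenance = list(method = "fixed_bin_number",
                                   parameter = n_bins)),
            class = "discretized_voi")
}

# Pack a discretised VOI into its bounding-box level array (NA outside VOI),
# the representation consumed by the C++ texture kernels.
level_array <- function(dvoi) {
  co <- dvoi$coords
  lo <- apply(co, 2, min)
  d <- apply(co, 2, max) - lo + 1L
  arr <- array(NA_integer_, dim = d)
  arr[cbind(co[, 1] - lo[1], co[, 2] - lo[2], co[, 3] - lo[3]) + 1L] <-
    dvoi$levels
  arr
}
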