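#' Phantom cohort parameters
#'
#' Parameters of the synthetic MNI-grid DAT-SPECT phantom. The phantom
#' emulates the *post-processed* product of a SPECT pipeline (reconstructed,
#' attenuation-corrected, spatially normalised, 6-mm smoothed): a uniform
#' background at `mu_bg` counts, striatal VOIs raised to `contrasts` times
#' background, disease effects applied as multiplicative losses, additive
#' Gaussian noise, then Gaussian smoothing at the point-spread FWHM and a
#' per-scanner global gain.
#'
#' The Parkinson's disease (PD) effect follows the known posterior-to-
#' anterior progression of dopamine-transporter loss in the putamen: a
#' multiplicative ramp from `1 - gradient_depth` at the most posterior
#' putaminal plane to 1 at the most anterior (linear when
#' `gradient_power = 1`), plus uniform fractional losses in caudate and
#' pallidum. Between-subject biological variability is modelled as
#' log-normal multipliers on the regional contrasts (`subject_sd`) and
#' Gaussian jitter on the gradient depth (`gradient_sd`).
#'
#' @param mu_bg background level in counts.
#' @param contrasts named numeric: normal-control contrast of caudate,
#'   putamen, pallidum as multiples of `mu_bg`.
#' @param gradient_depth PD fractional loss at the posterior putamen pole,
#'   in `[0, 1]`.
#' @param gradient_power exponent shaping the posterior-anterior ramp
#'   (1 = linear).
#' @param caudate_loss,pallidum_loss PD uniform fractional losses.
#' @param noise_sd additive Gaussian noise sd in counts (before smoothing).
#' @param fwhm_mm Gaussian point-spread FWHM in mm.
#' @param asymmetry left/right loss asymmetry in `[-1, 1]`; 0 = symmetric.
#' @param subject_sd sd of log-normal between-subject contrast multipliers.
#' @param gradient_sd sd of per-subject gradient-depth jitter (PD only).
#' @param scanner_gain,scanner_noise named multipliers for the two
#'   pseudo-scanners (`dataset1`, `dataset2`).
#' @param confine_effect if `TRUE`, the disease effect is applied to the
#'   VOI voxels *after* smoothing, so the group contrast is confined to
#'   the affected feature blocks by construction. With the default
#'   (`FALSE`, the realistic model) the point-spread function carries a
#'   putaminal loss into the adjacent pallidum and caudate, which then
#'   genuinely differ between groups as well. The confined variant exists
#'   for selection-recovery experiments that need an effect living only
#'   in named regions.
#' @param sizes named cohort sizes `nc1, pd1, nc2, pd2`.
#' @param seed root seed for [simulate_cohort].
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(mu_bg = 100,
                           contrasts = c(caudate = 3.0, putamen = 2.5,
                                         pallidum = 2.0),
                           gradient_depth = 0.6,
                           gradient_power = 1,
                           caudate_loss = 0.15,
                           pallidum_loss = 0.25,
                           noise_sd = 10,
                           fwhm_mm = 6.0,
                           asymmetry = 0,
                           subject_sd = 0.08,
                           gradient_sd = 0.12,
                           scanner_gain = c(dataset1 = 1.0, dataset2 = 0.9),
                           scanner_noise = c(dataset1 = 1.0, dataset2 = 1.3),
                           confine_effect = FALSE,
                           sizes = c(nc1 = 81, pd1 = 239, nc2 = 20, pd2 = 73),
                           seed = 1L) {
  stopifnot(mu_bg > 0, all(contrasts > 0),
            gradient_depth >= 0, gradient_depth <= 1,
            gradient_power > 0, fwhm_mm >= 0, noise_sd >= 0,
            caudate_loss >= 0, caudate_loss < 1,
            pallidum_loss >= 0, pallidum_loss < 1,
            abs(asymmetry) <= 1, subject_sd >= 0, gradient_sd >= 0)
  if (!all(c("caudate", "putamen", "pallidum") %in% names(contrasts)))
    stop("`contrasts` must name caudate, putamen, pallidum", call. = FALSE)
  structure(list(mu_bg = mu_bg, contrasts = contrasts,
                 gradient_depth = gradient_depth,
                 gradient_power = gradient_power,
                 caudate_loss = caudate_loss, pallidum_loss = pallidum_loss,
                 noise_sd = noise_sd, fwhm_mm = fwhm_mm,
                 asymmetry = asymmetry, subject_sd = subject_sd,
                 gradient_sd = gradient_sd,
                 scanner_gain = scanner_gain, scanner_noise = scanner_noise,
                 confine_effect = isTRUE(confine_effect),
                 sizes = sizes, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Build the synthetic striatal atlas
#'
#' Places six mirror-symmetric ellipsoidal striatal VOIs (caudate, putamen,
#' pallidum; left/right) and a posterior occipital background slab on the
#' grid. The putamen is elongated along the anteroposterior (y) axis so a
#' posterior uptake gradient is expressible; the left/right mirror is exact
#' about the mid-sagittal plane. Structure positions and sizes scale with
#' the grid so reduced grids remain usable; grids too small to hold the
#' structures raise a geometry error.
#'
#' @param shape integer length-3 grid shape, default 91 x 109 x 91.
#' @param spacing voxel spacing in mm.
#' @return An [atlas_mask] with the seven canonical regions.
#' @export
build_atlas <- function(shape = STANDARD_DIM, spacing = STANDARD_SPACING) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  sc <- (shape - 1) / (STANDARD_DIM - 1)
  # (centre_x_offset, centre_y, centre_z, semi_x, semi_y, semi_z) in voxels
  # of the standard grid; x offsets are from the mid-sagittal plane.
  spec <- list(
    caudate  = c(7.0,  70, 42, 3.0, 7.0, 4.0),
    putamen  = c(13.5, 62, 36, 4.0, 9.0, 5.0),
    pallidum = c(9.5,  58, 35, 2.5, 3.5, 3.0))
  semis <- do.call(rbind, lapply(spec, function(s) s[4:6] * sc))
  if (any(semis < 1))
    stop("grid too small to contain the striatal structures", call. = FALSE)
  midx <- (shape[1] - 1) / 2
  lab <- array(0L, dim = shape)
  xs <- seq_len(shape[1]) - 1; ys <- seq_len(shape[2]) - 1
  zs <- seq_len(shape[3]) - 1
  code <- 0L
  tab <- data.frame(code = integer(0), name = character(0))
  for (rn in names(spec)) {
    s <- spec[[rn]]
    for (side in c("L", "R")) {
      cx <- if (side == "L") midx - s[1] * sc[1] else midx + s[1] * sc[1]
      cy <- s[2] * sc[2]; cz <- s[3] * sc[3]
      ax <- s[4] * sc[1]; ay <- s[5] * sc[2]; az <- s[6] * sc[3]
      dx2 <- ((xs - cx) / ax)^2
      dy2 <- ((ys - cy) / ay)^2
      dz2 <- ((zs - cz) / az)^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
      code <- code + 1L
      sel <- inside & lab == 0L
      if (!any(sel))
        stop("grid too small: region ", rn, "_", side, " is empty",
             call. = FALSE)
      lab[sel] <- code
      tab <- rbind(tab, data.frame(code = code,
                                   name = paste0(rn, "_", side)))
    }
  }
  # posterior occipital slab
  occ <- array(FALSE, dim = shape)
  xi <- xs >= 28 * sc[1] & xs <= 62 * sc[1]
  yi <- ys >= 6 * sc[2] & ys <= 20 * sc[2]
  zi <- zs >= 26 * sc[3] & zs <= 48 * sc[3]
  occ[xi, yi, zi] <- TRUE
  code <- code + 1L
  sel <- occ & lab == 0L
  if (!any(sel)) stop("grid too small: occipital region is empty",
                      call. = FALSE)
  lab[sel] <- code
  tab <- rbind(tab, data.frame(code = code, name = "occipital"))
  atlas_mask(lab, tab, spacing = spacing)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

conv1_axis1 <- function(m, k) {
  # m: n x q matrix; zero-padded convolution along rows, kernel k (odd length)
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  norm <- numeric(n)
  for (t in -r:r) {
    w <- k[t + r + 1L]
    i <- max(1L, 1L - t):min(n, n - t)
    out[i, ] <- out[i, ] + w * m[i + t, , drop = FALSE]
    norm[i] <- norm[i] + w
  }
  out / norm
}

#' Separable 3D Gaussian smoothing
#'
#' FWHM is converted to sigma = FWHM / (2 sqrt(2 ln 2)) in mm and then to
#' voxels by the grid spacing. Edges are renormalised (truncated-kernel
#' weights rescaled to sum 1), so constant images are preserved exactly.
#'
#' @param values 3D numeric array.
#' @param fwhm_mm Gaussian FWHM in mm (0 = identity).
#' @param spacing voxel spacing in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(values, fwhm_mm, spacing = STANDARD_SPACING) {
  if (fwhm_mm <= 0) return(values)
  d <- dim(values)
  sig <- fwhm_to_sigma(fwhm_mm) / spacing
  kern <- lapply(sig, function(s) {
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  })
  # axis 1
  v <- array(conv1_axis1(matrix(values, d[1], d[2] * d[3]), kern[[1]]), dim = d)
  # axis 2
  v <- aperm(v, c(2, 1, 3))
  v <- array(conv1_axis1(matrix(v, d[2], d[1] * d[3]), kern[[2]]),
             dim = c(d[2], d[1], d[3]))
  v <- aperm(v, c(2, 1, 3))
  # axis 3
  v <- aperm(v, c(3, 2, 1))
  v <- array(conv1_axis1(matrix(v, d[3], d[2] * d[1]), kern[[3]]),
             dim = c(d[3], d[2], d[1]))
  aperm(v, c(3, 2, 1))
}

side_factor <- function(asymmetry, side) {
  if (side == "L") 1 + asymmetry else 1 - asymmetry
}

#' Simulate one phantom subject
#'
#' Builds the noiseless uptake map (background `mu_bg`, each striatal VOI at
#' its contrast times background; for PD, the posterior-anterior putaminal
#' loss ramp and the caudate/pallidum fractional losses), then adds Gaussian
#' noise, smooths at the point-spread FWHM, applies the scanner gain, and
#' clips at zero. Uses the current RNG state; see [simulate_cohort] for
#' seeded per-subject streams.
#'
#' @param params a [phantom_params].
#' @param group `"NC"` or `"PD"`.
#' @param scanner `"dataset1"` or `"dataset2"`.
#' @param atlas the [atlas_mask] to paint on (default: standard grid atlas).
#' @param id subject identifier.
#' @return A `subject_record`: list with `id`, `group`, `scanner`, `volume`.
#' @export
simulate_subject <- function(params, group, scanner,
                             atlas = build_atlas(), id = "subj") {
  stopifnot(inherits(params, "phantom_params"))
  if (!group %in% c("NC", "PD")) stop("invalid group: ", group, call. = FALSE)
  if (!scanner %in% c("dataset1", "dataset2"))
    stop("invalid scanner: ", scanner, call. = FALSE)
  vals <- array(params$mu_bg, dim = atlas$shape)
  # per-subject biological variability on regional contrasts
  mult <- if (params$subject_sd > 0)
    exp(rnorm(3, 0, params$subject_sd)) else rep(1, 3)
  names(mult) <- c("caudate", "putamen", "pallidum")
  g <- params$gradient_depth
  if (group == "PD" && params$gradient_sd > 0)
    g <- min(0.98, max(0.02, g + rnorm(1, 0, params$gradient_sd)))
  # per-VOI multiplicative disease factors (1 everywhere for NC)
  factors <- list()
  for (rn in c("caudate", "putamen", "pallidum")) {
    for (side in c("L", "R")) {
      nm <- paste0(rn, "_", side)
      sel <- which(atlas$labels == region_code(atlas, nm))
      fac <- rep(1, length(sel))
      if (group == "PD") {
        sf <- side_factor(params$asymmetry, side)
        if (rn == "putamen") {
          ys <- (sel - 1L) %/% atlas$shape[1] %% atlas$shape[2]
          yr <- range(ys)
          tfrac <- if (yr[2] > yr[1]) (ys - yr[1]) / (yr[2] - yr[1]) else
            rep(1, length(ys))
          # posterior (low y) -> anterior (high y) multiplicative ramp
          fac <- 1 - min(1, g * sf) * (1 - tfrac)^params$gradient_power
        } else {
          loss <- if (rn == "caudate") params$caudate_loss else
            params$pallidum_loss
          fac <- rep(1 - min(1, loss * sf), length(sel))
        }
      }
      factors[[nm]] <- list(sel = sel, fac = fac)
      vals[sel] <- params$contrasts[[rn]] * mult[[rn]] * params$mu_bg
      if (!params$confine_effect) vals[sel] <- vals[sel] * fac
    }
  }
  sn <- params$scanner_noise[[scanner]]
  if (params$noise_sd > 0)
    vals <- vals + rnorm(length(vals), 0, params$noise_sd * sn)
  vals <- gaussian_smooth_3d(vals, params$fwhm_mm, atlas$spacing)
  if (params$confine_effect)
    for (f in factors) vals[f$sel] <- vals[f$sel] * f$fac
  vals <- vals * params$scanner_gain[[scanner]]
  vals[vals < 0] <- 0
  structure(list(id = id, group = group, scanner = scanner,
                 volume = volume_grid(vals, spacing = atlas$spacing)),
            class = "subject_record")
}

#' Cohort design manifest
#'
#' Expands the cohort sizes of a [phantom_params] into one row per subject
#' with a deterministic per-subject seed derived from the root seed, so a
#' subject's volume can be regenerated independently of the rest of the
#' cohort.
#'
#' @param params a [phantom_params].
#' @return data.frame with columns `id`, `group`, `scanner`, `seed`.
#' @export
cohort_manifest <- function(params) {
  s <- params$sizes
  if (any(s <= 0)) stop("cohort sizes must be positive", call. = FALSE)
  design <- rbind(
    data.frame(group = rep("NC", s[["nc1"]]), scanner = "dataset1"),
    data.frame(group = rep("PD", s[["pd1"]]), scanner = "dataset1"),
    data.frame(group = rep("NC", s[["nc2"]]), scanner = "dataset2"),
    data.frame(group = rep("PD", s[["pd2"]]), scanner = "dataset2"))
  n <- nrow(design)
  design$id <- sprintf("S%04d", seq_len(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(params$seed)
  design$seed <- sample.int(.Machine$integer.max, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  design[, c("id", "group", "scanner", "seed")]
}

#' Simulate a full phantom cohort
#'
#' Deterministic under the params' root seed: per-subject seeds come from
#' [cohort_manifest], so the same seed yields bit-identical volumes.
#'
#' @param params a [phantom_params].
#' @param atlas atlas to use (built once if omitted).
#' @return List of `subject_record`s, with the manifest as attribute
#'   `"manifest"`.
#' @export
simulate_cohort <- function(params, atlas = build_atlas()) {
  man <- cohort_manifest(params)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    set.seed(man$seed[i])
    simulate_subject(params, man$group[i], man$scanner[i], atlas = atlas,
                     id = man$id[i])
  })
  attr(subjects, "manifest") <- man
  subjects
}
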