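#' @useDynLib striatomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm quantile median sd var approx predict setNames
#' @importFrom utils write.table read.delim head
NULL

STANDARD_DIM <- c(91L, 109L, 91L)
STANDARD_SPACING <- c(2, 2, 2)

REGION_NAMES <- c("caudate_L", "caudate_R", "putamen_L", "putamen_R",
                  "pallidum_L", "pallidum_R", "occipital")

#' Construct a 3D scalar volume
#'
#' A `volume_grid` is the unit of all image arithmetic in the package: a 3D
#' array of scalar voxel values (arbitrary count units) with isotropic or
#' anisotropic voxel spacing in mm. All computation is performed in voxel
#' space with 0-based voxel indices and x-fastest axis order; images are
#' assumed to already sit on a common spatially normalised grid (the default
#' pipeline grid is 91 x 109 x 91 voxels at 2 mm).
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3 voxel spacing in mm (strictly positive).
#' @return An object of class `volume_grid` with fields `values`, `shape`,
#'   `spacing`.
#' @export
volume_grid <- function(values, spacing = STANDARD_SPACING) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers", call. = FALSE)
  structure(list(values = values, shape = dim(values), spacing = spacing),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %d x %d x %d, spacing %.3g x %.3g x %.3g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a 3D NIfTI image (.nii or .nii.gz).
#' @return A [volume_grid].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions", call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  volume_grid(array(as.numeric(img), dim = d), spacing = spacing)
}

#' Write a volume as NIfTI
#'
#' Values and geometry round-trip through [read_volume] bit-exactly for
#' integer-valued data and to within float storage precision otherwise
#' (storage is 32-bit float unless `datatype = "double"`).
#'
#' @param volume a [volume_grid].
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type, default `"double"` for lossless
#'   round-trips.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Construct a labelled VOI atlas
#'
#' An `atlas_mask` pairs an integer label image with a region table mapping
#' label codes to region names. The canonical regions are the six striatal
#' VOIs (caudate, putamen, pallidum; left/right) and an occipital background
#' region used as the reference for uptake ratios.
#'
#' @param labels integer 3D array of region codes (0 = unlabelled).
#' @param region_table data.frame with columns `code` (integer) and `name`.
#' @param spacing voxel spacing in mm.
#' @return An object of class `atlas_mask`.
#' @export
atlas_mask <- function(labels, region_table, spacing = STANDARD_SPACING) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  stopifnot(is.data.frame(region_table),
            all(c("code", "name") %in% names(region_table)))
  region_table$code <- as.integer(region_table$code)
  region_table$name <- as.character(region_table$name)
  if (anyDuplicated(region_table$code) || anyDuplicated(region_table$name))
    stop("region codes and names must be unique", call. = FALSE)
  present <- unique(as.integer(labels))
  for (i in seq_len(nrow(region_table)))
    if (!region_table$code[i] %in% present)
      stop("region '", region_table$name[i], "' is empty in the label image",
           call. = FALSE)
  structure(list(labels = labels, shape = dim(labels),
                 spacing = as.numeric(spacing), regions = region_table),
            class = "atlas_mask")
}

#' @export
print.atlas_mask <- function(x, ...) {
  cat(sprintf("<atlas_mask %d x %d x %d, %d regions>\n",
              x$shape[1], x$shape[2], x$shape[3], nrow(x$regions)))
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  %2d  %-12s %d voxels\n", x$regions$code[i],
                x$regions$name[i], sum(x$labels == x$regions$code[i])))
  invisible(x)
}

#' Read / write an atlas as NIfTI label image + TSV region table
#'
#' @param label_path path to the NIfTI label image.
#' @param table_path path to a TSV with columns `code` and `name`.
#' @return An [atlas_mask].
#' @export
read_atlas <- function(label_path, table_path) {
  vol <- read_volume(label_path)
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  atlas_mask(array(as.integer(round(vol$values)), dim = vol$shape),
             tab, spacing = vol$spacing)
}

#' @rdname read_atlas
#' @param atlas an [atlas_mask].
#' @export
write_atlas <- function(atlas, label_path, table_path) {
  vol <- volume_grid(array(as.numeric(atlas$labels), dim = atlas$shape),
                     spacing = atlas$spacing)
  write_volume(vol, label_path, datatype = "short")
  write.table(atlas$regions, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(label_path)
}

check_geometry <- function(volume, atlas) {
  if (!identical(as.integer(volume$shape), as.integer(atlas$shape)))
    stop("volume and atlas grids do not align (shape mismatch)",
         call. = FALSE)
  if (max(abs(volume$spacing - atlas$spacing)) > 1e-6)
    stop("volume and atlas grids do not align (spacing mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

region_code <- function(atlas, region) {
  i <- match(region, atlas$regions$name)
  if (is.na(i)) stop("unknown region: ", region, call. = FALSE)
  atlas$regions$code[i]
}

#' Extract the voxels of one VOI
#'
#' Returns the voxel coordinates (0-based integer triples, x-fastest order)
#' and intensities of all voxels carrying the region's label.
#'
#' @param volume a [volume_grid].
#' @param atlas an [atlas_mask] on the same grid.
#' @param region region name present in the atlas table.
#' @return A `voi_sample`: list with `region`, `coords` (n x 3 integer
#'   matrix), `intensities` (numeric n), `spacing`.
#' @export
extract_voi <- function(volume, atlas, region) {
  check_geometry(volume, atlas)
  code <- region_code(atlas, region)
  sel <- which(atlas$labels == code)
  if (length(sel) == 0L) stop("empty VOI: ", region, call. = FALSE)
  d <- atlas$shape
  i0 <- sel - 1L
  coords <- cbind(x = i0 %% d[1],
                  y = (i0 %/% d[1]) %% d[2],
                  z = i0 %/% (d[1] * d[2]))
  structure(list(region = region, coords = coords,
                 intensities = as.numeric(volume$values[sel]),
                 spacing = volume$spacing),
            class = "voi_sample")
}
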