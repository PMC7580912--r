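#' octaquant: perfusion quantification for en-face OCT angiography
#'
#' Quantifies capillary perfusion on en-face OCTA slabs of the superficial
#' (SCP), middle (MCP) and deep (DCP) retinal capillary plexuses.  The core
#' contribution is a binarization threshold derived from the DCP's
#' skeletonized vessel length: skeletonized pixel counts are swept over
#' candidate thresholds, a two-segment regression separates the steep
#' noise-dominated limb from the signal plateau, and the threshold is the
#' intersection of the two lines.  Downstream modules compute vessel density,
#' vessel length density, adjusted flow index and foveal avascular zone area
#' in a parafoveal annulus, generate synthetic angiograms and cohorts with
#' ground truth, and reproduce the cohort statistics layer (Spearman stage
#' trends, covariate-adjusted ANCOVA with Benjamini-Hochberg post-hoc tests,
#' Cohen's d, sample size, ROC).
#'
#' @useDynLib octaquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm pf pt qt rnorm runif sd vcov predict anova
#' @importFrom utils read.csv write.csv
#' @keywords internal
"_PACKAGE"

PLEXUS_LEVELS <- c("SCP", "MCP", "DCP", "RETINA")

#' En-face OCTA image
#'
#' A single-plexus en-face angiogram slab: a square grid of non-negative
#' integer decorrelation intensities plus physical field-of-view metadata.
#' The nominal acquisition is 304 x 304 pixels over a 3 x 3 mm field centred
#' on the fovea; other square sizes are accepted.
#'
#' @param pixels square integer matrix, row 1 = top of the image, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param plexus one of `"SCP"`, `"MCP"`, `"DCP"`, `"RETINA"`.
#' @param fov_mm physical width of the field of view in mm (default 3).
#' @param bit_depth 8 or 16.
#' @return An object of class `enface_image` with elements `pixels`,
#'   `plexus`, `fov_mm`, `bit_depth`.
#' @export
enface_image <- function(pixels, plexus, fov_mm = 3.0, bit_depth = 8L) {
  plexus <- match.arg(toupper(plexus), PLEXUS_LEVELS)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) != ncol(pixels))
    stop("en-face image must be square, got ", nrow(pixels), " x ", ncol(pixels))
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (anyNA(pixels)) stop("pixels contain NA")
  if (min(pixels) < 0L || max(pixels) > 2L^bit_depth - 1L)
    stop("pixel intensities outside [0, 2^bit_depth - 1]")
  if (!is.numeric(fov_mm) || length(fov_mm) != 1L || fov_mm <= 0)
    stop("fov_mm must be a positive scalar")
  structure(list(pixels = pixels, plexus = plexus, fov_mm = fov_mm,
                 bit_depth = bit_depth),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %s slab, %d x %d px, %g mm FOV, %d-bit, range [%d, %d]\n",
              x$plexus, nrow(x$pixels), ncol(x$pixels), x$fov_mm, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.enface_image <- function(x) dim(x$pixels)

#' Load an en-face angiogram from a grayscale PNG or TIFF
#'
#' The file must be single-channel (grayscale) 8- or 16-bit; RGB, palette or
#' alpha-channel rasters are rejected so intensities are never silently
#' flattened.  Bit depth is inferred from the file.
#'
#' @param path path to a PNG or TIFF file.
#' @inheritParams enface_image
#' @return An [enface_image()].
#' @export
load_enface <- function(path, plexus, fov_mm = 3.0) {
  r <- read_gray_raster(path)
  enface_image(r$pixels, plexus = plexus, fov_mm = fov_mm,
               bit_depth = r$bit_depth)
}

#' Write an en-face angiogram to PNG or TIFF
#'
#' Format chosen by extension (`.tif`/`.tiff` for TIFF, PNG otherwise).
#'
#' @param img an [enface_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enface <- function(img, path) {
  stopifnot(inherits(img, "enface_image"))
  write_gray_raster(img$pixels, path, img$bit_depth)
  invisible(path)
}

#' Normalize intensities to the decorrelation scale `[0, 1]`
#'
#' Divides raw intensities by `2^bit_depth - 1`, the order-preserving mapping
#' onto the SSADA decorrelation scale on which the adjusted flow index is
#' reported (cohort means lie around 0.41-0.45).
#'
#' @param img an [enface_image()].
#' @return numeric matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(img) {
  stopifnot(inherits(img, "enface_image"))
  img$pixels / (2^img$bit_depth - 1)
}

#' Read a binary mask raster
#'
#' Masks are grayscale rasters with 0 = background and any positive value =
#' foreground.
#'
#' @param path PNG or TIFF path.
#' @return logical matrix.
#' @export
load_mask <- function(path) {
  r <- read_gray_raster(path)
  r$pixels > 0L
}

#' Write a binary mask as an 8-bit raster (foreground = 255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  write_gray_raster(matrix(ifelse(mask, 255L, 0L), nrow(mask)), path, 8L)
  invisible(path)
}
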