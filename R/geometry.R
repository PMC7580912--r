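# Parafoveal analysis geometry: pixel <-> mm conversion and the annular
# region (outer diameter 3 mm, inner diameter 1 mm) in which all perfusion
# metrics are evaluated.

#' Pixel scale of an en-face field
#'
#' @param fov_mm physical field width in mm.
#' @param width_px image width in pixels.
#' @return list with `mm_per_px`.
#' @export
pixel_scale <- function(fov_mm, width_px) {
  if (fov_mm <= 0 || width_px <= 0) stop("fov_mm and width_px must be positive")
  list(mm_per_px = fov_mm / width_px)
}

#' Parafoveal annulus specification
#'
#' Defaults follow the standard parafovea: a ring between 1 mm and 3 mm
#' diameters centred on the fovea.  The centre defaults to the geometric
#' image centre `((W-1)/2, (H-1)/2)` in 0-based pixel units; supply
#' `center_px` for decentred scans.
#'
#' @param outer_diameter_mm outer ring diameter, mm.
#' @param inner_diameter_mm inner ring diameter, mm.
#' @param center_px optional `c(x, y)` pixel coordinates of the foveal
#'   centre (0-based).
#' @return list of class `annulus_spec`.
#' @export
annulus_spec <- function(outer_diameter_mm = 3.0, inner_diameter_mm = 1.0,
                         center_px = NULL) {
  if (inner_diameter_mm < 0 || outer_diameter_mm <= inner_diameter_mm)
    stop("need 0 <= inner_diameter_mm < outer_diameter_mm")
  structure(list(outer_diameter_mm = outer_diameter_mm,
                 inner_diameter_mm = inner_diameter_mm,
                 center_px = center_px),
            class = "annulus_spec")
}

# squared pixel distances from centre, as a matrix matching shape
pixel_dist2 <- function(shape, center) {
  h <- shape[1]; w <- shape[2]
  dx <- (0:(w - 1)) - center[1]
  dy <- (0:(h - 1)) - center[2]
  outer(dy^2, dx^2, `+`)
}

#' Build the parafoveal annulus mask
#'
#' A pixel belongs to the annulus iff the Euclidean distance `d` (mm) from
#' its centre point to the annulus centre satisfies
#' `inner_radius <= d < outer_radius` (half-open, so concentric rings tile
#' without overlap).
#'
#' @param shape `c(nrow, ncol)` of the target image.
#' @param spec an [annulus_spec()].
#' @param scale a [pixel_scale()].
#' @return logical matrix.
#' @export
make_parafoveal_mask <- function(shape, spec = annulus_spec(),
                                 scale = pixel_scale(3.0, shape[2])) {
  stopifnot(inherits(spec, "annulus_spec"))
  h <- shape[1]; w <- shape[2]
  center <- spec$center_px %||% c((w - 1) / 2, (h - 1) / 2)
  r_out_px <- (spec$outer_diameter_mm / 2) / scale$mm_per_px
  r_in_px <- (spec$inner_diameter_mm / 2) / scale$mm_per_px
  lim <- min(center[1], center[2], w - 1 - center[1], h - 1 - center[2]) + 0.5
  corner <- sqrt(max((c(0, w - 1) - center[1])^2) +
                 max((c(0, h - 1) - center[2])^2)) + 0.5
  # error only when the ring is clipped by the image; an outer disk that
  # swallows the whole field (degenerate full-field region) is permitted
  if (r_out_px > lim + 1e-9 && r_out_px < corner)
    stop("annulus (outer radius ", signif(r_out_px, 4),
         " px) exceeds image bounds")
  d2 <- pixel_dist2(shape, center)
  d2 >= r_in_px^2 & d2 < r_out_px^2
}

#' Disk mask (used for the inner circle and for synthetic avascular zones)
#'
#' Half-open: pixel centres with distance `< radius` belong to the disk, so
#' the disk of the annulus' inner radius and the annulus itself are disjoint
#' and tile the outer disk.
#'
#' @param shape `c(nrow, ncol)`.
#' @param radius_px disk radius in pixels.
#' @param center_px optional `c(x, y)` centre (0-based); default image centre.
#' @return logical matrix.
#' @export
make_disk_mask <- function(shape, radius_px, center_px = NULL) {
  h <- shape[1]; w <- shape[2]
  center <- center_px %||% c((w - 1) / 2, (h - 1) / 2)
  pixel_dist2(shape, center) < radius_px^2
}

#' Physical area of a binary mask
#'
#' @param mask logical matrix.
#' @param scale a [pixel_scale()].
#' @return area in mm^2 (foreground pixel count times `mm_per_px^2`).
#' @export
mask_area_mm2 <- function(mask, scale) {
  stopifnot(is.matrix(mask))
  sum(mask) * scale$mm_per_px^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
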