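# Per-eye perfusion metrics computed inside the parafoveal annulus from
# binarized / skeletonized slabs: vessel density (VD, %), vessel length
# density (VLD, 1/mm), adjusted flow index (AFI, mean decorrelation of
# suprathreshold pixels) and foveal avascular zone (FAZ) area (mm^2).

#' Parafoveal vessel density
#'
#' Percentage of the analysis region occupied by binarized vessel pixels.
#'
#' @param bin logical vessel map.
#' @param mask logical analysis mask (same shape, non-empty).
#' @return percent in `[0, 100]`.
#' @export
vessel_density <- function(bin, mask) {
  check_same_shape(bin, mask)
  n <- sum(mask)
  if (n == 0L) stop("empty analysis mask")
  100 * sum(bin & mask) / n
}

#' Vessel length density
#'
#' Skeletonized vessel length per unit area: skeleton pixel count within the
#' mask times the pixel pitch, divided by the mask area.  Length is counted
#' as pixels times pitch (no diagonal correction by default, matching
#' pixel-count practice); set `diagonal_correction = TRUE` to weight
#' diagonal skeleton steps by sqrt(2).
#'
#' @param skel logical skeleton map.
#' @param mask logical analysis mask.
#' @param scale a [pixel_scale()].
#' @param diagonal_correction logical; see above.
#' @return vessel length density in 1/mm.
#' @export
vessel_length_density <- function(skel, mask, scale,
                                  diagonal_correction = FALSE) {
  check_same_shape(skel, mask)
  if (sum(mask) == 0L) stop("empty analysis mask")
  px <- skel & mask
  len_px <- if (!diagonal_correction) sum(px) else skeleton_length_px(px)
  (len_px * scale$mm_per_px) / mask_area_mm2(mask, scale)
}

# pixel-count length with sqrt(2) weighting of diagonal-only links
skeleton_length_px <- function(px) {
  h <- nrow(px); w <- ncol(px)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  straight <- sum(px & shift(px, 0, 1)) + sum(px & shift(px, 1, 0))
  diag_links <- sum(px & shift(px, 1, 1)) + sum(px & shift(px, 1, -1))
  # approximate: each link contributes its length; isolated pixels count 1
  straight + sqrt(2) * diag_links + sum(px & !(
    shift(px, 0, 1) | shift(px, 0, -1) | shift(px, 1, 0) | shift(px, -1, 0) |
    shift(px, 1, 1) | shift(px, 1, -1) | shift(px, -1, 1) | shift(px, -1, -1)))
}

#' Adjusted flow index
#'
#' Mean normalized decorrelation over mask pixels at or above the noise
#' threshold `t` (the same DCP-derived threshold used for binarization, so
#' all layers share one cutoff).
#'
#' @param img an [enface_image()].
#' @param mask logical analysis mask.
#' @param t integer threshold (raw intensity units).
#' @return dimensionless mean in `[0, 1]`.
#' @export
adjusted_flow_index <- function(img, mask, t) {
  stopifnot(inherits(img, "enface_image"))
  check_same_shape(img$pixels, mask)
  sel <- mask & img$pixels >= t
  if (!any(sel))
    stop("undefined AFI: no pixels at or above threshold ", t, " in the mask")
  sum(img$pixels[sel]) / sum(sel) / (2^img$bit_depth - 1)
}

#' Foveal avascular zone area
#'
#' Primary mode: a manually traced FAZ mask is supplied and its area
#' returned.  Assisted mode: the binarized full-retina slab is
#' morphologically closed (disk radius `closing_radius_px`) to seal small
#' gaps in the capillary ring, and the background component containing
#' `seed_px` is flood-filled (4-connectivity); its area is returned.  A fill
#' that escapes to the image border, or an area above `max_area_mm2`, is an
#' error (the avascular zone was not enclosed).
#'
#' @param retina_bin logical binarized full-retina vessel map (assisted
#'   mode).
#' @param scale a [pixel_scale()].
#' @param faz_mask optional logical traced mask (primary mode).
#' @param seed_px optional `c(x, y)` 0-based pixel inside the FAZ (assisted
#'   mode; defaults to the image centre).
#' @param closing_radius_px disk radius for the morphological closing
#'   (default 2).
#' @param max_area_mm2 plausibility bound on the area (default 2).
#' @return area in mm^2.
#' @export
faz_area <- function(retina_bin = NULL, scale, faz_mask = NULL,
                     seed_px = NULL, closing_radius_px = 2L,
                     max_area_mm2 = 2.0) {
  if (!is.null(faz_mask)) {
    area <- mask_area_mm2(faz_mask, scale)
  } else {
    if (is.null(retina_bin))
      stop("need either a traced faz_mask or a retina_bin for assisted mode")
    h <- nrow(retina_bin); w <- ncol(retina_bin)
    seed <- seed_px %||% c((w - 1) %/% 2, (h - 1) %/% 2)
    closed <- binary_close(retina_bin, closing_radius_px)
    if (closed[seed[2] + 1L, seed[1] + 1L])
      stop("seed pixel lies on a vessel after closing; choose a point inside ",
           "the avascular zone")
    reg <- cpp_flood_region(closed, seed[2] + 1L, seed[1] + 1L, 4L)
    if (reg$touches_border)
      stop("fill-escape: assisted FAZ fill reached the image border ",
           "(avascular zone not enclosed)")
    area <- length(reg$indices) * scale$mm_per_px^2
  }
  if (area > max_area_mm2)
    stop("implausible FAZ area ", signif(area, 4), " mm^2 (> ", max_area_mm2,
         " mm^2)")
  area
}

disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

binary_dilate <- function(m, r) {
  if (r <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  off <- disk_offsets(r)
  for (k in seq_len(nrow(off))) {
    dr <- off$dr[k]; dc <- off$dc[k]
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- out[rs, cs] | m[rs - dr, cs - dc]
  }
  out
}

binary_erode <- function(m, r) !binary_dilate(!m, r)

binary_close <- function(m, r) binary_erode(binary_dilate(m, r), r)

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Compute the full per-eye metric set
#'
#' Applies the single DCP-derived threshold to every supplied plexus slab and
#' evaluates VD (all plexuses), VLD, and AFI within the parafoveal annulus;
#' FAZ area is computed from the full-retina slab when present (or from a
#' supplied traced mask).
#'
#' @param images named list of [enface_image()]s; requires `SCP`, `MCP`,
#'   `DCP`, optionally `RETINA`.
#' @param spec an [annulus_spec()].
#' @param result a `threshold_result` from [compute_vld_threshold()] (or any
#'   list with an integer `threshold`).
#' @param faz_mask optional traced FAZ mask.
#' @param faz_seed optional `c(x, y)` seed for assisted FAZ mode.
#' @param vld_plexuses plexuses for which VLD is reported (default `"SCP"`,
#'   where skeletonization removes the influence of the large vessels).
#' @return list of class `metric_set`: `vd_pct`, `vld_per_mm`, `afi` (named
#'   by plexus), `faz_mm2` (or `NA`), `threshold_used`.
#' @export
compute_metricset <- function(images, spec = annulus_spec(), result,
                              faz_mask = NULL, faz_seed = NULL,
                              vld_plexuses = "SCP") {
  need <- c("SCP", "MCP", "DCP")
  miss <- setdiff(need, names(images))
  if (length(miss))
    stop("missing plexus slab(s): ", paste(miss, collapse = ", "))
  t <- result$threshold
  shape <- dim(images$DCP$pixels)
  scale <- pixel_scale(images$DCP$fov_mm, shape[2])
  mask <- make_parafoveal_mask(shape, spec, scale)
  vd <- vapply(need, function(p) {
    vessel_density(binarize(images[[p]], t), mask)
  }, numeric(1))
  vld <- vapply(vld_plexuses, function(p) {
    vessel_length_density(skeletonize(binarize(images[[p]], t)), mask, scale)
  }, numeric(1))
  afi <- vapply(need, function(p) {
    adjusted_flow_index(images[[p]], mask, t)
  }, numeric(1))
  faz <- NA_real_
  if (!is.null(faz_mask)) {
    faz <- faz_area(scale = scale, faz_mask = faz_mask)
  } else if ("RETINA" %in% names(images)) {
    faz <- faz_area(binarize(images$RETINA, t), scale, seed_px = faz_seed)
  }
  structure(list(vd_pct = vd, vld_per_mm = vld, afi = afi, faz_mm2 = faz,
                 threshold_used = as.integer(t)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set> threshold =", x$threshold_used, "\n")
  cat("  VD (%):  ", paste(sprintf("%s %.2f", names(x$vd_pct), x$vd_pct),
                           collapse = ", "), "\n")
  cat("  VLD (/mm):", paste(sprintf("%s %.2f", names(x$vld_per_mm),
                                    x$vld_per_mm), collapse = ", "), "\n")
  cat("  AFI:     ", paste(sprintf("%s %.3f", names(x$afi), x$afi),
                           collapse = ", "), "\n")
  if (!is.na(x$faz_mm2)) cat("  FAZ (mm^2):", sprintf("%.3f", x$faz_mm2), "\n")
  invisible(x)
}
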