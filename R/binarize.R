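# Binarization and thresholding.
#
# The central algorithm derives a global binarization threshold from the deep
# capillary plexus (DCP): the skeletonized vessel pixel count is swept over
# candidate thresholds, and because noise decays faster than true vessel
# signal as the threshold rises, the curve falls steeply through the noise
# range and plateaus over the signal range.  Ordinary least squares lines are
# fitted to the two regimes (breakpoint chosen by exhaustive two-segment SSE
# minimization) and the threshold is their intersection.  The single
# DCP-derived threshold is then used to binarize all plexus slabs of the eye.

#' Binarize an en-face image at an integer threshold
#'
#' Foreground iff raw intensity `>= t`.
#'
#' @param img an [enface_image()].
#' @param t integer threshold within the image's intensity range.
#' @return logical matrix (vessel map).
#' @export
binarize <- function(img, t) {
  stopifnot(inherits(img, "enface_image"))
  t <- as.integer(t)
  if (t < 0L || t > 2L^img$bit_depth - 1L)
    stop("threshold ", t, " outside the ", img$bit_depth, "-bit intensity range")
  img$pixels >= t
}

#' Topology-preserving skeletonization
#'
#' Reduces all vessel widths to one pixel by sequential thinning: simple,
#' non-endpoint border pixels are deleted in four directional subpasses until
#' stable.  The result is a subset of the input, contains no fully-foreground
#' 2x2 block, and preserves the 8-connected component count, so skeletonized
#' pixel counts measure vessel length independent of caliber.
#'
#' @param bin logical matrix (binary vessel map).
#' @return logical matrix (skeleton).
#' @export
skeletonize <- function(bin) {
  stopifnot(is.matrix(bin), is.logical(bin))
  cpp_thin(bin)
}

#' Sweep the skeletonized-vessel-length vs threshold curve
#'
#' For each integer threshold `t` in `[t_min, t_max]` the image is binarized
#' at `t`, skeletonized, and the skeleton pixel count recorded.  The count is
#' taken over the full image extent (total vessel length, not parafoveal).
#'
#' @param dcp the DCP [enface_image()] (the curve is defined on the DCP).
#' @param t_min,t_max inclusive sweep bounds; defaults cover
#'   `1 .. 2^bit_depth - 2`.
#' @return list of class `threshold_curve` with `thresholds` and
#'   `vld_counts`.
#' @export
sweep_vld_curve <- function(dcp, t_min = 1L, t_max = NULL) {
  stopifnot(inherits(dcp, "enface_image"))
  t_max <- as.integer(t_max %||% (2L^dcp$bit_depth - 2L))
  t_min <- as.integer(t_min)
  if (t_min >= t_max) stop("degenerate sweep range [", t_min, ", ", t_max, "]")
  if (t_min < 0L || t_max > 2L^dcp$bit_depth - 1L)
    stop("sweep range outside the intensity range")
  counts <- cpp_vld_sweep(dcp$pixels, t_min, t_max)
  structure(list(thresholds = t_min:t_max, vld_counts = as.integer(counts)),
            class = "threshold_curve")
}

ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - (intercept + slope * x)
  list(slope = slope, intercept = intercept, sse = sum(res^2))
}

#' Two-segment piecewise-linear fit of a threshold curve
#'
#' Restricts the curve to its declining limb: the window starts at the global
#' argmax of the counts and ends where the curve first stops declining — at
#' `fit_upper` if given, or earlier if the counts rise back above the running
#' minimum by more than `rise_tol` of the limb's total drop (at very high
#' thresholds the vessels themselves fragment and the skeleton count grows
#' again; that region is neither the steep noise limb nor the signal plateau,
#' so it is excluded from the fit).  Within the window, every admissible
#' breakpoint with at least `min_segment` points on each side is
#' grid-searched, ordinary least squares lines are fitted to the left
#' (steep, noise) and right (plateau, signal) segments, and the breakpoint
#' minimizing total SSE is returned together with the crossing abscissa of
#' the two lines.
#'
#' @param curve a `threshold_curve` from [sweep_vld_curve()].
#' @param min_segment minimum points per segment (default 10).
#' @param fit_upper optional inclusive upper threshold bound for the fit
#'   window (callers typically pass `0.9 * (2^bit_depth - 1)` to exclude the
#'   high-threshold falloff where vessels themselves vanish).
#' @param rise_tol fraction of the declining limb's total drop by which the
#'   counts may exceed the running minimum before the window is cut
#'   (default 0.05).
#' @return list of class `piecewise_fit` with `breakpoint`, `noise_line`,
#'   `signal_line` (each `c(slope, intercept)`), `intersection_x`,
#'   `total_sse`, and the fitted window `fit_range`.
#' @export
fit_two_segment <- function(curve, min_segment = 10L, fit_upper = NULL,
                            rise_tol = 0.05) {
  stopifnot(inherits(curve, "threshold_curve"))
  th <- curve$thresholds
  ct <- as.numeric(curve$vld_counts)
  start <- which.max(ct)
  end <- length(th)
  if (!is.null(fit_upper)) {
    end <- max(which(th <= fit_upper))
    if (end <= start) stop("fit window above argmax is empty")
  }
  # cut the window where the curve stops declining (vessel-fragmentation
  # regime): a sustained rise (3 consecutive points) above the running
  # minimum by more than rise_tol of the drop seen so far, with a floor at
  # three robust noise SDs so ordinary curve noise never truncates the fit
  y_win <- ct[start:end]
  run_min <- cummin(y_win)
  drop <- ct[start] - run_min
  rise <- y_win - run_min
  sigma_hat <- stats::mad(diff(y_win)) / sqrt(2)
  tol <- pmax(rise_tol * drop, 3 * sigma_hat, 0.01 * ct[start] + 2)
  up <- rise > tol
  sustained <- which(up & c(up[-1], FALSE) & c(up[-(1:2)], FALSE, FALSE))
  if (length(sustained)) end <- max(start + 1L, start + min(sustained) - 2L)
  x <- th[start:end]
  y <- ct[start:end]
  n <- length(x)
  if (n < 2L * min_segment)
    stop("fitting window has ", n, " points; need at least 2*min_segment = ",
         2L * min_segment)
  best <- NULL
  for (b in min_segment:(n - min_segment)) {
    left <- ols_line(x[1:b], y[1:b])
    right <- ols_line(x[(b + 1):n], y[(b + 1):n])
    sse <- left$sse + right$sse
    if (is.null(best) || sse < best$sse)
      best <- list(b = b, left = left, right = right, sse = sse)
  }
  m_n <- best$left$slope; c_n <- best$left$intercept
  m_s <- best$right$slope; c_s <- best$right$intercept
  if (abs(m_n - m_s) < 1e-8 * max(1, abs(m_n), abs(m_s)))
    stop("fit-degenerate: noise and signal segments are (near-)parallel")
  ix <- (c_s - c_n) / (m_n - m_s)
  if (ix < x[1] - 0.5 || ix > x[n] + 0.5)
    stop("fit-invalid: regression-line intersection at ", signif(ix, 5),
         " lies outside the fitted threshold range [", x[1], ", ", x[n], "]")
  structure(list(breakpoint = x[best$b],
                 noise_line = c(slope = m_n, intercept = c_n),
                 signal_line = c(slope = m_s, intercept = c_s),
                 intersection_x = ix,
                 total_sse = best$sse,
                 fit_range = c(x[1], x[n])),
            class = "piecewise_fit")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' DCP vessel-length-density-based binarization threshold
#'
#' Runs the full thresholding algorithm on a DCP slab: sweep the skeletonized
#' vessel count over candidate thresholds, fit the two-segment regression to
#' the declining limb, and take the (rounded) intersection of the noise and
#' signal lines as the binarization threshold.  The returned threshold is
#' intended to binarize the SCP, MCP and DCP slabs of the same eye, so all
#' layers share one cutoff.
#'
#' @param dcp the DCP [enface_image()].
#' @param t_min,t_max sweep bounds (defaults `1` and `2^bit_depth - 2`).
#' @param min_segment minimum points per fitted segment (default 10).
#' @param fit_upper_frac upper bound of the fitting window as a fraction of
#'   the intensity maximum (default 0.9).
#' @return list of class `threshold_result` with integer `threshold`, the
#'   `curve`, and the `fit` (diagnostics for audit).
#' @export
compute_vld_threshold <- function(dcp, t_min = 1L, t_max = NULL,
                                  min_segment = 10L, fit_upper_frac = 0.9) {
  stopifnot(inherits(dcp, "enface_image"))
  t_max <- as.integer(t_max %||% (2L^dcp$bit_depth - 2L))
  curve <- sweep_vld_curve(dcp, t_min, t_max)
  fit <- fit_two_segment(curve, min_segment = min_segment,
                         fit_upper = fit_upper_frac * (2^dcp$bit_depth - 1))
  t_hat <- round_half_away(fit$intersection_x)
  if (t_hat < t_min || t_hat > t_max) {
    warning("intersection ", signif(fit$intersection_x, 5),
            " clamped to sweep bounds [", t_min, ", ", t_max, "]")
    t_hat <- min(max(t_hat, t_min), t_max)
  }
  structure(list(threshold = as.integer(t_hat), curve = curve, fit = fit),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(paste0("<threshold_result> threshold = %d ",
                     "(intersection %.2f, breakpoint %d, SSE %.1f)\n"),
              x$threshold, x$fit$intersection_x, x$fit$breakpoint,
              x$fit$total_sse))
  invisible(x)
}

#' Mean auto-threshold
#'
#' The ImageJ-style Mean method: the threshold is the arithmetic mean of all
#' pixel intensities, rounded to the nearest integer.
#'
#' @param img an [enface_image()].
#' @return integer threshold (binarize with intensity `>= t`).
#' @export
mean_threshold <- function(img) {
  stopifnot(inherits(img, "enface_image"))
  as.integer(round_half_away(mean(img$pixels)))
}

#' Huang fuzzy auto-threshold
#'
#' Huang & Wang's fuzzy-thresholding criterion: for each candidate threshold
#' the image is split at the candidate, pixel memberships are assigned from
#' the distance to their class mean, and the Shannon fuzziness of the
#' membership map is computed from the intensity histogram.  The returned
#' threshold minimizes the fuzziness, searched exhaustively; foreground is
#' `intensity >= t`.
#'
#' @param img an [enface_image()] with at least two distinct intensities.
#' @return integer threshold.
#' @export
huang_threshold <- function(img) {
  stopifnot(inherits(img, "enface_image"))
  g <- as.vector(img$pixels)
  gmin <- min(g); gmax <- max(g)
  if (gmin == gmax)
    stop("no-threshold: constant image has no Huang threshold")
  h <- tabulate(g - gmin + 1L, nbins = gmax - gmin + 1L)
  lev <- gmin:gmax
  crits <- vapply((gmin + 1L):gmax, function(t) huang_criterion(h, lev, t),
                  numeric(1))
  as.integer(((gmin + 1L):gmax)[which.min(crits)])
}

# Shannon fuzziness of the split {g < t} vs {g >= t}
huang_criterion <- function(h, lev, t) {
  lo <- lev < t
  C <- max(lev) - min(lev)
  mu0 <- sum(h[lo] * lev[lo]) / sum(h[lo])
  mu1 <- sum(h[!lo] * lev[!lo]) / sum(h[!lo])
  mu <- ifelse(lo, mu0, mu1)
  u <- 1 / (1 + abs(lev - mu) / C)   # membership in [0.5, 1]
  sh <- ifelse(u > 1 - 1e-12, 0, -u * log(u) - (1 - u) * log(1 - u))
  sum(h * sh)
}
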