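# Synthetic multi-plexus angiograms and cohort tables with ground truth.
#
# The angiogram generator emulates the structure the thresholding method
# relies on: a bimodal intensity mixture (low background decorrelation noise
# vs high vessel signal), branched curvilinear capillary networks per plexus,
# a central avascular zone, and severity-dependent capillary dropout.  It is
# a stated world, not an imaging physics model: no speckle, no projection
# artifacts, no depth attenuation.

#' Synthetic angiogram specification
#'
#' Defaults emulate the nominal acquisition (304 x 304 px over 3 x 3 mm,
#' 8-bit) with a clean separation between background noise (uniform on
#' `[20, 55]`) and vessel signal (uniform on `[150, 230]`), a 0.25 mm
#' avascular-zone radius (about 0.2 mm^2, the healthy-eye scale), and
#' capillary widths of 1-3 px (roughly 10-30 um at 10 um/px).
#'
#' @param shape image side length in pixels.
#' @param fov_mm field of view in mm.
#' @param n_seeds number of initial vessel growth seeds per plexus.
#' @param vessel_width_px integer range `c(min, max)` of capillary widths.
#' @param dropout_fraction fraction of branch segments deleted (capillary
#'   dropout severity dial), in `[0, 1]`.
#' @param faz_radius_mm radius of the central avascular disk.
#' @param vessel_intensity list `(min, max)` of the uniform vessel signal
#'   support.
#' @param noise_intensity list `(min, max)` of the uniform background noise
#'   support.
#' @param bit_depth 8 or 16.
#' @param branch_prob per-step probability that a walker spawns a branch.
#' @param n_large_vessels arteriole-like wide vessels added to the SCP only.
#' @param large_vessel_width_px width of those vessels.
#' @param rng_seed integer seed; all randomness flows from it through
#'   per-plexus, per-phase L'Ecuyer substreams, so adding draws to one phase
#'   does not perturb the others.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = 304L, fov_mm = 3.0, n_seeds = 64L,
                           vessel_width_px = c(1L, 3L),
                           dropout_fraction = 0.0, faz_radius_mm = 0.25,
                           vessel_intensity = list(min = 150, max = 230),
                           noise_intensity = list(min = 20, max = 55),
                           bit_depth = 8L, branch_prob = 0.05,
                           n_large_vessels = 4L, large_vessel_width_px = 5L,
                           rng_seed = 1L) {
  if (dropout_fraction < 0 || dropout_fraction > 1)
    stop("dropout_fraction must lie in [0, 1]")
  if (noise_intensity$min > noise_intensity$max ||
      vessel_intensity$min > vessel_intensity$max)
    stop("intensity supports must have min <= max")
  if (noise_intensity$min >= vessel_intensity$min)
    stop("noise support must sit below the vessel support")
  if (faz_radius_mm * 2 >= fov_mm)
    stop("avascular zone larger than the field of view")
  structure(list(shape = as.integer(shape), fov_mm = fov_mm,
                 n_seeds = as.integer(n_seeds),
                 vessel_width_px = as.integer(vessel_width_px),
                 dropout_fraction = dropout_fraction,
                 faz_radius_mm = faz_radius_mm,
                 vessel_intensity = vessel_intensity,
                 noise_intensity = noise_intensity,
                 bit_depth = as.integer(bit_depth),
                 branch_prob = branch_prob,
                 n_large_vessels = as.integer(n_large_vessels),
                 large_vessel_width_px = as.integer(large_vessel_width_px),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# n independent L'Ecuyer-CMRG substreams derived from one seed
rng_streams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  out
}

with_stream <- function(stream, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  old_kind <- RNGkind()
  assign(".Random.seed", stream, globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  force(expr)
}

# Biased random walkers with stochastic branching; returns a list of
# branches, each an integer matrix of (row, col) 1-based pixel coordinates.
grow_network <- function(shape, n_seeds, faz_r_px, branch_prob, step_budget,
                         turn_sd = 0.35) {
  h <- shape; w <- shape
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  # seeds: half enter from the border heading inward, half interior
  n_border <- ceiling(n_seeds / 2)
  walkers <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    if (i <= n_border) {
      side <- sample.int(4L, 1L)
      u <- runif(1, 0, w - 1)
      pos <- switch(side, c(u, 0), c(u, h - 1), c(0, u), c(w - 1, u))
      theta <- atan2(cy - pos[2], cx - pos[1]) + rnorm(1, 0, 0.5)
    } else {
      pos <- c(runif(1, 0, w - 1), runif(1, 0, h - 1))
      theta <- runif(1, -pi, pi)
    }
    walkers[[i]] <- list(x = pos[1], y = pos[2], theta = theta)
  }
  branches <- list()
  steps_used <- 0L
  qi <- 1L
  while (qi <= length(walkers) && steps_used < step_budget) {
    wk <- walkers[[qi]]
    qi <- qi + 1L
    x <- wk$x; y <- wk$y; theta <- wk$theta
    max_steps <- min(600L, step_budget - steps_used)
    rr <- integer(max_steps); cc <- integer(max_steps)
    nsteg <- 0L
    for (s in seq_len(max_steps)) {
      theta <- theta + rnorm(1, 0, turn_sd)
      x2 <- x + cos(theta); y2 <- y + sin(theta)
      # steer away from the avascular zone
      d <- sqrt((x2 - cx)^2 + (y2 - cy)^2)
      if (d < faz_r_px + 1) {
        theta <- atan2(y2 - cy, x2 - cx) + rnorm(1, 0, 0.3)
        x2 <- x + cos(theta); y2 <- y + sin(theta)
        if (sqrt((x2 - cx)^2 + (y2 - cy)^2) < faz_r_px) break
      }
      if (x2 < 0 || x2 > w - 1 || y2 < 0 || y2 > h - 1) break
      x <- x2; y <- y2
      nsteg <- nsteg + 1L
      rr[nsteg] <- as.integer(round(y)) + 1L
      cc[nsteg] <- as.integer(round(x)) + 1L
      if (runif(1) < branch_prob && length(walkers) < 4L * n_seeds + 512L) {
        walkers[[length(walkers) + 1L]] <-
          list(x = x, y = y,
               theta = theta + sample(c(-1, 1), 1) * runif(1, pi / 4, pi / 2.5))
      }
    }
    steps_used <- steps_used + nsteg
    if (nsteg > 2L)
      branches[[length(branches) + 1L]] <- cbind(rr[seq_len(nsteg)],
                                                 cc[seq_len(nsteg)])
  }
  branches
}

# render centreline pixels at a given width
thicken <- function(mask, width) {
  if (width <= 1L) return(mask)
  if (width == 2L) {
    h <- nrow(mask); w <- ncol(mask)
    out <- mask
    out[, -1] <- out[, -1] | mask[, -w]
    out[-1, ] <- out[-1, ] | mask[-h, ]
    out[-1, -1] <- out[-1, -1] | mask[-h, -w]
    return(out)
  }
  binary_dilate(mask, (width - 1) / 2)
}

draw_plexus <- function(shape, branches, widths) {
  vessel <- matrix(FALSE, shape, shape)
  centre <- matrix(FALSE, shape, shape)
  for (wdt in sort(unique(widths))) {
    m <- matrix(FALSE, shape, shape)
    for (b in which(widths == wdt)) {
      px <- branches[[b]]
      m[px] <- TRUE
    }
    centre <- centre | m
    vessel <- vessel | thicken(m, wdt)
  }
  list(vessel = vessel, centreline = centre)
}

sample_uniform_int <- function(n, lim) {
  as.integer(floor(runif(n, lim$min, lim$max + 1)))
}

#' Generate a synthetic multi-plexus angiogram with ground truth
#'
#' Grows seeded branched random-walk capillary networks per plexus (the SCP
#' additionally receives a few wide, arteriole-like vessels), deletes a
#' `dropout_fraction` of branches, renders vessel and background pixels from
#' the two intensity distributions, and records ground truth (vessel mask,
#' centreline skeleton, parafoveal true VD/VLD, and the highest intensity
#' attainable by pure noise) before intensity sampling.  The full-retina slab
#' is the projection (union) of the three plexus networks.  Bit-identical
#' reproducible for a fixed `rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param plexuses which capillary plexuses to generate (default all three
#'   plus the full-retina projection).  Substreams are bound to plexus
#'   identity, so e.g. the DCP generated alone is bit-identical to the DCP
#'   of a full run with the same seed.
#' @return list with `images` (named list of [enface_image()]s for SCP, MCP,
#'   DCP, RETINA) and `truth` (per-plexus `vessel_mask`, `skeleton`,
#'   `true_vd_pct`, `true_vld_per_mm`, plus `boundary_t` and the annulus
#'   mask used for the true parafoveal metrics).
#' @export
generate_angiogram <- function(spec = synthetic_spec(),
                               plexuses = c("SCP", "MCP", "DCP", "RETINA")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  plexuses <- match.arg(plexuses, several.ok = TRUE)
  shape <- spec$shape
  scale <- pixel_scale(spec$fov_mm, shape)
  faz_r_px <- spec$faz_radius_mm / scale$mm_per_px
  step_budget <- max(500L, as.integer(round(0.32 * shape * shape)))
  streams <- rng_streams(spec$rng_seed, 12L)
  grow <- intersect(c("SCP", "MCP", "DCP"),
                    if ("RETINA" %in% plexuses) c("SCP", "MCP", "DCP")
                    else plexuses)
  ann <- make_parafoveal_mask(
    c(shape, shape),
    annulus_spec(outer_diameter_mm = min(3, spec$fov_mm),
                 inner_diameter_mm = min(1, spec$fov_mm / 3)),
    scale)
  truth <- list()
  masks <- list()
  images <- list()
  maxv <- 2L^spec$bit_depth - 1L
  for (p in grow) {
    i <- match(p, c("SCP", "MCP", "DCP"))
    branches <- with_stream(streams[[3 * i - 2]], {
      grow_network(shape, spec$n_seeds, faz_r_px, spec$branch_prob,
                   step_budget)
    })
    keepwidths <- with_stream(streams[[3 * i - 1]], {
      nb <- length(branches)
      widths <- sample(spec$vessel_width_px[1]:spec$vessel_width_px[2], nb,
                       replace = TRUE)
      if (p == "SCP" && spec$n_large_vessels > 0 && nb > 0) {
        big <- sample.int(nb, min(spec$n_large_vessels, nb))
        widths[big] <- spec$large_vessel_width_px
      }
      keep <- runif(nb) >= spec$dropout_fraction
      list(keep = keep, widths = widths)
    })
    kept <- which(keepwidths$keep)
    drawn <- draw_plexus(shape, branches[kept], keepwidths$widths[kept])
    ann_n <- sum(ann)
    truth[[p]] <- list(
      vessel_mask = drawn$vessel,
      skeleton = drawn$centreline,
      true_vd_pct = 100 * sum(drawn$vessel & ann) / ann_n,
      true_vld_per_mm = sum(drawn$centreline & ann) * scale$mm_per_px /
        mask_area_mm2(ann, scale))
    masks[[p]] <- drawn$vessel
    pix <- with_stream(streams[[3 * i]], {
      img <- matrix(sample_uniform_int(shape * shape, spec$noise_intensity),
                    shape, shape)
      nv <- sum(drawn$vessel)
      img[drawn$vessel] <- sample_uniform_int(nv, spec$vessel_intensity)
      img
    })
    pix[pix < 0L] <- 0L; pix[pix > maxv] <- maxv
    images[[p]] <- enface_image(pix, p, spec$fov_mm, spec$bit_depth)
  }
  if ("RETINA" %in% plexuses) {
    retina_mask <- masks$SCP | masks$MCP | masks$DCP
    retina_pix <- with_stream(streams[[10]], {
      img <- matrix(sample_uniform_int(shape * shape, spec$noise_intensity),
                    shape, shape)
      img[retina_mask] <- sample_uniform_int(sum(retina_mask),
                                             spec$vessel_intensity)
      img
    })
    retina_pix[retina_pix < 0L] <- 0L; retina_pix[retina_pix > maxv] <- maxv
    images$RETINA <- enface_image(retina_pix, "RETINA", spec$fov_mm,
                                  spec$bit_depth)
    truth$RETINA <- list(vessel_mask = retina_mask)
  }
  disjoint <- spec$noise_intensity$max < spec$vessel_intensity$min
  boundary_t <- if (disjoint) spec$noise_intensity$max else
    spec$noise_intensity$min +
      0.999 * (spec$noise_intensity$max - spec$noise_intensity$min)
  truth$boundary_t <- boundary_t
  truth$parafoveal_mask <- ann
  list(images = images, truth = truth)
}

# --- synthetic cohorts -----------------------------------------------------

#' Default per-stage parameter means and dispersions for synthetic cohorts
#'
#' Stage order: healthy, diabetes without retinopathy, mild, moderate and
#' severe NPDR.  Values approximate published covariate-adjusted cohort
#' summaries of the parafoveal parameters.
#' @keywords internal
default_param_table <- function() {
  params <- c("SCP_VD", "MCP_VD", "DCP_VD", "SCP_VLD", "SCP_AFI", "MCP_AFI",
              "DCP_AFI", "FAZ")
  means <- rbind(
    SCP_VD  = c(46.38, 45.76, 40.72, 40.12, 35.52),
    MCP_VD  = c(46.83, 45.61, 43.05, 41.03, 37.23),
    DCP_VD  = c(42.05, 41.15, 38.52, 36.87, 34.16),
    SCP_VLD = c(16.84, 16.92, 14.58, 13.92, 12.39),
    SCP_AFI = c(0.428, 0.428, 0.434, 0.439, 0.445),
    MCP_AFI = c(0.434, 0.435, 0.429, 0.427, 0.423),
    DCP_AFI = c(0.421, 0.423, 0.422, 0.415, 0.410),
    FAZ     = c(0.262, 0.212, 0.259, 0.335, 0.390))
  sds <- rbind(
    SCP_VD  = c(4.93, 4.77, 4.74, 4.84, 4.79),
    MCP_VD  = c(4.48, 4.34, 4.31, 4.40, 4.35),
    DCP_VD  = c(4.60, 4.45, 4.42, 4.51, 4.46),
    SCP_VLD = c(1.82, 1.76, 1.75, 1.78, 1.76),
    SCP_AFI = c(0.015, 0.014, 0.014, 0.014, 0.013),
    MCP_AFI = c(0.015, 0.014, 0.014, 0.014, 0.013),
    DCP_AFI = c(0.020, 0.019, 0.018, 0.018, 0.021),
    FAZ     = c(0.122, 0.120, 0.119, 0.124, 0.119))
  colnames(means) <- colnames(sds) <- as.character(0:4)
  list(params = params, means = means, sds = sds)
}

#' Synthetic cohort specification
#'
#' Group sizes, per-stage parameter means/SDs, and per-stage covariate
#' distributions default to the published cohort structure (24/23/21/21/18
#' eyes across stages 0-4; ages in the late-40s to mid-50s; Q-scores around
#' 7.6-8.5).  `covariate_effects` optionally adds linear age and Q-score
#' effects to every parameter (units per year / per Q-point, applied around
#' reference values of 52 years and Q = 8), producing confounded cohorts for
#' exercising covariate adjustment.
#'
#' @param n_per_group named integer vector, names `"0"`..`"4"`.
#' @param param_means,param_sds numeric matrices, rows = parameters,
#'   columns = stages `"0"`..`"4"`.
#' @param age_mean,age_sd,q_mean,q_sd,ssi_mean,ssi_sd per-stage covariate
#'   distribution parameters (length 5).
#' @param male_prob per-stage probability of male sex.
#' @param covariate_effects optional list per parameter:
#'   `list(SCP_VD = c(age = -0.1, q_score = 1.5), ...)`.
#' @param rng_seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(`0` = 24L, `1` = 23L, `2` = 21L,
                                        `3` = 21L, `4` = 18L),
                        param_means = NULL, param_sds = NULL,
                        age_mean = c(46.54, 53.04, 52.71, 56.81, 55.94),
                        age_sd = c(13.35, 13.99, 13.76, 10.88, 11.39),
                        q_mean = c(8.46, 8.17, 7.86, 7.57, 7.67),
                        q_sd = c(0.83, 0.65, 0.85, 1.08, 0.77),
                        ssi_mean = c(71.0, 68.1, 66.4, 64.1, 64.5),
                        ssi_sd = c(6.3, 5.7, 6.8, 8.0, 6.3),
                        male_prob = c(9, 8, 8, 8, 6) /
                                    c(24, 23, 21, 21, 18),
                        covariate_effects = NULL, rng_seed = 1L) {
  def <- default_param_table()
  param_means <- param_means %||% def$means
  param_sds <- param_sds %||% def$sds
  if (any(n_per_group <= 0)) stop("group counts must be positive")
  if (any(param_sds < 0)) stop("parameter SDs must be non-negative")
  structure(list(n_per_group = n_per_group, param_means = param_means,
                 param_sds = param_sds, age_mean = age_mean, age_sd = age_sd,
                 q_mean = q_mean, q_sd = q_sd, ssi_mean = ssi_mean,
                 ssi_sd = ssi_sd, male_prob = male_prob,
                 covariate_effects = covariate_effects,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic per-eye cohort table
#'
#' Draws per-eye covariates (age truncated to 25-75 years, Q-score to
#' `[0, 10]`, SSI, sex) from stage-specific distributions and per-eye
#' parameters from per-stage normal distributions, optionally shifted by
#' linear covariate effects (see [cohort_spec()]).  Reproducible for a fixed
#' seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame, one row per eye, validated as an eye table.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  streams <- rng_streams(spec$rng_seed, 5L)
  rows <- list()
  stages <- as.integer(names(spec$n_per_group))
  for (k in seq_along(stages)) {
    st <- stages[k]
    n <- spec$n_per_group[k]
    rows[[k]] <- with_stream(streams[[k]], {
      age <- rnorm_trunc(n, spec$age_mean[k], spec$age_sd[k], 25, 75)
      q <- rnorm_trunc(n, spec$q_mean[k], spec$q_sd[k], 0, 10)
      ssi <- rnorm(n, spec$ssi_mean[k], spec$ssi_sd[k])
      sex <- ifelse(runif(n) < spec$male_prob[k], "M", "F")
      tab <- data.frame(eye_id = sprintf("S%d_%03d", st, seq_len(n)),
                        stage = st, age = age, sex = sex, q_score = q,
                        ssi = ssi, cmt_um = NA_real_,
                        stringsAsFactors = FALSE)
      for (p in rownames(spec$param_means)) {
        mu <- spec$param_means[p, as.character(st)]
        sdv <- spec$param_sds[p, as.character(st)]
        eff <- spec$covariate_effects[[p]]
        if (!is.null(eff))
          mu <- mu + eff[["age"]] * (age - 52) + eff[["q_score"]] * (q - 8)
        tab[[p]] <- rnorm(n, mu, sdv)
      }
      tab
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_eye_table(out)
  out
}
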