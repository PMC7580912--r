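test_that("binarize follows the >= convention and matches brute force", {
  const <- enface_image(matrix(100L, 20, 20), "DCP")
  expect_true(all(binarize(const, 100)))
  expect_false(any(binarize(const, 101)))
  img <- random_enface(21)
  for (t in c(0L, 37L, 128L, 255L)) {
    expect_identical(binarize(img, t), img$pixels >= t)
  }
  expect_error(binarize(img, 300), "intensity range")
})

test_that("foreground count is non-increasing in the threshold", {
  for (seed in 1:5) {
    img <- random_enface(seed, n = 32)
    counts <- vapply(0:255, function(t) sum(binarize(img, t)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("skeletonization thins a wide bar to a unit-width line", {
  bar <- matrix(FALSE, 60, 60)
  bar[20:22, 5:54] <- TRUE            # 3 px wide, 50 px long
  sk <- skeletonize(bar)
  expect_true(all(bar[sk]))
  expect_false(has_2x2_block(sk))
  expect_lte(abs(sum(sk) - 50), 2)
  # single pixel is a fixed point; empty map stays empty
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_identical(skeletonize(one), one)
  expect_identical(skeletonize(matrix(FALSE, 7, 7)), matrix(FALSE, 7, 7))
})

test_that("skeleton contract holds on random blob fixtures", {
  for (seed in 1:20) {
    m <- random_blob_mask(seed)
    sk <- skeletonize(m)
    expect_true(all(m[sk]), info = paste("subset, seed", seed))
    expect_false(has_2x2_block(sk), info = paste("2x2, seed", seed))
    expect_identical(octaquant:::cpp_count_components(sk, 8L),
                     octaquant:::cpp_count_components(m, 8L),
                     info = paste("components, seed", seed))
  }
})

test_that("component counting agrees with an independent union-find oracle", {
  for (seed in 101:110) {
    m <- random_blob_mask(seed, n = 30, n_points = 12, radius = 1)
    expect_identical(octaquant:::cpp_count_components(m, 8L),
                     rcount_components(m, 8))
    expect_identical(octaquant:::cpp_count_components(m, 4L),
                     rcount_components(m, 4))
  }
})

test_that("sweep curve equals an independent binarize+skeletonize loop", {
  img <- small_eye(31, shape = 64)$images$DCP
  curve <- sweep_vld_curve(img, 10L, 200L)
  oracle <- vapply(10:200, function(t) sum(skeletonize(binarize(img, t))),
                   integer(1))
  expect_identical(curve$vld_counts, oracle)
  expect_true(all(curve$vld_counts >= 0 &
                  curve$vld_counts <= length(img$pixels)))
})

test_that("sweep on a constant image drops to zero above the constant", {
  img <- enface_image(matrix(100L, 30, 30), "DCP")
  curve <- sweep_vld_curve(img, 1L, 254L)
  expect_true(all(curve$vld_counts[curve$thresholds > 100] == 0L))
  expect_true(all(curve$vld_counts[curve$thresholds <= 100] ==
                  curve$vld_counts[1]))
  expect_error(sweep_vld_curve(img, 50L, 50L), "degenerate")
})

test_that("two-segment fit recovers exact piecewise-linear geometry", {
  curve <- piecewise_curve(1:120, break_t = 60, m1 = -50, m2 = -1)
  fit <- fit_two_segment(curve, min_segment = 10L)
  # the crossing lies on a data point, so the point at t = 60 fits either
  # segment exactly and the SSE-optimal breakpoint may sit one unit early
  expect_lte(abs(fit$breakpoint - 60), 1)
  expect_lt(abs(fit$intersection_x - 60), 1e-6)
  expect_lt(fit$total_sse, 1e-12)
  expect_equal(unname(fit$noise_line["slope"]), -50)
  expect_equal(unname(fit$signal_line["slope"]), -1)
})

test_that("degenerate fits error out", {
  # one straight line: both segments share a slope
  line <- structure(list(thresholds = 1:60, vld_counts = 3000 - 5 * (1:60)),
                    class = "threshold_curve")
  expect_error(fit_two_segment(line), "degenerate")
  short <- piecewise_curve(1:15, 8, -50, -1)
  expect_error(fit_two_segment(short, min_segment = 10L), "min_segment")
})

test_that("fit tolerates noise: intersection within 3 units in >=95% of runs", {
  set.seed(2026)
  truth <- 60
  hits <- 0L
  for (i in 1:100) {
    y <- piecewise_curve(1:120, truth, -50, -1)$vld_counts
    y <- y + rnorm(120, 0, 0.01 * diff(range(y)))
    curve <- structure(list(thresholds = 1:120, vld_counts = y),
                       class = "threshold_curve")
    fit <- tryCatch(fit_two_segment(curve), error = function(e) NULL)
    if (!is.null(fit) && abs(fit$intersection_x - truth) <= 3) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("mean threshold equals the rounded arithmetic mean", {
  half <- enface_image(matrix(c(rep(0L, 50), rep(100L, 50)), 10, 10), "SCP")
  expect_identical(mean_threshold(half), 50L)
  expect_identical(mean_threshold(enface_image(matrix(77L, 5, 5), "SCP")), 77L)
  img <- random_enface(77)
  expect_identical(mean_threshold(img),
                   as.integer(floor(mean(img$pixels) + 0.5)))
})

test_that("Huang threshold separates tight bimodal modes and is the argmin", {
  set.seed(8)
  g <- c(rep(30L, 500), rep(200L, 400), sample(28:32, 60, TRUE),
         sample(198:202, 40, TRUE))
  n <- 31L
  img <- enface_image(matrix(g[1:(n * n)], n, n), "DCP")
  t_hat <- huang_threshold(img)
  expect_gt(t_hat, 32)
  expect_lte(t_hat, 198)
  # independent exhaustive evaluation of the fuzziness criterion
  crit <- function(t) {
    v <- as.vector(img$pixels)
    C <- max(v) - min(v)
    mu0 <- mean(v[v < t]); mu1 <- mean(v[v >= t])
    mu <- ifelse(v < t, mu0, mu1)
    u <- 1 / (1 + abs(v - mu) / C)
    sum(ifelse(u > 1 - 1e-12, 0, -u * log(u) - (1 - u) * log(1 - u)))
  }
  cand <- (min(img$pixels) + 1L):max(img$pixels)
  vals <- vapply(cand, crit, numeric(1))
  expect_identical(t_hat, cand[which.min(vals)])
  expect_error(huang_threshold(enface_image(matrix(9L, 4, 4), "DCP")),
               "no-threshold")
})

test_that("VLD threshold is deterministic and rotation invariant", {
  eye <- small_eye(55, shape = 120)
  t1 <- compute_vld_threshold(eye$images$DCP)
  t2 <- compute_vld_threshold(eye$images$DCP)
  expect_identical(t1$threshold, t2$threshold)
  rot <- enface_image(t(eye$images$DCP$pixels)[, 120:1], "DCP")
  t3 <- compute_vld_threshold(rot)
  expect_lte(abs(t3$threshold - t1$threshold), 1)
})

test_that("VLD threshold lands in the noise/signal gap on disjoint supports", {
  for (seed in 1:5) {
    eye <- generate_angiogram(synthetic_spec(shape = 140L, rng_seed = seed),
                              plexuses = "DCP")
    tr <- compute_vld_threshold(eye$images$DCP)
    expect_gt(tr$threshold, eye$truth$boundary_t)
    expect_lte(tr$threshold, 150)
    # ground-truth membership: >=99% of pure-noise pixels below the cutoff
    noise_px <- eye$images$DCP$pixels[!eye$truth$DCP$vessel_mask]
    vessel_px <- eye$images$DCP$pixels[eye$truth$DCP$vessel_mask]
    expect_gte(mean(noise_px < tr$threshold), 0.99)
    expect_gte(mean(vessel_px >= tr$threshold), 0.95)
  }
})
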