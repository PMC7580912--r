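# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; nothing binary ships with the package.

# a small random en-face image with the given intensity range
random_enface <- function(seed, n = 48L, lo = 0L, hi = 255L, plexus = "DCP",
                          bit_depth = 8L) {
  set.seed(seed)
  enface_image(matrix(sample(lo:hi, n * n, replace = TRUE), n, n),
               plexus, fov_mm = 3.0, bit_depth = bit_depth)
}

# random blobby binary mask: dilated random points
random_blob_mask <- function(seed, n = 40L, n_points = 25L, radius = 2L) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  idx <- cbind(sample.int(n, n_points, TRUE), sample.int(n, n_points, TRUE))
  m[idx] <- TRUE
  octaquant:::binary_dilate(m, radius)
}

# small synthetic eye (all four slabs) for pipeline-level tests
small_eye <- function(seed, shape = 120L, dropout = 0, ...) {
  generate_angiogram(synthetic_spec(shape = shape, rng_seed = seed,
                                    dropout_fraction = dropout, ...))
}

# independent component counter used as an oracle against the C++ one:
# union-find over explicit neighbour pairs
rcount_components <- function(mask, connectivity = 8) {
  n <- sum(mask)
  if (n == 0) return(0L)
  idx <- which(mask, arr.ind = TRUE)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[mask] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  offs <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1)) else rbind(c(-1,0), c(0,-1))
  for (k in seq_len(nrow(idx))) {
    r <- idx[k,1]; c <- idx[k,2]
    for (o in seq_len(nrow(offs))) {
      rr <- r + offs[o,1]; cc <- c + offs[o,2]
      if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
          mask[rr, cc]) union2(id[r, c], id[rr, cc])
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# TRUE iff the mask contains a fully-foreground 2x2 block
has_2x2_block <- function(m) {
  h <- nrow(m); w <- ncol(m)
  any(m[-h, -w] & m[-1, -w] & m[-h, -1] & m[-1, -1])
}

# exact two-piece linear curve: slope m1 up to break_t, slope m2 after,
# lines crossing exactly at break_t
piecewise_curve <- function(t, break_t, m1, m2, y_at_break = 2000) {
  y1 <- y_at_break + m1 * (t - break_t)
  y2 <- y_at_break + m2 * (t - break_t)
  y <- ifelse(t <= break_t, y1, y2)
  structure(list(thresholds = t, vld_counts = y), class = "threshold_curve")
}
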