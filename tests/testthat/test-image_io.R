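test_that("PNG and TIFF round trips preserve pixels at both bit depths", {
  for (depth in c(8L, 16L)) {
    img <- random_enface(100 + depth, n = 40, hi = 2L^depth - 1L,
                         bit_depth = depth)
    for (ext in c("png", "tif")) {
      path <- withr::local_tempfile(fileext = paste0(".", ext))
      write_enface(img, path)
      back <- load_enface(path, "DCP")
      expect_identical(back$pixels, img$pixels,
                       info = sprintf("%d-bit %s", depth, ext))
      expect_identical(back$bit_depth, depth)
    }
  }
})

test_that("PNG reader reconstructs all scanline filter types", {
  # hand-build a PNG whose rows use filters 0..4; decode must match the
  # plain pixel matrix
  set.seed(42)
  h <- 5L; w <- 7L
  pix <- matrix(sample(0:255, h * w, TRUE), h, w)
  rows <- lapply(seq_len(h), function(r) as.integer(pix[r, ]))
  filt <- list()
  prev <- rep(0L, w)
  for (r in seq_len(h)) {
    cur <- rows[[r]]
    ft <- (r - 1L) %% 5L
    enc <- integer(w)
    for (x in seq_len(w)) {
      a <- if (x > 1) cur[x - 1] else 0L
      b <- prev[x]
      cc <- if (x > 1) prev[x - 1] else 0L
      pred <- switch(ft + 1L, 0L, a, b, (a + b) %/% 2L, {
        p <- a + b - cc
        pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
        if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
      })
      enc[x] <- (cur[x] - pred) %% 256L
    }
    filt[[r]] <- c(ft, enc)
    prev <- cur
  }
  raw_scan <- as.raw(unlist(filt))
  ihdr <- c(octaquant:::u32be(w), octaquant:::u32be(h),
            as.raw(c(8L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(raw_scan, type = "gzip")
  path <- withr::local_tempfile(fileext = ".png")
  out <- c(octaquant:::PNG_SIG, octaquant:::png_chunk("IHDR", ihdr),
           octaquant:::png_chunk("IDAT", idat),
           octaquant:::png_chunk("IEND", raw(0)))
  writeBin(out, path)
  r <- octaquant:::read_gray_png(path)
  expect_identical(r$pixels, pix)
})

test_that("multi-channel and non-square rasters are rejected", {
  # craft an RGB (colour type 2) PNG via the chunk writer
  path <- withr::local_tempfile(fileext = ".png")
  ihdr <- c(octaquant:::u32be(2L), octaquant:::u32be(2L),
            as.raw(c(8L, 2L, 0L, 0L, 0L)))
  scan <- as.raw(c(0, rep(10, 6), 0, rep(20, 6)))  # 2 rows, 3 bytes/px
  idat <- memCompress(scan, type = "gzip")
  writeBin(c(octaquant:::PNG_SIG, octaquant:::png_chunk("IHDR", ihdr),
             octaquant:::png_chunk("IDAT", idat),
             octaquant:::png_chunk("IEND", raw(0))), path)
  expect_error(load_enface(path, "DCP"), "colour type")

  path2 <- withr::local_tempfile(fileext = ".png")
  octaquant:::write_gray_png(matrix(0L, 10, 20), path2)
  expect_error(load_enface(path2, "SCP"), "square")

  expect_error(enface_image(matrix(0L, 3, 3), "DCP", bit_depth = 12),
               "bit_depth")
  expect_error(enface_image(matrix(300L, 3, 3), "DCP"), "intensities")
})

test_that("normalize_intensity maps the range onto [0,1] monotonically", {
  img <- random_enface(7, n = 16)
  nm <- normalize_intensity(img)
  expect_equal(nm, img$pixels / 255)
  expect_true(all(nm >= 0 & nm <= 1))
  # strict monotonicity on the value scale
  img2 <- enface_image(matrix(c(0L, 51L, 128L, 255L), 2, 2), "SCP")
  expect_equal(sort(as.vector(normalize_intensity(img2))),
               c(0, 0.2, 128 / 255, 1))
  o <- order(as.vector(img$pixels))
  expect_true(all(diff(as.vector(nm)[o]) >= 0))
})

test_that("qc_eligible applies the boundary rules exactly as worded", {
  # >= for Q-score and SSI; strict > for macular thickness
  ok <- qc_eligible(list(q_score = 6, ssi = 50, sex = "M", cmt_um = 320))
  expect_true(ok$eligible)
  expect_length(ok$failed, 0)

  bad_q <- qc_eligible(list(q_score = 5, ssi = 70, sex = "M", cmt_um = 300))
  expect_false(bad_q$eligible)
  expect_identical(bad_q$failed, "q_score")

  edema <- qc_eligible(list(q_score = 8, ssi = 60, sex = "F", cmt_um = 306))
  expect_false(edema$eligible)
  expect_identical(edema$failed, "macular_edema")

  skipped <- qc_eligible(list(q_score = 9))
  expect_true(skipped$eligible)
  expect_setequal(skipped$skipped, c("ssi", "macular_edema"))
})

test_that("qc eligibility is monotone in q_score and ssi", {
  set.seed(11)
  for (i in 1:50) {
    q <- runif(1, 0, 12); s <- runif(1, 30, 90)
    rec <- list(q_score = q, ssi = s, sex = "M", cmt_um = runif(1, 250, 350))
    up <- list(q_score = q + runif(1, 0, 5), ssi = s + runif(1, 0, 30),
               sex = rec$sex, cmt_um = rec$cmt_um)
    if (qc_eligible(rec)$eligible) expect_true(qc_eligible(up)$eligible)
  }
})

test_that("parameter tables round-trip and are validated", {
  tab <- do.call(rbind, lapply(0:4, function(s)
    eye_record(paste0("E", s), s, age = 40 + s, sex = "F", q_score = 8,
               ssi = 60, params = list(SCP_VD = 45 - s))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(tab, path)
  back <- load_parameter_table(path)
  expect_equal(nrow(back), 5)
  expect_equal(back$SCP_VD, tab$SCP_VD)
  expect_equal(back$stage, tab$stage)

  bad <- tab; bad$stage[2] <- 7L
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(load_parameter_table(path2), "stage")

  nostage <- tab; nostage$stage <- NULL
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(nostage, path3, row.names = FALSE)
  expect_error(load_parameter_table(path3), "stage")
})

test_that("mask rasters round-trip as binary", {
  m <- random_blob_mask(5)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)
  expect_identical(load_mask(path), m)
})
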