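test_that("guidewire detection handles perfect and degenerate shadows", {
  fr <- matrix(0.6, 200, 448)
  fr[, 100:130] <- 0
  expect_identical(detect_guidewire(fr), 100:130)
  expect_identical(detect_guidewire(matrix(0.5, 200, 448)), integer(0))
})

test_that("guidewire detection matches exhaustive band search on phantoms", {
  for (s in 1:5) {
    sim <- generate_pullback(small_phantom_config(100 + s, n_frames = 1))
    fr <- sim$pullback$frames[, , 1]
    truth <- sim$truth$guidewire_alines[[1]]
    det <- detect_guidewire(fr, width_range = c(4L, 10L))
    # exhaustive search: minimal mean depth-summed intensity over all
    # contiguous wrapped bands of the true width
    s_col <- colMeans(fr)
    n <- length(s_col); w <- length(truth)
    band_means <- vapply(seq_len(n), function(st)
      mean(s_col[((st - 1 + 0:(w - 1)) %% n) + 1]), numeric(1))
    oracle <- ((which.min(band_means) - 1 + 0:(w - 1)) %% n) + 1
    expect_lte(max(abs(range(det) - range(truth))), 2)
    expect_lte(max(abs(range(det) - range(oracle))), 2)
  }
})

test_that("lumen segmentation finds a step edge exactly", {
  fr <- matrix(0, 200, 64)
  fr[51:200, ] <- 0.8
  lb <- segment_lumen(fr)
  expect_identical(lb$boundary, rep(50L, 64))
})

test_that("lumen segmentation tracks a sinusoidal phantom within 2 pixels", {
  for (s in 1:3) {
    sim <- generate_pullback(small_phantom_config(200 + s, n_frames = 1))
    fr <- sim$pullback$frames[, , 1]
    gw <- detect_guidewire(fr, width_range = c(4L, 10L))
    lb <- segment_lumen(fr, gw)
    err <- abs(lb$boundary - sim$truth$lumen_boundary[, 1])
    expect_lte(max(err), 2)
  }
})

test_that("lumen segmentation is equivariant under theta rotation", {
  sim <- generate_pullback(small_phantom_config(42, n_frames = 1))
  fr <- sim$pullback$frames[, , 1]
  b0 <- segment_lumen(fr)$boundary
  k <- 13L
  rot <- fr[, c((k + 1):ncol(fr), 1:k)]
  bk <- segment_lumen(rot)$boundary
  expect_equal(bk, b0[c((k + 1):ncol(fr), 1:k)])
})

test_that("all-dark frames are rejected", {
  expect_error(segment_lumen(matrix(0.001, 100, 32)), "no detectable lumen")
})

test_that("pixel shifting aligns, records, and inverts", {
  fr <- matrix(runif(100 * 16), 100, 16)
  sh <- pixel_shift(fr, rep(7L, 16))
  expect_equal(sh$frame[1:93, ], fr[8:100, ])
  expect_true(all(sh$frame[94:100, ] == 0))
  expect_identical(sh$shift, rep(7L, 16))
  # inverse on retained pixels
  b <- sample(0:20, 16, replace = TRUE)
  sh2 <- pixel_shift(fr, b)
  back <- unshift(sh2$frame, sh2$shift)
  for (j in 1:16)
    expect_equal(back[(b[j] + 1):100, j], fr[(b[j] + 1):100, j])
  expect_error(pixel_shift(fr, rep(100L, 16)), "out of range")
})

test_that("shifted truth masks preserve column thickness", {
  sim <- generate_pullback(small_phantom_config(6, n_frames = 2))
  pp <- preprocess_pullback(sim$pullback, depth = 48L,
                            guidewire_width_range = c(4L, 10L))
  pm <- preprocess_mask(sim$truth$fc_mask_raw, pp$shifts, 48L)
  th <- aline_thickness(pm, sim$pullback$pixel_size_r)
  d <- th - sim$truth$thickness_truth
  expect_true(all(abs(d[!is.na(d)]) < 1e-9))
  expect_identical(is.na(th), is.na(sim$truth$thickness_truth))
})

test_that("depth cropping follows slice semantics", {
  fr <- matrix(seq_len(968 * 8), 968, 8)
  out <- crop_depth(fr, 200L)
  expect_equal(dim(out), c(200L, 8L))
  expect_identical(out, fr[1:200, ])
  expect_identical(crop_depth(fr, 968L), fr)
  expect_error(crop_depth(fr[1:100, ], 200L), "fewer than")
})

test_that("Gaussian smoothing is normalized, exact, and mass-conserving", {
  expect_equal(smooth_frame(matrix(0.4, 30, 40)), matrix(0.4, 30, 40),
               tolerance = 1e-12)
  # impulse response equals the analytically normalized truncated Gaussian
  fr <- matrix(0, 31, 41)
  fr[16, 21] <- 1
  out <- smooth_frame(fr)
  off <- -3:3
  k <- exp(-outer(off^2, off^2, "+") / 2)
  k <- k / sum(k)
  expect_lt(max(abs(out[13:19, 18:24] - k)), 1e-6)
  expect_lt(max(abs(out[-(13:19), ])), 1e-12)
  # total intensity of interior-supported images conserved
  fr2 <- matrix(0, 50, 60)
  fr2[20:30, 25:35] <- runif(11 * 11)
  expect_equal(sum(smooth_frame(fr2)), sum(fr2), tolerance = 1e-6)
})

test_that("preprocessing maps raw 968x448 to 200x448 and guards state", {
  sim <- generate_pullback(phantom_config(n_frames = 1, seed = 31))
  pp <- preprocess_pullback(sim$pullback)
  expect_equal(dim(pp$pullback$frames), c(200L, 448L, 1L))
  expect_true(pp$pullback$preprocessed)
  expect_equal(range(pp$pullback$frames), c(0, 1))
  # guidewire A-lines carry the black strip
  gw <- pp$guidewire[[1]]
  expect_gt(length(gw), 0)
  expect_lt(mean(pp$pullback$frames[, gw, 1]), 0.05)
  expect_error(preprocess_pullback(pp$pullback), "already preprocessed")
})

test_that("caps at most 1 mm deep land inside the 200-pixel window", {
  sim <- generate_pullback(small_phantom_config(8, n_frames = 3))
  pp <- preprocess_pullback(sim$pullback, depth = 200L,
                            guidewire_width_range = c(4L, 10L))
  for (f in 1:3) {
    m <- shift_mask(sim$truth$fc_mask_raw[, , f], pp$shifts[, f])
    expect_identical(sum(m[1:200, ]), sum(m))
  }
})

test_that("preprocessing commutes with circular theta shifts", {
  sim <- generate_pullback(small_phantom_config(13, n_frames = 1))
  fr <- sim$pullback$frames[, , 1]
  k <- 9L
  idx <- c((k + 1):ncol(fr), 1:k)
  pb1 <- polar_pullback(fr, preprocessed = FALSE)
  pb2 <- polar_pullback(fr[, idx], preprocessed = FALSE)
  p1 <- preprocess_pullback(pb1, depth = 48L,
                            guidewire_width_range = c(4L, 10L))
  p2 <- preprocess_pullback(pb2, depth = 48L,
                            guidewire_width_range = c(4L, 10L))
  expect_equal(p2$pullback$frames[, , 1], p1$pullback$frames[, idx, 1],
               tolerance = 1e-9)
})
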