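test_that("per-A-line thickness is the inclusive column span", {
  m <- matrix(FALSE, 60, 5)
  m[11:30, 2] <- TRUE                  # rows 10-29 (0-based): 20 pixels
  th <- aline_thickness(m, 5)
  expect_equal(th[1, 2], 100)
  expect_true(all(is.na(th[1, -2])))
  raw <- m
  attr(raw, "space") <- "raw"
  expect_error(aline_thickness(raw), "raw coordinates")
})

test_that("phantom thickness is recovered within one radial pixel", {
  errs <- c()
  for (s in 1:5) {
    sim <- generate_pullback(small_phantom_config(400 + s, n_frames = 4))
    pp <- preprocess_pullback(sim$pullback, depth = 48L,
                              guidewire_width_range = c(4L, 10L))
    pm <- preprocess_mask(sim$truth$fc_mask_raw, pp$shifts, 48L)
    th <- aline_thickness(pm, 5)
    d <- abs(th - sim$truth$thickness_truth)
    errs <- c(errs, d[!is.na(d)])
  }
  expect_lte(mean(errs), 5)
})

test_that("arc angles follow the A-line count rule", {
  full <- matrix(TRUE, 10, 448)
  part <- matrix(FALSE, 10, 448)
  part[3:6, 1:112] <- TRUE
  geom <- list(pixel_size_r = 5, frame_pitch = 0.2,
               lumen_boundary = matrix(200L, 448, 1),
               shifts = matrix(200L, 448, 1))
  s_full <- region_summary(full, aline_thickness(full, 5), geom)
  expect_equal(s_full$lesions$max_arc_deg, 360)
  s_part <- region_summary(part, aline_thickness(part, 5), geom)
  expect_equal(s_part$lesions$max_arc_deg, 90)
})

test_that("TCFA classification applies the strict 65 um rule", {
  geom <- list(pixel_size_r = 5, frame_pitch = 0.2,
               lumen_boundary = matrix(100L, 64, 1),
               shifts = matrix(100L, 64, 1))
  thin <- matrix(FALSE, 48, 64); thin[1:10, 10:30] <- TRUE   # 50 um
  thick <- matrix(FALSE, 48, 64); thick[1:16, 10:30] <- TRUE # 80 um
  expect_true(region_summary(thin, aline_thickness(thin, 5),
                             geom)$lesions$tcfa)
  expect_false(region_summary(thick, aline_thickness(thick, 5),
                              geom)$lesions$tcfa)
  # exactly 65 um (13 px) is not thin-cap under the strict inequality
  at65 <- matrix(FALSE, 48, 64); at65[1:13, 10:30] <- TRUE
  expect_false(region_summary(at65, aline_thickness(at65, 5),
                              geom)$lesions$tcfa)
})

test_that("TCFA status is monotone under cap thinning", {
  geom <- list(pixel_size_r = 5, frame_pitch = 0.2,
               lumen_boundary = matrix(100L, 64, 1),
               shifts = matrix(100L, 64, 1))
  m <- matrix(FALSE, 48, 64)
  m[1:14, 5:40] <- TRUE
  base <- region_summary(m, aline_thickness(m, 5), geom)$lesions$tcfa
  for (rows in 13:8) {
    m[rows:14, 20] <- FALSE            # progressively thin one A-line
    now <- region_summary(m, aline_thickness(m, 5), geom)$lesions$tcfa
    if (base) expect_true(now)         # thinning never unsets tcfa
    base <- base || now
  }
  expect_true(base)
})

test_that("cap area matches polar closed forms", {
  W <- 448
  zero_shift <- rep(0L, W)
  expect_equal(fc_area(matrix(FALSE, 300, W), zero_shift, 5), 0)
  # full annulus between radial indices 100 and 300 (0.5 and 1.5 mm)
  ann <- matrix(FALSE, 400, W)
  ann[101:300, ] <- TRUE
  r1 <- 100 * 5e-3; r2 <- 300 * 5e-3
  expect_equal(fc_area(ann, zero_shift, 5), pi * (r2^2 - r1^2),
               tolerance = 0.01)
  half <- ann; half[, (W / 2 + 1):W] <- FALSE
  expect_equal(fc_area(half, zero_shift, 5), pi * (r2^2 - r1^2) / 2,
               tolerance = 0.01)
  # shifted coordinates restore the same area through the shift record
  shifted <- matrix(FALSE, 300, W)
  shifted[1:200, ] <- TRUE
  expect_equal(fc_area(shifted, rep(100L, W), 5), pi * (r2^2 - r1^2),
               tolerance = 0.01)
  expect_error(fc_area(ann, NULL, 5), "shift record")
})

test_that("surface area matches the cylinder closed form", {
  # lumen radius 1.5 mm (index 300), full 360-degree cap, 10 frames at
  # 0.2 mm pitch: lateral area 2 pi r L = 18.85 mm^2
  st <- array(TRUE, c(20, 448, 10))
  lb <- matrix(300L, 448, 10)
  sa <- surface_area(st, lb, 5, 0.2)
  expect_equal(as.numeric(sa), 2 * pi * 1.5 * 2, tolerance = 0.02)
  expect_equal(as.numeric(surface_area(array(FALSE, c(20, 448, 2)),
                                       lb[, 1:2], 5, 0.2)), 0)
  # single frame with arc length L contributes 0.2 * L
  one <- array(FALSE, c(20, 448, 1))
  one[5, 1:112, 1] <- TRUE
  L <- 112 / 448 * 2 * pi * 1.5
  expect_equal(as.numeric(surface_area(one, lb[, 1, drop = FALSE], 5, 0.2)),
               0.2 * L, tolerance = 0.01)
})

test_that("lesions are linked across frames and across the theta seam", {
  st <- array(FALSE, c(30, 64, 3))
  st[5:9, c(60:64, 1:5), 1] <- TRUE    # straddles the seam
  st[5:9, c(62:64, 1:8), 2] <- TRUE    # overlaps frame 1 angularly
  st[5:9, 30:40, 3] <- TRUE            # separate lesion
  geom <- list(pixel_size_r = 5, frame_pitch = 0.2,
               lumen_boundary = matrix(100L, 64, 3),
               shifts = matrix(100L, 64, 3))
  s <- region_summary(st, aline_thickness(st, 5), geom)
  expect_equal(nrow(s$lesions), 2)
  spanning <- s$lesions[s$lesions$frame_start == 1, ]
  expect_equal(spanning$frame_end, 2)
  expect_equal(spanning$length_mm, 0.4)
  # the seam lesion is one region of 10-11 A-lines, not two split halves
  expect_equal(s$per_frame$n_alines[s$per_frame$frame == 1], 10)
})

test_that("thickness heatmaps export to PLY and read back exactly", {
  st <- array(FALSE, c(30, 32, 4))
  st[1:20, 5:20, ] <- TRUE             # uniform 100 um cap
  hm <- thickness_heatmap(st, 5)
  expect_equal(dim(hm), c(4L, 32L))
  expect_true(all(hm[, 5:20] == 100))
  path <- tempfile(fileext = ".ply")
  write_thickness_ply(hm, path, lumen_radius_mm = 1.5, frame_pitch = 0.2)
  mesh <- read_thickness_ply(path)
  expect_equal(nrow(mesh), 4 * 32)
  back <- matrix(mesh$thickness, 4, 32, byrow = TRUE)
  expect_equal(back, ifelse(is.na(hm), 0, hm))
})

test_that("Bland-Altman statistics match their definitions", {
  expect_equal(bland_altman(1:10, 1:10)$bias, 0)
  expect_equal(bland_altman(1:10, 1:10)$sd, 0)
  ba5 <- bland_altman(1:10 + 5, 1:10)
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$sd, 0)
  expect_error(bland_altman(1, 2), "pairs")
  # Monte-Carlo oracle: differences ~ N(3, 20^2)
  set.seed(8)
  n <- 1e4
  y <- runif(n, 50, 200)
  x <- y + rnorm(n, 3, 20)
  ba <- bland_altman(x, y)
  expect_lt(abs(ba$bias - 3), 3 * 20 / sqrt(n))
  expect_equal(ba$sd, 20, tolerance = 0.05)
  expect_equal(ba$fraction_within, 0.95, tolerance = 0.02)
})

test_that("coefficient of variation uses the population convention", {
  expect_equal(coefficient_of_variation(c(90, 110)), 0.1)
  expect_equal(coefficient_of_variation(rep(7, 5)), 0)
  x <- c(3, 9, 14, 2)
  expect_equal(coefficient_of_variation(x * 17),
               coefficient_of_variation(x))
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))
  m <- cbind(a = c(90, 110), b = c(10, 10))
  expect_equal(unname(coefficient_of_variation(m)), c(0.1, 0))
})
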