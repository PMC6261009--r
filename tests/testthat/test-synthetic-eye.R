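test_that("meridian sag integrates the prescribed curvature profile exactly", {
  tr <- surface_truth(limbus_radius_mm = 6.8, dip_amplitude = 0.3,
                      dip_sigma_mm = 0.35)
  r <- seq(0, 9, by = 0.001)
  prof <- make_meridian_sag(tr, 0, r)
  ## boundary conditions by construction
  expect_equal(prof$s[1], 0)
  expect_equal(prof$d1[1], 0)
  ## closed-form s/d1/d2 are mutually consistent: numeric derivatives agree
  d1_num <- diff(prof$s) / 0.001
  expect_lt(max(abs(d1_num - (prof$d1[-1] + prof$d1[-length(r)]) / 2)), 1e-6)
  d2_num <- diff(prof$s, differences = 2) / 0.001^2
  expect_lt(max(abs(d2_num - prof$d2[-c(1, length(r))])), 1e-4)
  ## interior local minimum of d2 sits exactly on the limbus ring radius
  sel <- r >= 4.5 & r <= 8.5
  expect_equal(r[sel][which.min(prof$d2[sel])], 6.8, tolerance = 1e-9)
  ## inside the cornea the curvature is 1/R_c, far outside it approaches 1/R_s
  expect_equal(prof$d2[r == 2], 1 / 7.8, tolerance = 1e-9)
  expect_equal(prof$d2[r == 9], 1 / 12, tolerance = 1e-6)
})

test_that("qualitative slope narrative holds: rise, dip at the limbus, rise again", {
  tr <- surface_truth()
  r <- seq(0, 9, by = 0.01)
  prof <- make_meridian_sag(tr, 0, r)
  pre <- r > 0.1 & r < 5.5
  expect_true(all(diff(prof$d1[pre]) > 0))            # rising toward the limbus
  at <- r > 6.5 & r < 7.1
  expect_true(any(diff(prof$d1[at]) < 0))             # decreases through the limbus
  post <- r > 8.3
  expect_true(all(diff(prof$d1[post]) > 0))           # rises again on the sclera
})

test_that("degenerate generator parameters are rejected analytically", {
  expect_error(surface_truth(dip_amplitude = 0), class = "limbus3d_bad_parameters")
  expect_error(surface_truth(dip_sigma_mm = -1), class = "limbus3d_bad_parameters")
  expect_error(surface_truth(limbus_radius_mm = 3), class = "limbus3d_bad_parameters")
  expect_error(surface_truth(scleral_R_mm = 7), class = "limbus3d_bad_parameters")
  expect_error(image_truth(intensities = c(110, 20, 220)),
               class = "limbus3d_bad_parameters")
  expect_error(image_truth(pupil_radius_px = 400),
               class = "limbus3d_bad_parameters")
})

test_that("surface generation is deterministic and honours its truth record", {
  tr <- surface_truth(tilt_x_deg = -0.3, tilt_y_deg = 1.76)
  a <- make_surface(tr, spacing = 0.2, noise_sd_mm = 0.005, seed = 7)
  b <- make_surface(tr, spacing = 0.2, noise_sd_mm = 0.005, seed = 7)
  expect_identical(a$field$points, b$field$points)
  ## plane fit on the analytic truth ring recovers the prescribed tilt exactly
  pl <- fit_contour_plane(a$truth$contour)
  expect_equal(pl$theta_x, -0.3, tolerance = 1e-6)
  expect_equal(pl$theta_y, 1.76, tolerance = 1e-6)
  expect_lt(pl$rms_residual, 1e-9)
  ## untilted symmetric surface: heights equal the closed-form radial sag
  s0 <- make_surface(surface_truth(), spacing = 0.2, seed = 8)
  p <- s0$field$points
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  expect_lt(max(abs(p[, 3] + make_meridian_sag(surface_truth(), 0, r)$s)), 1e-9)
})

test_that("occlusion sectors remove exactly the requested points", {
  tr <- surface_truth()
  occ <- list(lo = 60, hi = 120, r_from = 4)
  full <- make_surface(tr, spacing = 0.2, seed = 9)
  cut <- make_surface(tr, spacing = 0.2, seed = 9, occlusion = occ)
  p <- full$field$points
  ang <- (atan2(p[, 2], p[, 1]) * 180 / pi) %% 360
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  inside <- ang >= 60 & ang <= 120 & r >= 4
  expect_identical(nrow(cut$field$points), sum(!inside))
})

test_that("synthetic eye images match their analytic white-to-white truth", {
  it <- image_truth(noise_sd = 0, seed = 1)
  im <- make_eye_image(it)
  ## noiseless image has exactly three intensity values
  expect_identical(sort(unique(as.vector(im$image$pixels))),
                   as.integer(unname(it$intensities)))
  ## with highlights, four
  it4 <- image_truth(noise_sd = 0, highlights = TRUE, seed = 1)
  expect_identical(length(unique(as.vector(make_eye_image(it4)$image$pixels))), 4L)
  ## analytic truth: ellipse polar radius at the cardinal angles
  expect_equal(im$truth$wtw_radius_mm[1], 295 * 0.02)
  expect_equal(im$truth$wtw_radius_mm[91], 287.5 * 0.02)
  ## determinism
  n1 <- make_eye_image(image_truth(noise_sd = 8, seed = 5))
  n2 <- make_eye_image(image_truth(noise_sd = 8, seed = 5))
  expect_identical(n1$image$pixels, n2$image$pixels)
})

test_that("three-population images put the right histogram mass at each mode", {
  ## labelled mixture built directly: 15% pupil, 35% iris, 50% sclera
  set.seed(42)
  n <- 100 * 100
  labels <- rep(1:3, times = c(0.15, 0.35, 0.50) * n)
  means <- c(20, 110, 220)[labels]
  sds <- c(5, 8, 10)[labels]
  px <- matrix(pmin(pmax(round(rnorm(n, means, sds)), 0), 255), 100, 100)
  sp <- intensity_spectrum(eye_image(px, 0.02, 0.02))
  expect_identical(sum(sp$counts), as.integer(n))
  ## mass near each mode (split at the midpoints between populations)
  cuts <- c(-1, 65, 165, 255)
  mass <- vapply(1:3, function(k) {
    sum(sp$counts[(cuts[k] + 2):(cuts[k + 1] + 1)]) / n
  }, numeric(1))
  expect_equal(mass, c(0.15, 0.35, 0.50), tolerance = 0.02)
  pk <- locate_colour_peaks(sp)
  expect_lte(abs(pk$pupil_I - 20), 3)
  expect_lte(abs(pk$iris_I - 110), 3)
  expect_lte(abs(pk$sclera_I - 220), 3)
})
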