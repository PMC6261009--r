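test_that("polar resampling reproduces closed-form sag on symmetric surfaces", {
  field <- make_analytic_surface("sphere", R_mm = 7.8, r_max = 7.5)
  ms <- polar_resample(field, n_meridians = 36, dr = 0.01, r_max = 7.2)
  ## closed-form spot check: sphere sag at r = 6.8
  k <- which(abs(ms$r_grid - 6.8) < 1e-9)
  expect_equal(unname(ms$sag[1, k]), sphere_sag(6.8, 7.8), tolerance = 1e-3)
  ## rotational symmetry: every meridian sees the same profile
  spread <- apply(ms$sag[, ms$r_grid > 0.5 & ms$r_grid < 7], 2,
                  function(x) diff(range(x)))
  expect_lt(max(spread), 1e-3)
  expect_true(all(ms$valid))
  ## sag convention: zero at the apex, increasing outward
  expect_equal(unname(ms$sag[1, 1]), 0, tolerance = 1e-9)
})

test_that("occluded sectors surface as invalid samples, and sparse coverage errors", {
  tr <- surface_truth()
  occ <- make_surface(tr, occlusion = list(lo = 60, hi = 120, r_from = 4),
                      seed = 1)
  ms <- polar_resample(occ$field, n_meridians = 72, dr = 0.05)
  mid_sector <- ms$angles > 65 & ms$angles < 115
  far <- ms$r_grid > 4.5
  expect_true(all(!ms$valid[mid_sector, far]))
  outside <- ms$angles < 55 | ms$angles > 125
  expect_true(all(ms$valid[outside, ]))
  ## a field covering too little of the polar grid errors
  tiny <- height_field(cbind(runif(100, -1, 1), runif(100, -1, 1), 0))
  expect_error(polar_resample(tiny, n_meridians = 36, r_max = 8.5),
               class = "limbus3d_insufficient_coverage")
})

test_that("Savitzky-Golay derivatives match closed forms", {
  r <- seq(0, 8, by = 0.01)
  ## paraboloid: d1 = r/R, d2 = 1/R, exact for a cubic local fit
  prof <- meridian_derivatives(r^2 / (2 * 7.8), r, smooth_halfwidth = 0.25)
  interior <- r > 0.3 & r < 7.7
  expect_lt(max(abs(prof$d1[interior] - r[interior] / 7.8)), 1e-6)
  expect_lt(max(abs(prof$d2[interior] - 1 / 7.8)), 1e-6)
  ## sphere: d2 = R^2 / (R^2 - r^2)^(3/2)
  sprof <- meridian_derivatives(sphere_sag(r[r < 7], 7.8), r[r < 7],
                                smooth_halfwidth = 0.25)
  k <- which(abs(r - 4) < 1e-9)
  expect_equal(sprof$d2[k], 7.8^2 / (7.8^2 - 16)^1.5, tolerance = 1e-3)
  ## constant sag: both derivatives vanish
  cprof <- meridian_derivatives(rep(2, length(r)), r)
  expect_lt(max(abs(cprof$d1), na.rm = TRUE), 1e-12)
  expect_lt(max(abs(cprof$d2), na.rm = TRUE), 1e-12)
  ## gaps propagate; a window wider than every valid run is an error
  s <- r^2 / 2
  v <- rep(TRUE, length(r)); v[300:500] <- FALSE
  gprof <- meridian_derivatives(s, r, valid = v, smooth_halfwidth = 0.25)
  expect_true(all(!gprof$valid[300:500]))
  expect_error(meridian_derivatives(s[1:30], r[1:30], smooth_halfwidth = 0.25),
               class = "limbus3d_window_too_wide")
})

test_that("turning-point location agrees with the brute-force analytic oracle", {
  for (rl in c(5.9, 6.4, 6.8, 7.0)) {
    tr <- surface_truth(limbus_radius_mm = rl)
    r <- seq(0, 8.5, by = 0.01)
    prof <- meridian_derivatives(make_meridian_sag(tr, 0, r)$s, r)
    res <- locate_limbus_point(prof)
    expect_true(res$valid)
    oracle <- brute_force_limbus(tr, 0)
    expect_lt(abs(res$radius - oracle), 0.01)
    expect_lt(abs(res$radius - rl), 0.01)
  }
  ## strictly monotone d2 (a sphere) has no turning point in the window
  r <- seq(0, 7.5, by = 0.01)
  sp <- meridian_derivatives(sphere_sag(r, 7.8), r)
  out <- locate_limbus_point(sp, window = c(4.5, 7.2))
  expect_false(out$valid)
  expect_true(is.na(out$radius))
})

test_that("contour assembly flags invalid meridians and guards the valid fraction", {
  tr <- surface_truth()
  r <- seq(0, 8.5, by = 0.01)
  prof <- meridian_derivatives(make_meridian_sag(tr, 0, r)$s, r)
  good <- locate_limbus_point(prof)
  bad <- list(radius = NA_real_, quality = NA_real_, sag = NA_real_, valid = FALSE)
  ms <- structure(list(angles = (0:35) * 10, r_grid = r, dr = 0.01,
                       sag = matrix(0, 36, length(r)),
                       valid = matrix(TRUE, 36, length(r))),
                  class = "meridian_set")
  results <- rep(list(good), 36)
  results[7:12] <- rep(list(bad), 6)
  ct <- assemble_limbus_contour(ms, results)
  expect_identical(sum(!ct$valid), 6L)
  expect_true(all(is.na(ct$points[7:12, ])))
  ## valid points satisfy the polar relation
  th <- ms$angles[1] * pi / 180
  expect_equal(unname(ct$points[1, 1]), good$radius * cos(th))
  ## too many invalid meridians abort assembly
  results[1:24] <- rep(list(bad), 24)
  expect_error(assemble_limbus_contour(ms, results),
               class = "limbus3d_too_few_valid_meridians")
})

test_that("axis diameters are rigid-motion invariant chords", {
  ct <- ring_contour(6.82)
  d <- axis_diameters(ct)
  expect_equal(d$NT, 13.64)
  expect_equal(d$SI, 13.64)
  ## a rigid 2-degree rotation about Y preserves both chords
  a <- 2 * pi / 180
  R <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rot <- limbus_contour(ct$angle_deg, ct$points %*% t(R), ct$valid)
  dr <- axis_diameters(rot)
  expect_equal(dr$NT, 13.64, tolerance = 1e-9)
  expect_equal(dr$SI, 13.64, tolerance = 1e-9)
  ## invalid cardinal meridian is an error
  ct$valid[181] <- FALSE
  expect_error(axis_diameters(ct), class = "limbus3d_axis_meridian_invalid")
})

test_that("detection is equivariant under rotation of the input surface", {
  tr <- surface_truth(limbus_radius_mm = 6.8)
  sim <- make_surface(tr, seed = 21)
  base <- detect_limbus(sim$field, n_meridians = 72)$contour
  ## rotate the surface by 30 degrees about Z
  a <- 30 * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rot_field <- height_field(sim$field$points %*% t(Rz))
  rot <- detect_limbus(rot_field, n_meridians = 72)$contour
  r_base <- sqrt(base$points[, 1]^2 + base$points[, 2]^2)
  r_rot <- sqrt(rot$points[, 1]^2 + rot$points[, 2]^2)
  ## the symmetric ring: radii at meridian m of the rotated surface equal
  ## radii at meridian m - 30 degrees of the original
  shift <- 30 / (360 / 72)
  expect_lt(max(abs(r_rot - r_base[((seq_len(72) - 1 - shift) %% 72) + 1])), 0.01)
})
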