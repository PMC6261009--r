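test_that("plane fits recover constructed tilts and reject degenerate contours", {
  th <- (0:359) * pi / 180
  ## plane z = tan(1.76 deg) * x
  a <- tan(1.76 * pi / 180)
  ct <- limbus_contour(0:359, cbind(6.8 * cos(th), 6.8 * sin(th),
                                    a * 6.8 * cos(th)), rep(TRUE, 360))
  pl <- fit_contour_plane(ct)
  expect_equal(pl$theta_y, 1.76, tolerance = 1e-6)
  expect_equal(pl$theta_x, 0, tolerance = 1e-9)
  expect_lt(pl$rms_residual, 1e-12)
  ## flat contour
  flat <- ring_contour(6.8, z = -3)
  pf <- fit_contour_plane(flat)
  expect_equal(pf$theta_x, 0)
  expect_equal(pf$theta_y, 0)
  ## sinusoidal z = 0.1 sin(theta): slope b = 0.1/6.8 by normal equations
  sin_ct <- limbus_contour(0:359, cbind(6.8 * cos(th), 6.8 * sin(th),
                                        0.1 * sin(th)), rep(TRUE, 360))
  ps <- fit_contour_plane(sin_ct)
  expect_equal(ps$b, 0.1 / 6.8, tolerance = 1e-6)
  expect_equal(ps$theta_x, atan(0.1 / 6.8) * 180 / pi, tolerance = 1e-3)
  ## collinear points are degenerate
  line <- limbus_contour(0:9, cbind(0:9, 0:9, rep(0, 10)), rep(TRUE, 10))
  expect_error(fit_contour_plane(line), class = "limbus3d_degenerate_contour")
  few <- limbus_contour(0:9, cbind(cos(1:10), sin(1:10), 0),
                        valid = c(TRUE, TRUE, rep(FALSE, 8)))
  expect_error(fit_contour_plane(few), class = "limbus3d_degenerate_contour")
})

test_that("leveling zeroes the tilt, preserves residuals and is idempotent", {
  th <- (0:359) * pi / 180
  a <- tan(2.5 * pi / 180); b <- tan(-1.2 * pi / 180)
  planar <- limbus_contour(0:359,
                           cbind(6.8 * cos(th), 6.8 * sin(th),
                                 a * 6.8 * cos(th) + b * 6.8 * sin(th) - 3),
                           rep(TRUE, 360))
  lv <- level_contour(planar)
  expect_lt(diff(range(lv$points[, 3])), 1e-9)
  lv2 <- level_contour(lv)
  expect_lt(max(abs(lv2$points - lv$points)), 1e-9)
  ## non-planar: tilt removed and rms preserved up to the (tiny) difference
  ## between vertical and plane-orthogonal residuals at slopes of a few
  ## degrees -- the fit minimizes vertical distances, which a rigid rotation
  ## re-weights by cos(tilt)
  wavy <- limbus_contour(0:359,
                         cbind(6.8 * cos(th), 6.8 * sin(th),
                               a * 6.8 * cos(th) + 0.05 * sin(3 * th)),
                         rep(TRUE, 360))
  pl0 <- fit_contour_plane(wavy)
  plv <- fit_contour_plane(level_contour(wavy))
  expect_equal(plv$theta_x, 0, tolerance = 1e-3)
  expect_equal(plv$theta_y, 0, tolerance = 1e-3)
  expect_equal(plv$rms_residual, pl0$rms_residual, tolerance = 2e-3)
})

test_that("sagittal depths resolve clinical orientations per laterality", {
  ## all-constant depth
  flat <- ring_contour(6.8, z = -3, laterality = "right")
  d <- sagittal_depths(flat)
  expect_equal(unname(unlist(d)), rep(3, 4))
  ## 2-degree tilt about Y: temporal-nasal difference is the chord formula
  th <- (0:359) * pi / 180
  a <- tan(2 * pi / 180)
  tl <- limbus_contour(0:359, cbind(6.8 * cos(th), 6.8 * sin(th),
                                    a * 6.8 * cos(th) - 3),
                       rep(TRUE, 360), laterality = "right")
  dt <- sagittal_depths(tl)
  expect_equal(abs(dt$temporal - dt$nasal), 2 * 6.8 * tan(2 * pi / 180),
               tolerance = 1e-3)
  expect_equal(dt$superior, dt$inferior)
  ## right vs left: nasal and temporal swap
  dl <- sagittal_depths(tl, laterality = "left")
  expect_equal(dl$nasal, dt$temporal)
  expect_equal(dl$temporal, dt$nasal)
  ## invalid cardinal meridian errors
  tl$valid[91] <- FALSE
  expect_error(sagittal_depths(tl), class = "limbus3d_axis_meridian_invalid")
})

test_that("mirroring a right eye to a left eye flips theta_y and keeps theta_x", {
  tr <- surface_truth(tilt_x_deg = -0.3, tilt_y_deg = 1.76)
  sim <- make_surface(tr, spacing = 0.2, seed = 3)
  ct <- sim$truth$contour
  mirrored <- limbus_contour(ct$angle_deg,
                             cbind(-ct$points[, 1], ct$points[, 2:3]),
                             ct$valid)
  pr <- fit_contour_plane(ct)
  pm <- fit_contour_plane(mirrored)
  expect_equal(pm$theta_y, -pr$theta_y, tolerance = 1e-9)
  expect_equal(pm$theta_x, pr$theta_x, tolerance = 1e-9)
})

test_that("radial difference maps recover offsets, extremes and validity spans", {
  lim <- ring_contour(6.8)
  w <- wtw_contour(c(0, 0), rep(5.9, 360))
  dm <- radial_difference_map(lim, w)
  expect_true(all(abs(dm$delta_mm - 0.9) < 1e-9))
  expect_equal(dm$mean_mm, 0.9, tolerance = 1e-9)
  ## sinusoidal limbus radius: delta = 0.9 + 0.3 cos(theta)
  th <- (0:359) * pi / 180
  r <- 6.8 + 0.3 * cos(th)
  sin_lim <- limbus_contour(0:359, cbind(r * cos(th), r * sin(th), 0),
                            rep(TRUE, 360))
  dms <- radial_difference_map(sin_lim, w)
  expect_identical(dms$argmax_deg, 0L)
  expect_identical(dms$argmin_deg, 180L)
  ## limbus valid only on the upper half: delta valid exactly there
  half <- sin_lim
  half$valid[182:360] <- FALSE
  dmh <- radial_difference_map(half, w)
  expect_identical(which(dmh$valid) - 1L, 0:180)
  expect_lte(dmh$argmax_deg, 180L)
  ## both contours rotated together leave the map unchanged
  rot <- limbus_contour(0:359, cbind(r * cos(th + pi / 2), r * sin(th + pi / 2), 0),
                        rep(TRUE, 360))
  dmr <- radial_difference_map(rot, w)
  expect_equal(max(abs(sort(dmr$delta_mm) - sort(dms$delta_mm))), 0,
               tolerance = 1e-9)
  ## no overlap errors
  none <- sin_lim
  none$valid[] <- FALSE
  expect_error(radial_difference_map(none, w), class = "limbus3d_no_overlap")
})
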