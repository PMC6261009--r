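## Synthetic anterior-eye generators with exact analytic ground truth.
##
## The surface model encodes the defining property of the limbus used by the
## detector: the cornea and sclera have different curvatures and the
## transition ring carries a local dip in the second radial derivative of
## sagittal height.  The radial curvature profile is
##
##   d2(r) = k_c + (k_s - k_c) * S(r)  -  A * exp(-(r - r_L)^2 / (2 sigma^2))
##
## where k_c = 1/corneal_R and k_s = 1/scleral_R (k_s < k_c), S is a cubic
## smoothstep that begins only at r_L + 3*sigma, and the Gaussian dip is
## centred on the limbus ring radius r_L.  Because S is exactly flat over the
## dip's support, d2 has its interior local minimum exactly at r_L, so the
## generator's truth is analytic, never the output of the detector.  Sag is
## obtained in closed form by integrating d2 twice with s(0) = 0, s'(0) = 0.

#' Ground-truth description of a synthetic anterior-eye surface
#'
#' @param limbus_radius_mm limbus ring radius, a scalar or a length-360
#'   per-degree vector, each value in \[4.5, 8.5\] mm.
#' @param tilt_x_deg,tilt_y_deg tilt of the limbus plane in degrees.  The
#'   surface is rotated rigidly so that a least-squares plane through the
#'   truth ring has slopes `tan(tilt_y)` in x and `tan(tilt_x)` in y.
#' @param dip_amplitude amplitude A of the Gaussian curvature dip (1/mm);
#'   must be positive, otherwise no interior second-derivative minimum
#'   exists and the limbus is undefined.
#' @param dip_sigma_mm width sigma of the dip (mm).
#' @param corneal_R_mm,scleral_R_mm corneal and scleral radii of curvature
#'   (mm); the scleral radius must be the larger (flatter sclera).
#' @param transition_width_mm width of the corneal-to-scleral curvature
#'   smoothstep that starts at `limbus_radius + 3*dip_sigma`.
#' @param seed integer seed recorded in the truth and used by
#'   [make_surface()] unless overridden.
#' @return an object of class `surface_truth`.
#' @export
surface_truth <- function(limbus_radius_mm = 6.8,
                          tilt_x_deg = 0, tilt_y_deg = 0,
                          dip_amplitude = 0.3, dip_sigma_mm = 0.35,
                          corneal_R_mm = 7.8, scleral_R_mm = 12,
                          transition_width_mm = 1.0,
                          seed = NULL) {
  l3d_assert(length(limbus_radius_mm) %in% c(1L, 360L) &&
               is_finite_num(limbus_radius_mm),
             "bad_parameters", "limbus_radius_mm must be scalar or length 360")
  l3d_assert(all(limbus_radius_mm >= 4.5 & limbus_radius_mm <= 8.5),
             "bad_parameters", "limbus_radius_mm must lie in [4.5, 8.5] mm")
  l3d_assert(is_finite_num(dip_sigma_mm) && dip_sigma_mm > 0,
             "bad_parameters", "dip_sigma_mm must be > 0")
  l3d_assert(is_finite_num(dip_amplitude) && dip_amplitude > 0,
             "bad_parameters",
             "dip_amplitude must be > 0: without a dip the second derivative is monotone and has no interior minimum")
  l3d_assert(scleral_R_mm > corneal_R_mm, "bad_parameters",
             "scleral_R_mm must exceed corneal_R_mm (flatter sclera)")
  structure(list(limbus_radius_mm = limbus_radius_mm,
                 tilt_x_deg = tilt_x_deg, tilt_y_deg = tilt_y_deg,
                 dip_amplitude = dip_amplitude, dip_sigma_mm = dip_sigma_mm,
                 corneal_R_mm = corneal_R_mm, scleral_R_mm = scleral_R_mm,
                 transition_width_mm = transition_width_mm,
                 seed = seed),
            class = "surface_truth")
}

## limbus radius at arbitrary angles (deg) from scalar or per-degree truth
truth_limbus_radius <- function(truth, angle_deg) {
  rl <- truth$limbus_radius_mm
  if (length(rl) == 1L) return(rep(rl, length(angle_deg)))
  a <- wrap360(angle_deg)
  i0 <- floor(a) %% 360
  t <- a - floor(a)
  (1 - t) * rl[i0 + 1L] + t * rl[(i0 + 1L) %% 360 + 1L]
}

## cubic smoothstep and its first/second antiderivatives, all zero below a;
## r and a recycle against each other (per-point dip centres)
smoothstep_int <- function(r, a, b) {
  n <- max(length(r), length(a), length(b))
  r <- rep_len(r, n); a <- rep_len(a, n); b <- rep_len(b, n)
  w <- b - a
  u <- pmin(pmax((r - a) / w, 0), 1)
  S <- 3 * u^2 - 2 * u^3
  I1 <- w * (u^3 - u^4 / 2)              # int_a^r S
  I2 <- w^2 * (u^4 / 4 - u^5 / 10)       # int_a^r int_a^v S
  beyond <- r > b
  if (any(beyond)) {
    rb <- r[beyond] - b[beyond]
    wb <- w[beyond]
    I1[beyond] <- wb / 2 + rb
    I2[beyond] <- wb^2 * 0.15 + (wb / 2) * rb + rb^2 / 2
  }
  list(S = S, I1 = I1, I2 = I2)
}

## closed-form curvature profile, slope and sag of one meridian; r and m
## (dip centre) recycle against each other
dip_profile <- function(r, m, truth) {
  kc <- 1 / truth$corneal_R_mm
  ks <- 1 / truth$scleral_R_mm
  A <- truth$dip_amplitude
  sg <- truth$dip_sigma_mm
  a <- m + 3 * sg
  b <- a + truth$transition_width_mm
  ss <- smoothstep_int(r, a, b)
  dk <- ks - kc
  ## Gaussian term: G1 = int_0^r A e^{-(u-m)^2/2s^2}, G2 = int_0^r G1
  s2 <- sg * sqrt(2)
  G1 <- A * sg * sqrt(pi / 2) * (pracma::erf((r - m) / s2) + pracma::erf(m / s2))
  G2 <- (r - m) * G1 + A * sg^2 * (exp(-(r - m)^2 / (2 * sg^2)) - exp(-m^2 / (2 * sg^2)))
  list(d2 = kc + dk * ss$S - A * exp(-(r - m)^2 / (2 * sg^2)),
       d1 = kc * r + dk * ss$I1 - G1,
       s  = kc * r^2 / 2 + dk * ss$I2 - G2)
}

#' Analytic sagittal-height profile of one synthetic meridian
#'
#' Returns the closed-form sag s(r) (and its first two radial derivatives)
#' of the curvature-dip surface along one meridian, with s(0) = 0 and
#' ds/dr(0) = 0 by construction.
#'
#' @param truth a [surface_truth()].
#' @param angle_deg meridian angle in degrees.
#' @param r radial positions (mm), from 0.
#' @return a list with components `r`, `s`, `d1`, `d2`.
#' @export
make_meridian_sag <- function(truth, angle_deg, r) {
  stopifnot(inherits(truth, "surface_truth"))
  l3d_assert(all(r >= 0), "bad_parameters", "r must be non-negative")
  m <- truth_limbus_radius(truth, angle_deg)
  p <- dip_profile(r, m, truth)
  list(r = r, s = p$s, d1 = p$d1, d2 = p$d2)
}

## rotation used to impose the prescribed plane tilt: minimal rotation taking
## +Z to the normal of the plane z = tan(ty)*x + tan(tx)*y
tilt_rotation <- function(tilt_x_deg, tilt_y_deg) {
  a <- tan(deg2rad(tilt_y_deg))
  b <- tan(deg2rad(tilt_x_deg))
  u <- c(-a, -b, 1)
  rotation_between(c(0, 0, 1), u)
}

#' Generate a synthetic anterior-eye height field with known limbus
#'
#' Samples the curvature-dip surface on an XY layout, applies the rigid
#' tilt rotation, re-centres on the post-tilt apex, and optionally adds
#' Gaussian height noise and removes eyelid-occluded sectors.  The analytic
#' truth (limbus ring points after the same rigid motion) is returned
#' alongside the field and is never derived from the detector.
#'
#' @param truth a [surface_truth()].
#' @param spacing grid spacing in mm (grid layout), emulating typical
#'   profilometer point density.
#' @param layout `"grid"` for a regular XY lattice or `"scattered"` for
#'   uniform random points.
#' @param n_points number of points for the scattered layout.
#' @param noise_sd_mm standard deviation of additive Gaussian height noise
#'   (mm); 0.005 corresponds to 5 micrometres.
#' @param occlusion `NULL`, or a list (or list of lists) with elements
#'   `lo`, `hi` (sector bounds in degrees) and `r_from` (mm): points with
#'   meridian angle inside \[lo, hi\] and radius >= r_from are removed,
#'   emulating eyelid cover.
#' @param r_max maximal sampled radius (mm).
#' @param seed integer seed; defaults to `truth$seed`.
#' @return a list with `field` (a [height_field()]) and `truth` (the input
#'   truth extended with the rigidly-moved limbus ring `contour`, the plane
#'   slopes `plane`, and the apex shift applied).
#' @export
make_surface <- function(truth, spacing = 0.05, layout = c("grid", "scattered"),
                         n_points = NULL, noise_sd_mm = 0, occlusion = NULL,
                         r_max = 9, seed = truth$seed) {
  stopifnot(inherits(truth, "surface_truth"))
  layout <- match.arg(layout)
  if (!is.null(seed)) set.seed(seed)
  if (layout == "grid") {
    g <- seq(-r_max, r_max, by = spacing)
    xy <- expand.grid(x = g, y = g)
    x <- xy$x; y <- xy$y
  } else {
    if (is.null(n_points)) n_points <- round(pi * (r_max / spacing)^2)
    rr <- r_max * sqrt(runif(n_points))
    aa <- runif(n_points, 0, 2 * pi)
    x <- rr * cos(aa); y <- rr * sin(aa)
  }
  r <- sqrt(x^2 + y^2)
  keep <- r <= r_max
  x <- x[keep]; y <- y[keep]; r <- r[keep]
  ang <- wrap360(rad2deg(atan2(y, x)))
  m <- truth_limbus_radius(truth, ang)
  z <- -dip_profile(r, m, truth)$s
  pts <- cbind(x, y, z)

  R <- tilt_rotation(truth$tilt_x_deg, truth$tilt_y_deg)
  tilted <- abs(truth$tilt_x_deg) > 0 || abs(truth$tilt_y_deg) > 0
  if (tilted) pts <- pts %*% t(R)

  ## analytic truth ring, same rigid motion
  th <- 0:359
  rl <- truth_limbus_radius(truth, th)
  ring <- cbind(rl * cos(deg2rad(th)), rl * sin(deg2rad(th)),
                -dip_profile(rl, rl, truth)$s)
  if (tilted) ring <- ring %*% t(R)

  ## re-centre on the post-tilt apex so z <= 0 with z = 0 at the origin
  apex <- c(0, 0, 0)
  if (tilted) {
    zfun <- function(p) {
      rr <- sqrt(sum(p^2))
      mm <- truth_limbus_radius(truth, wrap360(rad2deg(atan2(p[2], p[1]))))
      -(R %*% c(p, -dip_profile(rr, mm, truth)$s))[3]
    }
    opt <- optim(c(0, 0), zfun, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 500))
    p0 <- opt$par
    rr <- sqrt(sum(p0^2))
    mm <- truth_limbus_radius(truth, wrap360(rad2deg(atan2(p0[2], p0[1]))))
    apex <- as.numeric(R %*% c(p0, -dip_profile(rr, mm, truth)$s))
    pts <- sweep(pts, 2, apex)
    ring <- sweep(ring, 2, apex)
  }

  if (noise_sd_mm > 0) pts[, 3] <- pts[, 3] + rnorm(nrow(pts), 0, noise_sd_mm)

  if (!is.null(occlusion)) {
    if (!is.null(occlusion$lo)) occlusion <- list(occlusion)
    drop <- rep(FALSE, nrow(pts))
    pr <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    pa <- wrap360(rad2deg(atan2(pts[, 2], pts[, 1])))
    for (oc in occlusion) {
      drop <- drop | (pa >= oc$lo & pa <= oc$hi & pr >= oc$r_from)
    }
    pts <- pts[!drop, , drop = FALSE]
  }

  field <- height_field(pts, grid_flag = layout == "grid" && !tilted)
  truth$contour <- limbus_contour(angle_deg = th, points = ring,
                                  valid = rep(TRUE, 360),
                                  quality = rep(NA_real_, 360))
  truth$plane <- c(a = tan(deg2rad(truth$tilt_y_deg)),
                   b = tan(deg2rad(truth$tilt_x_deg)))
  truth$apex_shift <- apex
  list(field = field, truth = truth)
}

#' Closed-form spherical or paraboloidal test surfaces
#'
#' Convenience height fields whose sag is known exactly: a spherical cap
#' s(r) = R - sqrt(R^2 - r^2) or a paraboloid s(r) = r^2 / (2R).
#'
#' @param profile `"sphere"` or `"paraboloid"`.
#' @param R_mm radius of curvature (mm).
#' @param spacing grid spacing (mm).
#' @param r_max maximal radius (mm); for a sphere must be < `R_mm`.
#' @return a [height_field()].
#' @export
make_analytic_surface <- function(profile = c("sphere", "paraboloid"),
                                  R_mm = 7.8, spacing = 0.05, r_max = 7.5) {
  profile <- match.arg(profile)
  if (profile == "sphere") l3d_assert(r_max < R_mm, "bad_parameters",
                                      "sphere: r_max must be < R_mm")
  g <- seq(-r_max, r_max, by = spacing)
  xy <- expand.grid(x = g, y = g)
  r2 <- xy$x^2 + xy$y^2
  keep <- r2 <= r_max^2
  r2 <- r2[keep]
  s <- if (profile == "sphere") R_mm - sqrt(R_mm^2 - r2) else r2 / (2 * R_mm)
  height_field(cbind(xy$x[keep], xy$y[keep], -s), grid_flag = TRUE)
}

#' Ground-truth description of a synthetic eye image
#'
#' Three intensity populations (pupil < iris < sclera) as seen by a
#' profilometer camera: a dark pupil disc inside a darker-than-sclera iris
#' ellipse on a bright scleral background, with optional specular highlight
#' dots from the device's two vertically-aligned illumination spots.
#'
#' @param iris_semi_axes_px horizontal and vertical iris semi-axes (px).
#' @param pupil_radius_px pupil radius (px), smaller than both semi-axes.
#' @param intensities the three population means `(pupil, iris, sclera)`,
#'   strictly increasing, in 0..255.
#' @param noise_sd Gaussian pixel-noise standard deviation (intensity
#'   levels).
#' @param cal_h,cal_v calibration factors (mm per pixel).
#' @param size image `(height, width)` in pixels.
#' @param center_px iris centre `(col, row)`; default image centre.
#' @param highlights logical, add two 255-level highlight dots.
#' @param highlight_radius_px,highlight_sep_px geometry of the dots.
#' @param seed integer seed used by [make_eye_image()].
#' @return an object of class `image_truth`.
#' @export
image_truth <- function(iris_semi_axes_px = c(295, 287.5),
                        pupil_radius_px = 125,
                        intensities = c(pupil = 20, iris = 110, sclera = 220),
                        noise_sd = 8, cal_h = 0.02, cal_v = 0.02,
                        size = c(1024, 1280), center_px = NULL,
                        highlights = FALSE, highlight_radius_px = 6,
                        highlight_sep_px = 60, seed = NULL) {
  l3d_assert(length(intensities) == 3 &&
               intensities[1] < intensities[2] && intensities[2] < intensities[3],
             "bad_parameters", "intensities must satisfy pupil < iris < sclera")
  l3d_assert(pupil_radius_px < min(iris_semi_axes_px), "bad_parameters",
             "pupil radius must be smaller than both iris semi-axes")
  l3d_assert(cal_h > 0 && cal_v > 0, "bad_parameters",
             "calibration factors must be positive")
  if (is.null(center_px)) center_px <- c((size[2] + 1) / 2, (size[1] + 1) / 2)
  structure(list(iris_semi_axes_px = iris_semi_axes_px,
                 pupil_radius_px = pupil_radius_px,
                 intensities = intensities, noise_sd = noise_sd,
                 cal_h = cal_h, cal_v = cal_v, size = size,
                 center_px = center_px, highlights = highlights,
                 highlight_radius_px = highlight_radius_px,
                 highlight_sep_px = highlight_sep_px, seed = seed),
            class = "image_truth")
}

#' Render a synthetic eye image with analytic white-to-white truth
#'
#' @param truth an [image_truth()].
#' @param seed integer seed; defaults to `truth$seed`.
#' @return a list with `image` (an [eye_image()]) and `truth` extended with
#'   `wtw_radius_mm`, the analytic per-degree polar radius of the iris
#'   ellipse about its centre in millimetres.
#' @export
make_eye_image <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "image_truth"))
  if (!is.null(seed)) set.seed(seed)
  H <- truth$size[1]; W <- truth$size[2]
  cx <- truth$center_px[1]; cy <- truth$center_px[2]
  a <- truth$iris_semi_axes_px[1]; b <- truth$iris_semi_axes_px[2]
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  row <- matrix(seq_len(H), H, W)
  dx <- col - cx; dy <- row - cy
  pix <- matrix(truth$intensities[3], H, W)
  iris <- (dx / a)^2 + (dy / b)^2 <= 1
  pix[iris] <- truth$intensities[2]
  pupil <- dx^2 + dy^2 <= truth$pupil_radius_px^2
  pix[pupil] <- truth$intensities[1]
  if (isTRUE(truth$highlights)) {
    for (sgn in c(-1, 1)) {
      hl <- dx^2 + (dy - sgn * truth$highlight_sep_px / 2)^2 <=
        truth$highlight_radius_px^2
      pix[hl] <- 255
    }
  }
  if (truth$noise_sd > 0) {
    pix <- pix + matrix(rnorm(H * W, 0, truth$noise_sd), H, W)
  }
  pix <- pmin(pmax(round(pix), 0), 255)
  th <- deg2rad(0:359)
  am <- a * truth$cal_h; bm <- b * truth$cal_v
  truth$wtw_radius_mm <- am * bm / sqrt((bm * cos(th))^2 + (am * sin(th))^2)
  list(image = eye_image(pix, cal_h = truth$cal_h, cal_v = truth$cal_v),
       truth = truth)
}
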