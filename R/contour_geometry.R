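## Geometry of the detected limbus contour: best-fit plane and tilt angles,
## leveling, per-orientation sagittal depths, and the per-degree radial
## difference between the limbus contour and the white-to-white contour.
##
## Tilt convention: the plane z = a*x + b*y + c tilts by theta_y = atan(a)
## about the Y-axis (measured counter-clockwise from +X) and by
## theta_x = atan(b) about the X-axis (measured counter-clockwise from +Y).
## Mirroring a right eye into a left eye (x -> -x) flips the sign of
## theta_y and preserves theta_x.

#' Least-squares plane fit of a limbus contour
#'
#' Ordinary least squares in z over the valid contour points; at the few
#' degrees of tilt seen at the limbus this is indistinguishable from a
#' total-least-squares fit and is exactly verifiable by hand.
#'
#' @param contour a [limbus_contour()].
#' @return an object of class `plane_fit` with slopes `a`, `b`, offset `c`
#'   (mm), angles `theta_x`, `theta_y` (degrees) and `rms_residual` (mm).
#' @export
fit_contour_plane <- function(contour) {
  stopifnot(inherits(contour, "limbus_contour"))
  p <- contour$points[contour$valid, , drop = FALSE]
  if (nrow(p) < 3) l3d_error("degenerate_contour", "fewer than 3 valid points")
  xy <- sweep(p[, 1:2], 2, colMeans(p[, 1:2]))
  if (min(svd(xy)$d) < 1e-9) {
    l3d_error("degenerate_contour", "contour points are collinear in XY")
  }
  fit <- lm.fit(cbind(1, p[, 1], p[, 2]), p[, 3])
  cf <- fit$coefficients
  structure(list(a = cf[[2]], b = cf[[3]], c = cf[[1]],
                 theta_x = rad2deg(atan(cf[[3]])),
                 theta_y = rad2deg(atan(cf[[2]])),
                 rms_residual = sqrt(mean(fit$residuals^2))),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> theta_x %.3f deg, theta_y %.3f deg, rms %.4f mm\n",
              x$theta_x, x$theta_y, x$rms_residual))
  invisible(x)
}

#' Level a contour so its fitted plane is normal to the Z-axis
#'
#' Rigidly rotates the contour by the minimal rotation taking the fitted
#' plane's normal to +Z; refitting the leveled contour gives zero tilt and
#' an unchanged rms residual.
#'
#' @param contour a [limbus_contour()].
#' @param plane optional [fit_contour_plane()] result (fitted if omitted).
#' @return the leveled [limbus_contour()].
#' @export
level_contour <- function(contour, plane = NULL) {
  stopifnot(inherits(contour, "limbus_contour"))
  if (is.null(plane)) plane <- fit_contour_plane(contour)
  R <- rotation_between(c(-plane$a, -plane$b, 1), c(0, 0, 1))
  pts <- contour$points
  ok <- contour$valid
  pts[ok, ] <- pts[ok, , drop = FALSE] %*% t(R)
  limbus_contour(contour$angle_deg, pts, contour$valid, contour$quality,
                 contour$laterality)
}

#' Sagittal depths of the limbus at the clinical orientations
#'
#' Depth is |z| of the (raw, unleveled) contour point on each clinical
#' meridian, relative to the corneal apex plane z = 0.  Nasal and temporal
#' resolve through the laterality convention.
#'
#' @param contour a [limbus_contour()] with a laterality tag (or supply
#'   `laterality`).
#' @param laterality `"right"` or `"left"`; overrides the contour tag.
#' @return named list with `nasal`, `temporal`, `superior`, `inferior` (mm).
#' @export
sagittal_depths <- function(contour, laterality = contour$laterality) {
  stopifnot(inherits(contour, "limbus_contour"))
  ang <- clinical_angles(laterality)
  out <- lapply(ang, function(a) {
    i <- which(abs(contour$angle_deg - a) < 1e-6)
    if (length(i) != 1 || !contour$valid[i]) {
      l3d_error("axis_meridian_invalid",
                sprintf("meridian %g deg missing or invalid", a))
    }
    unname(abs(contour$points[i, 3]))
  })
  names(out) <- names(ang)
  out
}

## polar radius about `origin` resampled to integer degrees; linear
## interpolation in angle, only across gaps up to max_gap_deg
resample_polar_radius <- function(xy, valid, origin, max_gap_deg = 3) {
  xy <- xy[valid, , drop = FALSE]
  if (nrow(xy) == 0) return(rep(NA_real_, 360))
  dx <- xy[, 1] - origin[1]
  dy <- xy[, 2] - origin[2]
  a <- wrap360(rad2deg(atan2(dy, dx)))
  r <- sqrt(dx^2 + dy^2)
  o <- order(a)
  a <- a[o]; r <- r[o]
  ## periodic extension for interpolation across 0/360
  a_ext <- c(a[length(a)] - 360, a, a[1] + 360)
  r_ext <- c(r[length(r)], r, r[1])
  out <- rep(NA_real_, 360)
  th <- 0:359
  seg <- findInterval(th, a_ext)
  ok <- seg >= 1 & seg < length(a_ext)
  gap <- a_ext[pmin(seg + 1, length(a_ext))] - a_ext[pmax(seg, 1)]
  on_node <- ok & th == a_ext[pmax(seg, 1)]   # exact hits need no neighbour
  ok <- ok & (gap <= max_gap_deg | on_node)
  if (any(ok)) {
    i <- seg[ok]
    t <- (th[ok] - a_ext[i]) / (a_ext[i + 1] - a_ext[i])
    out[ok] <- (1 - t) * r_ext[i] + t * r_ext[i + 1]
  }
  out
}

#' Radial difference map between limbus and white-to-white contours
#'
#' For each integer degree, delta(theta) is the XY-projected polar radius
#' of the limbus contour minus the white-to-white radius, both measured
#' about a common origin: the corneal apex (surface origin) or the
#' white-to-white centre.
#'
#' @param limbus a [limbus_contour()].
#' @param wtw a [wtw_contour()] in the same frame (image principal point
#'   registered to the surface origin).
#' @param origin_policy `"apex"` or `"wtw_center"`.
#' @return an object of class `delta_map` with `delta_mm` (360 values),
#'   `valid`, `argmax_deg`, `argmin_deg`, `mean_mm`.
#' @export
radial_difference_map <- function(limbus, wtw,
                                  origin_policy = c("apex", "wtw_center")) {
  stopifnot(inherits(limbus, "limbus_contour"), inherits(wtw, "wtw_contour"))
  origin_policy <- match.arg(origin_policy)
  origin <- if (origin_policy == "apex") c(0, 0) else wtw$center
  r_lim <- resample_polar_radius(limbus$points[, 1:2, drop = FALSE],
                                 limbus$valid, origin)
  th <- deg2rad(0:359)
  wtw_xy <- cbind(wtw$center[1] + wtw$radius_mm * cos(th),
                  wtw$center[2] + wtw$radius_mm * sin(th))
  r_wtw <- resample_polar_radius(wtw_xy, rep(TRUE, 360), origin)
  delta <- r_lim - r_wtw
  valid <- is.finite(delta)
  if (!any(valid)) l3d_error("no_overlap", "no angle where both contours are valid")
  idx <- which(valid)
  structure(list(delta_mm = delta, valid = valid,
                 argmax_deg = idx[which.max(delta[idx])] - 1L,
                 argmin_deg = idx[which.min(delta[idx])] - 1L,
                 mean_mm = mean(delta[valid])),
            class = "delta_map")
}

#' @export
print.delta_map <- function(x, ...) {
  cat(sprintf("<delta_map> mean %.3f mm, max at %d deg, min at %d deg, %d/360 valid\n",
              x$mean_mm, x$argmax_deg, x$argmin_deg, sum(x$valid)))
  invisible(x)
}

#' Write a delta map to CSV (`angle_deg,delta_mm,valid`)
#'
#' @param map a `delta_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delta_map <- function(map, path) {
  df <- data.frame(angle_deg = 0:359, delta_mm = map$delta_mm,
                   valid = as.integer(map$valid))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-eye geometry report
#'
#' Bundles the quantities reported per eye: tilt angles, residual, limbus
#' diameters, white-to-white distances, sagittal depths and the delta-map
#' summary.
#'
#' @param limbus a [limbus_contour()] with laterality.
#' @param wtw optional [wtw_contour()]; delta map and WTW distances are
#'   omitted when absent.
#' @param origin_policy passed to [radial_difference_map()].
#' @return named list (an `eye_report`).
#' @export
eye_report <- function(limbus, wtw = NULL,
                       origin_policy = c("apex", "wtw_center")) {
  plane <- fit_contour_plane(limbus)
  dia <- axis_diameters(limbus)
  depths <- sagittal_depths(limbus)
  rep <- list(laterality = limbus$laterality,
              theta_x_deg = plane$theta_x, theta_y_deg = plane$theta_y,
              rms_mm = plane$rms_residual,
              limbus_nt_mm = dia$NT, limbus_si_mm = dia$SI,
              depth_nasal_mm = depths$nasal, depth_temporal_mm = depths$temporal,
              depth_superior_mm = depths$superior,
              depth_inferior_mm = depths$inferior)
  if (!is.null(wtw)) {
    d <- wtw_axis_distances(wtw)
    dm <- radial_difference_map(limbus, wtw, origin_policy)
    rep <- c(rep, list(wtw_nt_mm = d$NT, wtw_si_mm = d$SI,
                       delta_argmax_deg = dm$argmax_deg,
                       delta_argmin_deg = dm$argmin_deg,
                       delta_mean_mm = dm$mean_mm))
  }
  class(rep) <- "eye_report"
  rep
}
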