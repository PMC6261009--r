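## 3D limbus detection from anterior-surface height data.
##
## The cornea and the sclera have different curvatures; on each meridian the
## surface tangent gradient ds/dr rises from zero at the apex to a local
## maximum just before the limbus, decreases through the limbal transition,
## then rises again on the sclera.  The limbus is therefore located, per
## meridian, at the turning point of the second radial derivative of
## sagittal height: the most prominent interior local minimum of d2s/dr2
## inside a search window bracketing clinically plausible limbal radii.
## Meridians without enough valid data (eyelid cover) yield invalid flags,
## never failures, so partially occluded scans still produce a contour.

## ---- scattered -> grid rasterization --------------------------------------
## Moving-least-squares plane fit per grid node over a 3x3 cell
## neighbourhood, vectorized through moment accumulation.  This is the
## "local linear interpolation" stage: exact on planes, O(h^2) on smooth
## surfaces, and NA wherever a node has no supporting points.

shift_sum3 <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(0, nr + 2, nc + 2)
  S <- matrix(0, nr, nc)
  P[2:(nr + 1), 2:(nc + 1)] <- M
  for (di in 0:2) for (dj in 0:2) {
    S <- S + P[di + seq_len(nr), dj + seq_len(nc)]
  }
  S
}

## returns list(xg, yg, Z) with Z[y, x]
rasterize_height_field <- function(field, spacing = 0.05) {
  p <- field$points
  h <- spacing
  xg <- seq(floor(min(p[, 1]) / h) * h, ceiling(max(p[, 1]) / h) * h, by = h)
  yg <- seq(floor(min(p[, 2]) / h) * h, ceiling(max(p[, 2]) / h) * h, by = h)
  nx <- length(xg); ny <- length(yg)
  ix <- pmin(pmax(round((p[, 1] - xg[1]) / h), 0), nx - 1)
  iy <- pmin(pmax(round((p[, 2] - yg[1]) / h), 0), ny - 1)
  lin <- ix * ny + iy + 1
  acc <- function(v) {
    M <- matrix(0, ny, nx)
    s <- rowsum(v, lin)
    M[as.integer(rownames(s))] <- s
    shift_sum3(M)
  }
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  n   <- acc(rep(1, length(x)))
  Sx  <- acc(x);      Sy  <- acc(y)
  Sxx <- acc(x * x);  Syy <- acc(y * y); Sxy <- acc(x * y)
  Sz  <- acc(z);      Szx <- acc(z * x); Szy <- acc(z * y)
  X0 <- matrix(xg, ny, nx, byrow = TRUE)
  Y0 <- matrix(yg, ny, nx)
  Sdx <- Sx - n * X0
  Sdy <- Sy - n * Y0
  Sdx2 <- Sxx - 2 * X0 * Sx + n * X0^2
  Sdy2 <- Syy - 2 * Y0 * Sy + n * Y0^2
  Sdxy <- Sxy - X0 * Sy - Y0 * Sx + n * X0 * Y0
  Szdx <- Szx - X0 * Sz
  Szdy <- Szy - Y0 * Sz
  det <- n * (Sdx2 * Sdy2 - Sdxy^2) - Sdx * (Sdx * Sdy2 - Sdxy * Sdy) +
    Sdy * (Sdx * Sdxy - Sdx2 * Sdy)
  detc <- Sz * (Sdx2 * Sdy2 - Sdxy^2) - Sdx * (Szdx * Sdy2 - Sdxy * Szdy) +
    Sdy * (Szdx * Sdxy - Sdx2 * Szdy)
  Z <- detc / det
  Z[n < 3 | abs(det) < 1e-10] <- NA_real_
  list(xg = xg, yg = yg, Z = Z)
}

#' Resample a height field onto a polar meridian grid
#'
#' Interpolates sagittal height s = -z onto `n_meridians` uniformly spaced
#' meridians at radial step `dr`, by local-plane rasterization of the
#' scattered points followed by bilinear sampling.  Samples without point
#' support are flagged invalid.
#'
#' @param field an apex-centred [height_field()].
#' @param n_meridians number of meridians (default 360, i.e. 1 degree).
#' @param dr radial step (mm).
#' @param r_max maximal radius (mm); should pass the limbal zone.
#' @param spacing rasterization grid spacing (mm).
#' @param max_invalid_fraction error threshold on the overall fraction of
#'   unsupported samples.
#' @return an object of class `meridian_set` with `angles`, `r_grid`,
#'   matrices `sag` and `valid` (meridians in rows), and `dr`.
#' @export
polar_resample <- function(field, n_meridians = 360, dr = 0.01, r_max = 8.5,
                           spacing = 0.05, max_invalid_fraction = 0.5) {
  stopifnot(inherits(field, "height_field"))
  ras <- rasterize_height_field(field, spacing)
  angles <- seq(0, 360, length.out = n_meridians + 1)[seq_len(n_meridians)]
  r_grid <- seq(0, r_max, by = dr)
  th <- deg2rad(angles)
  X <- outer(cos(th), r_grid)          # n_meridians x n_r
  Y <- outer(sin(th), r_grid)
  z <- interp_bilinear(ras$xg, ras$yg, ras$Z, as.vector(X), as.vector(Y))
  sag <- matrix(-z, n_meridians, length(r_grid))
  valid <- is.finite(sag)
  frac_bad <- mean(!valid)
  if (frac_bad > max_invalid_fraction) {
    l3d_error("insufficient_coverage",
              sprintf("%.0f%% of polar samples lack point support", 100 * frac_bad))
  }
  ## pin the common apex sample to exactly zero sag
  s0 <- interp_bilinear(ras$xg, ras$yg, ras$Z, 0, 0)
  if (is.finite(s0)) sag <- sag + s0
  sag[!valid] <- NA_real_
  structure(list(angles = angles, r_grid = r_grid, sag = sag, valid = valid,
                 dr = dr),
            class = "meridian_set")
}

#' @export
print.meridian_set <- function(x, ...) {
  cat(sprintf("<meridian_set> %d meridians x %d radial samples (dr %.3g mm), %.1f%% valid\n",
              length(x$angles), length(x$r_grid), x$dr, 100 * mean(x$valid)))
  invisible(x)
}

## precompute the three Savitzky-Golay filter matrices for a window
sg_filters <- function(nwin, poly_order, dr) {
  lapply(0:2, function(m) signal::sgolay(p = poly_order, n = nwin, m = m,
                                         ts = dr))
}

#' Radial derivatives of one meridian's sagittal height
#'
#' First and second derivatives via local polynomial (Savitzky-Golay)
#' fitting: a polynomial of order `poly_order` is fitted over a sliding
#' window of half-width `smooth_halfwidth` and the derivatives evaluated
#' analytically from the fitted coefficients.  Invalid gaps propagate:
#' each contiguous valid run is filtered independently and runs shorter
#' than the window stay invalid.
#'
#' @param s sagittal heights (mm) on the radial grid.
#' @param r radial grid (mm), uniform spacing.
#' @param smooth_halfwidth half-width of the fitting window (mm).  The
#'   default, 0.7 mm, is about twice the width of the limbal curvature
#'   transition, the scale at which the second-derivative estimate is most
#'   noise-efficient without blurring the transition away.
#' @param poly_order polynomial order (>= 2 for a second derivative).
#' @param valid logical availability flags (default: finite `s`).
#' @param filters optional precomputed [signal::sgolay()] filter list.
#' @return an object of class `derivative_profile` with `r`, `s`,
#'   `s_smooth`, `d1`, `d2`, `valid`.
#' @export
meridian_derivatives <- function(s, r, smooth_halfwidth = 0.7, poly_order = 3,
                                 valid = NULL, filters = NULL) {
  dr <- r[2] - r[1]
  l3d_assert(poly_order >= 2, "bad_parameters", "poly_order must be >= 2")
  nwin <- 2 * round(smooth_halfwidth / dr) + 1
  l3d_assert(nwin > poly_order, "bad_parameters",
             "window too short for the polynomial order")
  if (is.null(valid)) valid <- is.finite(s)
  runs <- rle(valid)
  if (!any(runs$values & runs$lengths >= nwin)) {
    l3d_error("window_too_wide",
              sprintf("no contiguous valid span of >= %d samples for a %.2f mm window",
                      nwin, 2 * smooth_halfwidth))
  }
  if (is.null(filters)) filters <- sg_filters(nwin, poly_order, dr)
  s_sm <- d1 <- d2 <- rep(NA_real_, length(s))
  covered <- rep(FALSE, length(s))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < nwin) next
    i <- starts[k]:ends[k]
    s_sm[i] <- signal::sgolayfilt(s[i], filters[[1]])
    d1[i] <- signal::sgolayfilt(s[i], filters[[2]])
    d2[i] <- signal::sgolayfilt(s[i], filters[[3]])
    covered[i] <- TRUE
  }
  structure(list(r = r, s = s, s_smooth = s_sm, d1 = d1, d2 = d2,
                 valid = covered),
            class = "derivative_profile")
}

#' Locate the limbus turning point on one meridian
#'
#' The limbus is the most prominent interior local minimum of the second
#' derivative profile within the search window; its prominence is the
#' quality score.  The minimum's position is refined to sub-sample
#' precision by a three-point parabolic fit.  Returns an invalid result
#' (not an error) when the window lacks data or no interior minimum
#' reaches `min_prominence`; prominence ties break toward smaller radius
#' (the corneal side).
#'
#' @param profile a `derivative_profile` from [meridian_derivatives()].
#' @param window search window `c(r_lo, r_hi)` in mm, chosen to bracket
#'   clinically reported limbal radii.
#' @param min_prominence minimal prominence (1/mm) of the accepted minimum.
#' @param min_window_fraction minimal fraction of the window that must hold
#'   valid samples.
#' @return list with `radius`, `quality`, `sag`, `valid`.
#' @export
locate_limbus_point <- function(profile, window = c(4.5, 8.5),
                                min_prominence = 0.02,
                                min_window_fraction = 0.8) {
  stopifnot(inherits(profile, "derivative_profile"))
  invalid <- list(radius = NA_real_, quality = NA_real_, sag = NA_real_,
                  valid = FALSE)
  sel <- which(profile$r >= window[1] & profile$r <= window[2])
  if (length(sel) == 0) return(invalid)
  if (mean(profile$valid[sel]) < min_window_fraction) return(invalid)
  ## largest contiguous valid run inside the window
  runs <- rle(profile$valid[sel])
  ends <- cumsum(runs$lengths)
  ok <- which(runs$values)
  k <- ok[which.max(runs$lengths[ok])]
  i <- sel[(ends[k] - runs$lengths[k] + 1):ends[k]]
  mins <- prominent_minima(profile$d2[i])
  mins <- mins[mins$prominence >= min_prominence, , drop = FALSE]
  if (nrow(mins) == 0) return(invalid)
  at <- i[mins$index[1]]
  ## parabolic sub-sample refinement of the minimum position
  off <- 0
  if (at > i[1] && at < i[length(i)]) {
    y0 <- profile$d2[at - 1]; y1 <- profile$d2[at]; y2 <- profile$d2[at + 1]
    den <- y0 - 2 * y1 + y2
    if (is.finite(den) && den > 0) off <- max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
  }
  dr <- profile$r[2] - profile$r[1]
  radius <- profile$r[at] + off * dr
  sag <- if (off >= 0) {
    (1 - off) * profile$s_smooth[at] + off * profile$s_smooth[min(at + 1, length(profile$r))]
  } else {
    (1 + off) * profile$s_smooth[at] - off * profile$s_smooth[max(at - 1, 1)]
  }
  list(radius = radius, quality = mins$prominence[1], sag = sag, valid = TRUE)
}

#' Assemble per-meridian limbus points into a 3D contour
#'
#' @param mset the `meridian_set` the points were detected on.
#' @param results list of per-meridian results from
#'   [locate_limbus_point()], one per meridian of `mset`.
#' @param min_valid_fraction minimal fraction of valid meridians.
#' @param laterality optional `"right"`/`"left"` tag.
#' @return a [limbus_contour()]; invalid meridians are flagged, never
#'   interpolated.
#' @export
assemble_limbus_contour <- function(mset, results, min_valid_fraction = 0.5,
                                    laterality = NULL) {
  stopifnot(inherits(mset, "meridian_set"))
  n <- length(mset$angles)
  stopifnot(length(results) == n)
  valid <- vapply(results, function(x) isTRUE(x$valid), logical(1))
  if (mean(valid) < min_valid_fraction) {
    l3d_error("too_few_valid_meridians",
              sprintf("only %d/%d meridians yielded a limbus point", sum(valid), n))
  }
  radius <- vapply(results, function(x) x$radius %||% NA_real_, numeric(1))
  sag <- vapply(results, function(x) x$sag %||% NA_real_, numeric(1))
  quality <- vapply(results, function(x) x$quality %||% NA_real_, numeric(1))
  th <- deg2rad(mset$angles)
  pts <- cbind(radius * cos(th), radius * sin(th), -sag)
  pts[!valid, ] <- NA_real_
  limbus_contour(mset$angles, pts, valid, quality, laterality)
}

#' Nasal-temporal and superior-inferior limbus diameters
#'
#' 3D Euclidean chord lengths between the 0/180 and 90/270 degree contour
#' points (rigid-motion invariant).
#'
#' @param contour a [limbus_contour()].
#' @return list with `NT` and `SI` in mm.
#' @export
axis_diameters <- function(contour) {
  stopifnot(inherits(contour, "limbus_contour"))
  at <- function(a) {
    i <- which(abs(contour$angle_deg - a) < 1e-6)
    if (length(i) != 1 || !contour$valid[i]) {
      l3d_error("axis_meridian_invalid",
                sprintf("meridian %g deg missing or invalid", a))
    }
    contour$points[i, ]
  }
  d3 <- function(p, q) sqrt(sum((p - q)^2))
  list(NT = d3(at(0), at(180)), SI = d3(at(90), at(270)))
}

#' Full limbus detection pipeline
#'
#' Polar resampling, per-meridian Savitzky-Golay derivatives, turning-point
#' location, contour assembly.  Meridians whose valid span cannot support
#' the smoothing window come back invalid rather than failing.
#'
#' @param x a [height_field()] or an [eye_record()] (its height field is
#'   used and its laterality carried onto the contour).
#' @param n_meridians,dr,r_max,spacing passed to [polar_resample()].
#' @param smooth_halfwidth,poly_order passed to [meridian_derivatives()].
#' @param window,min_prominence passed to [locate_limbus_point()].
#' @param min_valid_fraction passed to [assemble_limbus_contour()].
#' @param laterality optional override tag.
#' @return list with `contour` (a [limbus_contour()]) and `meridians` (the
#'   `meridian_set`).
#' @export
detect_limbus <- function(x, n_meridians = 360, dr = 0.01, r_max = 8.5,
                          spacing = 0.05, smooth_halfwidth = 0.7,
                          poly_order = 3, window = c(4.5, 8.5),
                          min_prominence = 0.02, min_valid_fraction = 0.5,
                          laterality = NULL) {
  if (inherits(x, "eye_record")) {
    if (is.null(laterality)) laterality <- x$laterality
    x <- x$height
  }
  mset <- polar_resample(x, n_meridians, dr, r_max, spacing)
  nwin <- 2 * round(smooth_halfwidth / dr) + 1
  filters <- sg_filters(nwin, poly_order, dr)
  results <- lapply(seq_along(mset$angles), function(m) {
    prof <- tryCatch(
      meridian_derivatives(mset$sag[m, ], mset$r_grid, smooth_halfwidth,
                           poly_order, valid = mset$valid[m, ],
                           filters = filters),
      limbus3d_window_too_wide = function(e) NULL)
    if (is.null(prof)) {
      return(list(radius = NA_real_, quality = NA_real_, sag = NA_real_,
                  valid = FALSE))
    }
    locate_limbus_point(prof, window, min_prominence)
  })
  contour <- assemble_limbus_contour(mset, results, min_valid_fraction,
                                     laterality)
  list(contour = contour, meridians = mset)
}
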