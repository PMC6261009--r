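## Dynamic white-to-white (visible iris boundary) detection.
##
## A grayscale anterior-eye image contains three intensity populations:
## the pupil (darkest), the iris, and the sclera (brightest).  Whatever the
## iris colour and lighting, the order of the three histogram peaks is
## preserved, so the iris/sclera threshold can be chosen dynamically per
## image: locate the three main peaks of the light-intensity frequency
## spectrum and cut at the valley between the iris and sclera peaks.  The
## boundary of the resulting dark (iris + pupil) region is the
## white-to-white contour.

#' Light-intensity frequency spectrum of an eye image
#'
#' @param image an [eye_image()].
#' @param smooth_window odd window (intensity levels) of the centred moving
#'   average applied to the raw counts; ends are reflected.
#' @return an object of class `intensity_spectrum` with `counts` and
#'   `smoothed`, both length 256 (levels 0..255).
#' @export
intensity_spectrum <- function(image, smooth_window = 7) {
  stopifnot(inherits(image, "eye_image"))
  l3d_assert(smooth_window >= 1 && smooth_window %% 2 == 1,
             "bad_parameters", "smooth_window must be an odd integer >= 1")
  counts <- tabulate(as.vector(image$pixels) + 1L, nbins = 256L)
  smoothed <- reflect_ma(counts, smooth_window)
  structure(list(counts = counts, smoothed = smoothed,
                 n_pixels = length(image$pixels),
                 smooth_window = smooth_window),
            class = "intensity_spectrum")
}

## centred moving average with reflective end padding, renormalized so the
## smoothed spectrum carries exactly the same total mass as the raw counts
reflect_ma <- function(x, w) {
  if (w == 1) return(as.numeric(x))
  h <- (w - 1) / 2
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[length(x) - seq_len(h)]))
  sm <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[h + seq_along(x)]
  sm * sum(x) / sum(sm)
}

#' Locate the pupil, iris and sclera histogram peaks
#'
#' Finds the three most prominent local maxima of the smoothed spectrum and
#' returns them ordered by intensity (not by prominence): the darkest peak
#' is the pupil, the middle the iris, the brightest the sclera.
#'
#' @param spectrum an [intensity_spectrum()].
#' @param min_prominence minimal peak prominence as a fraction of the
#'   spectrum's maximum.
#' @return an object of class `peak_triple` with intensity levels
#'   `pupil_I < iris_I < sclera_I` and their prominences.
#' @export
locate_colour_peaks <- function(spectrum, min_prominence = 0.01) {
  stopifnot(inherits(spectrum, "intensity_spectrum"))
  y <- spectrum$smoothed
  ## the intensity domain is bounded at 0 and 255; modes sitting on a
  ## boundary are genuine peaks, so pad with sentinels to expose them
  pk <- prominent_maxima(c(-1, y, -1))
  pk$index <- pk$index - 1L
  pk <- pk[pk$index >= 1 & pk$index <= 256 &
             pk$prominence >= min_prominence * max(y), , drop = FALSE]
  if (nrow(pk) < 3) {
    l3d_error("peak_count",
              sprintf("found %d prominent peaks, need 3 (pupil, iris, sclera)",
                      nrow(pk)))
  }
  pk <- pk[1:3, ]
  ## smoothing turns an isolated spike into a plateau; put the reported
  ## level at the raw-count mode within the plateau
  pk$index <- vapply(pk$index, function(i) {
    j <- i
    while (j < 256 && y[j + 1] == y[i]) j <- j + 1L
    window <- i:j
    window[which.max(spectrum$counts[window])]
  }, integer(1))
  o <- order(pk$index)
  structure(list(pupil_I = pk$index[o][1] - 1L,
                 iris_I = pk$index[o][2] - 1L,
                 sclera_I = pk$index[o][3] - 1L,
                 prominences = pk$prominence[o]),
            class = "peak_triple")
}

#' Dynamic iris/sclera threshold
#'
#' The valley: intensity of the minimum of the smoothed spectrum strictly
#' between the iris and sclera peaks.
#'
#' @param spectrum an [intensity_spectrum()].
#' @param peaks a `peak_triple` from [locate_colour_peaks()].
#' @return intensity level (0..255).
#' @export
iris_sclera_threshold <- function(spectrum, peaks) {
  rng <- (peaks$iris_I + 1L):(peaks$sclera_I + 1L)
  rng[which.min(spectrum$smoothed[rng])] - 1L
}

#' Extract the iris-and-pupil region of an eye image
#'
#' Thresholds the image at the iris/sclera valley, removes pixel bridges
#' with a single 3-px disc opening, keeps the connected component that
#' contains the seed point, and fills interior holes (the pupil and any
#' specular highlight dots).
#'
#' @param image an [eye_image()].
#' @param peaks a `peak_triple`.
#' @param seed_point pixel `(col, row)` expected inside the iris/pupil;
#'   default: the image principal point.
#' @param highlight_cutoff intensities at or above this level are treated
#'   as specular highlights (never part of the dark class).
#' @return logical matrix mask, same shape as the image.
#' @export
extract_iris_region <- function(image, peaks, seed_point = NULL,
                                highlight_cutoff = 250) {
  stopifnot(inherits(image, "eye_image"), inherits(peaks, "peak_triple"))
  if (is.null(seed_point)) seed_point <- round(principal_point(image))
  spectrum <- intensity_spectrum(image)
  thr <- iris_sclera_threshold(spectrum, peaks)
  dark <- image$pixels < thr & image$pixels < highlight_cutoff
  sr <- seed_point[2]; sc <- seed_point[1]
  l3d_assert(sr >= 1 && sr <= nrow(dark) && sc >= 1 && sc <= ncol(dark),
             "seed_outside_dark", "seed point outside the image")
  if (!dark[sr, sc]) {
    l3d_error("seed_outside_dark",
              "seed pixel falls in the bright class; supply a seed inside the iris or pupil")
  }
  opened <- EBImage::opening(EBImage::Image(dark * 1),
                             EBImage::makeBrush(3, "disc"))
  lab <- EBImage::bwlabel(opened)
  id <- EBImage::imageData(lab)[sr, sc]
  if (id == 0) {
    ## the opening removed the seed's pixels; fall back to the largest blob
    tab <- tabulate(EBImage::imageData(lab))
    if (length(tab) == 0 || max(tab) == 0) l3d_error("empty_region", "no dark region found")
    id <- which.max(tab)
  }
  comp <- EBImage::imageData(lab) == id
  if (!any(comp)) l3d_error("empty_region", "no dark region found")
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  EBImage::imageData(filled) > 0
}

#' Trace the white-to-white contour of an iris mask
#'
#' From the mask centroid, casts one ray per integer degree and records the
#' distance (in mm, anisotropically scaled by the two calibration factors)
#' to the outermost mask crossing.
#'
#' @param mask logical matrix from [extract_iris_region()].
#' @param image the [eye_image()] the mask came from.
#' @param laterality optional `"right"`/`"left"` tag carried on the result.
#' @return a [wtw_contour()].
#' @export
trace_wtw_contour <- function(mask, image, laterality = NULL) {
  stopifnot(is.matrix(mask), inherits(image, "eye_image"))
  npix <- sum(mask)
  if (npix < 3) l3d_error("degenerate_mask", "mask has fewer than 3 pixels")
  idx <- which(mask, arr.ind = TRUE)
  c_row <- mean(idx[, 1]); c_col <- mean(idx[, 2])
  center_mm <- px_to_mm(image, c_col, c_row)

  step <- min(image$cal_h, image$cal_v) / 4
  t_max <- sqrt((ncol(mask) * image$cal_h)^2 + (nrow(mask) * image$cal_v)^2) / 2
  t_grid <- seq(step, t_max, by = step)
  th <- deg2rad(0:359)
  ## pixel positions along each ray (physical angle theta, distance t in mm)
  cols <- round(outer(t_grid, cos(th) / image$cal_h) + c_col)
  rows <- round(outer(t_grid, -sin(th) / image$cal_v) + c_row)
  inside <- cols >= 1 & cols <= ncol(mask) & rows >= 1 & rows <= nrow(mask)
  hit <- matrix(FALSE, length(t_grid), 360)
  hit[inside] <- mask[cbind(rows[inside], cols[inside])]
  radius <- apply(hit, 2, function(v) {
    w <- which(v)
    if (length(w) == 0) NA_real_ else t_grid[max(w)]
  })
  if (anyNA(radius) || any(radius <= 0)) {
    l3d_error("degenerate_mask", "some rays never cross the mask")
  }
  wtw_contour(center = as.numeric(center_mm), radius_mm = radius,
              laterality = laterality)
}

#' Nasal-temporal and superior-inferior white-to-white distances
#'
#' @param contour a [wtw_contour()].
#' @return list with `NT` and `SI` (mm): the sums of opposite-ray radii
#'   along the horizontal (0/180 deg) and vertical (90/270 deg) lines.
#' @export
wtw_axis_distances <- function(contour) {
  stopifnot(inherits(contour, "wtw_contour"))
  r <- contour$radius_mm
  list(NT = r[1] + r[181], SI = r[91] + r[271])
}

#' Full white-to-white pipeline
#'
#' Spectrum -> peak triple -> dynamic threshold -> iris region -> contour.
#'
#' @param image an [eye_image()].
#' @param smooth_window,min_prominence,seed_point,highlight_cutoff passed
#'   to the component stages.
#' @param laterality optional tag.
#' @return list with `contour` (a [wtw_contour()]), `peaks`, `threshold`,
#'   `NT`, `SI`.
#' @export
detect_wtw <- function(image, smooth_window = 7, min_prominence = 0.01,
                       seed_point = NULL, highlight_cutoff = 250,
                       laterality = NULL) {
  spectrum <- intensity_spectrum(image, smooth_window)
  peaks <- locate_colour_peaks(spectrum, min_prominence)
  mask <- extract_iris_region(image, peaks, seed_point, highlight_cutoff)
  contour <- trace_wtw_contour(mask, image, laterality)
  d <- wtw_axis_distances(contour)
  list(contour = contour, peaks = peaks,
       threshold = iris_sclera_threshold(spectrum, peaks),
       NT = d$NT, SI = d$SI)
}
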