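## Per-eye records and contour files.
##
## Coordinate frame: corneal apex at the origin, +Z toward the camera, the
## anterior surface stored with z <= 0 (sag convention).  Meridian angle is
## counter-clockwise from +X.  Laterality is always explicit; clinical
## nasal/temporal labels mirror between right and left eyes.

#' Anterior-surface height field
#'
#' @param points numeric matrix with columns x, y, z in millimetres.
#' @param grid_flag logical, whether the points lie on a regular XY grid.
#' @return an object of class `height_field`.
#' @export
height_field <- function(points, grid_flag = FALSE) {
  points <- as.matrix(points)
  l3d_assert(ncol(points) == 3, "empty_surface", "points must have 3 columns")
  points <- points[stats::complete.cases(points) & is.finite(rowSums(points)), ,
                   drop = FALSE]
  l3d_assert(nrow(points) > 0, "empty_surface", "no finite height points")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, grid_flag = isTRUE(grid_flag)),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("<height_field> %d points, %s layout, r up to %.2f mm\n",
              nrow(x$points), if (x$grid_flag) "gridded" else "scattered",
              max(sqrt(x$points[, 1]^2 + x$points[, 2]^2))))
  invisible(x)
}

#' Calibrated 8-bit grayscale eye image
#'
#' @param pixels integer matrix (rows = image height) with values 0..255.
#' @param cal_h,cal_v horizontal and vertical calibration factors, mm per
#'   pixel, both positive.
#' @return an object of class `eye_image`.
#' @export
eye_image <- function(pixels, cal_h, cal_v) {
  pixels <- as.matrix(pixels)
  l3d_assert(is_finite_num(cal_h) && cal_h > 0 &&
               is_finite_num(cal_v) && cal_v > 0,
             "bad_calibration", "calibration factors must be finite and > 0")
  l3d_assert(all(is.finite(pixels)) && all(pixels >= 0 & pixels <= 255) &&
               all(pixels == round(pixels)),
             "bad_calibration", "pixel intensities must be integers in 0..255")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, height_px = nrow(pixels),
                 width_px = ncol(pixels), cal_h = cal_h, cal_v = cal_v),
            class = "eye_image")
}

#' @export
print.eye_image <- function(x, ...) {
  cat(sprintf("<eye_image> %dx%d px, cal %.4f x %.4f mm/px\n",
              x$height_px, x$width_px, x$cal_h, x$cal_v))
  invisible(x)
}

#' Image principal point
#'
#' The pixel `(col, row)` that registers to the surface XY origin; by
#' default the image centre.
#' @param image an [eye_image()].
#' @return numeric `(col, row)`.
#' @export
principal_point <- function(image) {
  c((image$width_px + 1) / 2, (image$height_px + 1) / 2)
}

#' Convert pixel coordinates to surface millimetres
#'
#' The image principal point (default: image centre) maps to the surface XY
#' origin; +x is rightward, +y upward (image rows increase downward).
#'
#' @param image an [eye_image()].
#' @param col,row pixel coordinates.
#' @return a two-column matrix of x, y in mm.
#' @export
px_to_mm <- function(image, col, row) {
  p0 <- principal_point(image)
  cbind(x = (col - p0[1]) * image$cal_h, y = (p0[2] - row) * image$cal_v)
}

#' Re-express a height field with the apex at the origin
#'
#' Subtracts the apex coordinates from every point so that z = 0 at the
#' apex and z <= 0 peripherally.  Idempotent once the apex is at the
#' origin.
#'
#' @param field a [height_field()].
#' @param apex numeric length-3 apex coordinates (mm).
#' @return the centred [height_field()].
#' @export
center_on_apex <- function(field, apex) {
  stopifnot(inherits(field, "height_field"))
  l3d_assert(length(apex) == 3 && is_finite_num(apex), "bad_apex",
             "apex must be a finite 3-vector")
  field$points <- sweep(field$points, 2, as.numeric(apex))
  field
}

#' Per-eye record
#'
#' @param laterality `"right"` or `"left"`; never inferred, always required.
#' @param height a [height_field()], apex-centred.
#' @param image an [eye_image()].
#' @param apex apex coordinates after centring (normally `c(0,0,0)`).
#' @param subject_id,scan_id opaque identifier strings.
#' @param meta optional provenance list.
#' @return an object of class `eye_record`.
#' @export
eye_record <- function(laterality, height, image, apex = c(0, 0, 0),
                       subject_id = "", scan_id = "", meta = list()) {
  l3d_assert(length(laterality) == 1 && laterality %in% c("right", "left"),
             "missing_field", "laterality must be \"right\" or \"left\"")
  stopifnot(inherits(height, "height_field"), inherits(image, "eye_image"))
  ## apex must lie inside the convex hull of the XY footprint
  xy <- height$points[, 1:2, drop = FALSE]
  hull <- grDevices::chull(xy)
  inside <- pracma::inpolygon(apex[1], apex[2], xy[hull, 1], xy[hull, 2],
                              boundary = TRUE)
  l3d_assert(isTRUE(inside), "bad_apex",
             "apex does not lie within the XY footprint of the height data")
  structure(list(laterality = laterality, height = height, image = image,
                 apex = as.numeric(apex), subject_id = subject_id,
                 scan_id = scan_id, meta = meta),
            class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("<eye_record> %s/%s, %s eye, %d surface points, image %dx%d\n",
              x$subject_id, x$scan_id, x$laterality, nrow(x$height$points),
              x$image$height_px, x$image$width_px))
  invisible(x)
}

#' Clinical meridian angles for a laterality
#'
#' Superior is 90 deg and inferior 270 deg for both eyes; nasal is 180 deg
#' for right eyes and 0 deg for left eyes (the camera faces the patient),
#' temporal the opposite.
#'
#' @param laterality `"right"` or `"left"`.
#' @return named numeric vector with elements nasal, temporal, superior,
#'   inferior (degrees).
#' @export
clinical_angles <- function(laterality) {
  l3d_assert(laterality %in% c("right", "left"), "missing_field",
             "laterality must be \"right\" or \"left\"")
  if (laterality == "right") {
    c(nasal = 180, temporal = 0, superior = 90, inferior = 270)
  } else {
    c(nasal = 0, temporal = 180, superior = 90, inferior = 270)
  }
}

## ---- portable record layout ------------------------------------------------
## directory with record.json (ids, laterality, apex, calibration),
## surface.csv (x_mm,y_mm,z_mm) and image.png (8-bit grayscale)

#' Write a per-eye record in the portable layout
#'
#' @param record an [eye_record()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_eye_record <- function(record, path) {
  stopifnot(inherits(record, "eye_record"))
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) l3d_error("io_failure", paste("cannot create", path))
  hdr <- list(subject_id = record$subject_id, scan_id = record$scan_id,
              laterality = record$laterality, apex = record$apex,
              cal_h = record$image$cal_h, cal_v = record$image$cal_v,
              grid_flag = record$height$grid_flag, meta = record$meta)
  r <- try({
    jsonlite::write_json(hdr, file.path(path, "record.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    df <- as.data.frame(record$height$points)
    names(df) <- c("x_mm", "y_mm", "z_mm")
    write.csv(df, file.path(path, "surface.csv"), row.names = FALSE)
    png::writePNG(record$image$pixels / 255, file.path(path, "image.png"))
  }, silent = TRUE)
  if (inherits(r, "try-error")) l3d_error("io_failure", as.character(r))
  invisible(path)
}

#' Load a per-eye record
#'
#' Reads either the portable directory layout written by
#' [save_eye_record()] or a profilometer-style MAT v5 container.  MAT field
#' names are vendor-specific and are therefore supplied through `key_map`;
#' heights are re-expressed apex-centred (z = 0 at the apex) on load and
#' the source path recorded in `meta`.
#'
#' @param path record directory or `.mat` file.
#' @param key_map for MAT input, a named list mapping the roles `height`
#'   (n-by-3 matrix or name of a field holding x,y,z columns), `apex`,
#'   `image`, `cal_h`, `cal_v` and optionally `laterality` to container
#'   field names.  See [default_key_map()].
#' @param laterality required for MAT containers that do not store it;
#'   never guessed.
#' @return an [eye_record()].
#' @export
load_eye_record <- function(path, key_map = default_key_map(),
                            laterality = NULL) {
  if (dir.exists(path)) return(load_record_portable(path))
  l3d_assert(file.exists(path), "io_failure", paste(path, "does not exist"))
  load_record_mat(path, key_map, laterality)
}

#' Default MAT key map
#'
#' A documented guess at container field names; real exports should supply
#' their own mapping.
#' @return named list of role -> field name.
#' @export
default_key_map <- function() {
  list(height = "height", apex = "apex", image = "image",
       cal_h = "cal_h", cal_v = "cal_v", laterality = "laterality")
}

load_record_portable <- function(path) {
  jf <- file.path(path, "record.json")
  sf <- file.path(path, "surface.csv")
  pf <- file.path(path, "image.png")
  for (f in c(jf, sf, pf)) {
    l3d_assert(file.exists(f), "missing_field", paste("missing", basename(f)))
  }
  hdr <- jsonlite::read_json(jf, simplifyVector = TRUE)
  l3d_assert(!is.null(hdr$laterality), "missing_field",
             "record.json lacks laterality")
  pts <- as.matrix(read.csv(sf))
  img <- round(png::readPNG(pf) * 255)
  if (length(dim(img)) == 3) img <- img[, , 1]
  field <- height_field(pts, grid_flag = isTRUE(hdr$grid_flag))
  field <- center_on_apex(field, hdr$apex)  # idempotent for apex (0,0,0)
  eye_record(laterality = hdr$laterality, height = field,
             image = eye_image(img, hdr$cal_h, hdr$cal_v),
             apex = c(0, 0, 0),
             subject_id = hdr$subject_id %||% "", scan_id = hdr$scan_id %||% "",
             meta = c(hdr$meta, list(source = path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_record_mat <- function(path, key_map, laterality) {
  vars <- read_mat5(path)
  need <- c("height", "apex", "image", "cal_h", "cal_v")
  for (role in need) {
    key <- key_map[[role]]
    l3d_assert(!is.null(key), "missing_field",
               paste("key_map lacks a name for role", role))
    l3d_assert(key %in% names(vars), "missing_field",
               paste0("container lacks field \"", key, "\" (role ", role, ")"))
  }
  if (is.null(laterality)) {
    lk <- key_map$laterality
    l3d_assert(!is.null(lk) && lk %in% names(vars), "missing_field",
               "laterality neither given nor present in the container")
    laterality <- tolower(as.character(vars[[lk]]))
    if (laterality %in% c("od", "r")) laterality <- "right"
    if (laterality %in% c("os", "l")) laterality <- "left"
  }
  cal_h <- as.numeric(vars[[key_map$cal_h]])[1]
  cal_v <- as.numeric(vars[[key_map$cal_v]])[1]
  l3d_assert(is_finite_num(cal_h) && cal_h > 0 && is_finite_num(cal_v) &&
               cal_v > 0, "bad_calibration", "calibration must be finite > 0")
  h <- vars[[key_map$height]]
  l3d_assert(is.matrix(h) && ncol(h) == 3, "empty_surface",
             "height field must be an n-by-3 matrix of x,y,z")
  apex <- as.numeric(vars[[key_map$apex]])
  field <- center_on_apex(height_field(h), apex)
  img <- vars[[key_map$image]]
  eye_record(laterality = laterality, height = field,
             image = eye_image(round(img), cal_h, cal_v), apex = c(0, 0, 0),
             meta = list(source = path, key_map = key_map))
}

## ---- contours --------------------------------------------------------------

#' 3D limbus contour
#'
#' One point per meridian: for valid meridians `points` holds
#' `(r cos(theta), r sin(theta), z)` in mm; invalid meridians are flagged,
#' never silently interpolated.
#'
#' @param angle_deg meridian angles in degrees.
#' @param points n-by-3 matrix (mm); rows of invalid meridians are NA.
#' @param valid logical flags.
#' @param quality per-meridian detection prominence (1/mm).
#' @param laterality optional `"right"`/`"left"` tag.
#' @return an object of class `limbus_contour`.
#' @export
limbus_contour <- function(angle_deg, points, valid, quality = NULL,
                           laterality = NULL) {
  points <- as.matrix(points)
  n <- length(angle_deg)
  stopifnot(nrow(points) == n, length(valid) == n)
  if (is.null(quality)) quality <- rep(NA_real_, n)
  colnames(points) <- c("x", "y", "z")
  structure(list(angle_deg = as.numeric(angle_deg), points = points,
                 valid = as.logical(valid), quality = as.numeric(quality),
                 laterality = laterality),
            class = "limbus_contour")
}

#' @export
print.limbus_contour <- function(x, ...) {
  r <- sqrt(x$points[x$valid, 1]^2 + x$points[x$valid, 2]^2)
  cat(sprintf("<limbus_contour> %d meridians, %d valid, radius %.2f-%.2f mm\n",
              length(x$angle_deg), sum(x$valid),
              if (length(r)) min(r) else NA, if (length(r)) max(r) else NA))
  invisible(x)
}

#' White-to-white contour
#'
#' Per-degree polar radii of the visible iris boundary about its centre.
#'
#' @param center boundary-mask centroid `(x, y)` in surface mm.
#' @param radius_mm 360 positive radii, one per integer degree 0..359.
#' @param laterality `"right"` or `"left"`.
#' @return an object of class `wtw_contour`.
#' @export
wtw_contour <- function(center, radius_mm, laterality = NULL) {
  l3d_assert(length(radius_mm) == 360 && all(is.finite(radius_mm)) &&
               all(radius_mm > 0), "bad_contour",
             "radius_mm must be 360 finite positive values")
  structure(list(center = as.numeric(center), radius_mm = as.numeric(radius_mm),
                 laterality = laterality),
            class = "wtw_contour")
}

#' @export
print.wtw_contour <- function(x, ...) {
  cat(sprintf("<wtw_contour> centre (%.2f, %.2f) mm, radius %.2f-%.2f mm\n",
              x$center[1], x$center[2], min(x$radius_mm), max(x$radius_mm)))
  invisible(x)
}

#' Write a contour to CSV
#'
#' Limbus contours use columns `angle_deg,x_mm,y_mm,z_mm,valid`; WTW
#' contours use `angle_deg,radius_mm`.  Centre and laterality are kept in
#' `#`-prefixed header comments so the round trip is lossless.
#'
#' @param contour a [limbus_contour()] or [wtw_contour()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(contour, "limbus_contour")) {
    if (!is.null(contour$laterality)) {
      writeLines(paste0("# laterality: ", contour$laterality), con)
    }
    df <- data.frame(angle_deg = contour$angle_deg,
                     x_mm = contour$points[, 1], y_mm = contour$points[, 2],
                     z_mm = contour$points[, 3],
                     valid = as.integer(contour$valid))
    write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, quote = FALSE)
  } else if (inherits(contour, "wtw_contour")) {
    writeLines(sprintf("# center_mm: %.17g %.17g",
                       contour$center[1], contour$center[2]), con)
    if (!is.null(contour$laterality)) {
      writeLines(paste0("# laterality: ", contour$laterality), con)
    }
    df <- data.frame(angle_deg = 0:359, radius_mm = contour$radius_mm)
    write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, quote = FALSE)
  } else {
    l3d_error("schema_mismatch", "not a contour object")
  }
  invisible(path)
}

#' Read a contour CSV written by [write_contour()]
#'
#' @param path CSV path.
#' @return a [limbus_contour()] or [wtw_contour()], auto-detected from the
#'   column schema.
#' @export
read_contour <- function(path) {
  l3d_assert(file.exists(path), "io_failure", paste(path, "does not exist"))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- read.csv(text = lines[!grepl("^#", lines)])
  lat <- sub("^# laterality: ", "", grep("^# laterality:", hdr, value = TRUE))
  if (length(lat) == 0) lat <- NULL
  if (identical(names(df), c("angle_deg", "x_mm", "y_mm", "z_mm", "valid"))) {
    limbus_contour(df$angle_deg, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
                   valid = df$valid == 1, laterality = lat)
  } else if (identical(names(df), c("angle_deg", "radius_mm"))) {
    cl <- grep("^# center_mm:", hdr, value = TRUE)
    center <- if (length(cl)) {
      as.numeric(strsplit(sub("^# center_mm: ", "", cl), " ")[[1]])
    } else c(0, 0)
    wtw_contour(center, df$radius_mm, laterality = lat)
  } else {
    l3d_error("schema_mismatch",
              paste("unrecognised contour schema:", paste(names(df), collapse = ",")))
  }
}
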