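# Independent oracles and fixture builders used across the suite.
# Fixtures are generated in code at test time; nothing binary is stored.

# Closed-form sag of a sphere of radius R (mm)
sphere_sag <- function(r, R) R - sqrt(R^2 - r^2)

# Brute-force limbus oracle: argmin of second-order central differences of
# the *analytic* sag at a fine step, restricted to the search window.
# Independent of the Savitzky-Golay path it cross-checks.
brute_force_limbus <- function(truth, angle_deg, window = c(4.5, 8.5),
                               step = 0.001) {
  r <- seq(0, window[2] + 0.5, by = step)
  s <- make_meridian_sag(truth, angle_deg, r)$s
  d2 <- diff(s, differences = 2) / step^2
  rc <- r[-c(1, length(r))]
  sel <- rc >= window[1] & rc <= window[2]
  rc[sel][which.min(d2[sel])]
}

# MAT v5 fixture written by the independent scipy implementation through the
# system python; returns the .mat path (NULL if python is unusable, which
# the calling test treats as a hard failure since the toolchain provides it)
write_scipy_mat <- function(dir, height, apex = c(0, 0, 0), compress = FALSE) {
  hcsv <- file.path(dir, "h.csv")
  utils::write.csv(as.data.frame(height), hcsv, row.names = FALSE)
  py <- file.path(dir, "gen.py")
  out <- file.path(dir, "fixture.mat")
  writeLines(c(
    "import scipy.io, numpy, pandas, sys",
    sprintf("h = pandas.read_csv(%s).values", deparse(hcsv)),
    "img = numpy.arange(64 * 80, dtype=numpy.uint8).reshape(64, 80) % 255",
    sprintf("apex = numpy.array(%s)", paste0("[", paste(apex, collapse = ","), "]")),
    sprintf(paste0("scipy.io.savemat(%s, {'height': h, 'apex': apex, ",
                   "'image': img, 'cal_h': 0.02, 'cal_v': 0.02, ",
                   "'laterality': 'right'}, do_compression=%s)"),
            deparse(out), if (compress) "True" else "False")
  ), py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)
  out
}

# small planar ring contour helper
ring_contour <- function(radius = 6.8, z = 0, n = 360, laterality = NULL) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  z <- rep_len(z, n)
  limbus_contour((seq_len(n) - 1) * 360 / n,
                 cbind(radius * cos(th), radius * sin(th), z),
                 valid = rep(TRUE, n), laterality = laterality)
}
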