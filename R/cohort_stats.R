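## Cohort summaries and significance tests.
##
## Per-eye geometry reports aggregate into mean +/- STD and min : max
## summaries per laterality and orientation, with pooled-variance
## two-sample t-tests between pairs of groups (the classical clinical
## default; Welch available by flag).  p is two-sided.

#' Summary statistics of a set of values
#'
#' @param values finite numeric values, n >= 1.
#' @param unit unit label carried on the result.
#' @return an object of class `summary_stats` with `n`, `mean`, `std`
#'   (sample SD, defined as 0 for n = 1), `min`, `max`, `unit`.
#' @export
summarize_values <- function(values, unit = "") {
  if (length(values) == 0) l3d_error("empty_input", "no values to summarize")
  l3d_assert(all(is.finite(values)), "empty_input", "values must be finite")
  structure(list(n = length(values), mean = mean(values),
                 std = if (length(values) > 1) sd(values) else 0,
                 min = min(values), max = max(values), unit = unit),
            class = "summary_stats")
}

#' Format a summary as the conventional table strings
#'
#' @param x a `summary_stats`.
#' @param ... unused.
#' @return character vector `c("mean +/- std", "min : max")`, 2 decimals.
#' @export
format.summary_stats <- function(x, ...) {
  c(sprintf("%.2f ± %.2f", x$mean, x$std),
    sprintf("%.2f : %.2f", x$min, x$max))
}

#' @export
print.summary_stats <- function(x, ...) {
  f <- format(x)
  cat(sprintf("<summary_stats> n=%d  %s  %s %s\n", x$n, f[1], f[2], x$unit))
  invisible(x)
}

#' Two-sample t-test
#'
#' Pooled-variance Student's t by default (df = n_a + n_b - 2), two-sided
#' p from the t distribution; `welch = TRUE` switches to the
#' unequal-variance form.  Degenerate zero-variance input is resolved by
#' the limits: equal-mean constant samples give t = 0, p = 1.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param welch use the Welch approximation instead of pooling.
#' @return an object of class `t_test_result` with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    l3d_error("too_few_observations", "each sample needs at least 2 values")
  }
  l3d_assert(all(is.finite(a)) && all(is.finite(b)), "too_few_observations",
             "samples must be finite")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
    } else {
      res <- list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(res, class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test> t = %.4f, df = %.4g, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Cohort table of per-eye geometry results
#'
#' Aggregates a cohort of per-eye reports into the standard layout: one
#' summary per metric x orientation x laterality, plus pairwise
#' pooled-t p-values (nasal-temporal vs superior-inferior within each
#' side, and right vs left within each orientation).
#'
#' @param reports a list of [eye_report()]s (or a data.frame with a
#'   `laterality` column and numeric metric columns).
#' @param metrics named list mapping display metric names to pairs of
#'   report fields `(NT-like, SI-like)`; the default covers limbus
#'   diameters, white-to-white distances and their difference.
#' @return list with `summary` (a data.frame of cells) and `p_values`
#'   (a data.frame of the pairwise tests).
#' @export
cohort_table <- function(reports,
                         metrics = list(
                           limbus = c("limbus_nt_mm", "limbus_si_mm"),
                           wtw = c("wtw_nt_mm", "wtw_si_mm"))) {
  df <- if (is.data.frame(reports)) reports else {
    do.call(rbind, lapply(reports, function(r) as.data.frame(r[lengths(r) == 1])))
  }
  l3d_assert(!is.null(df$laterality), "empty_group", "reports lack laterality")
  cells <- list(); pv <- list()
  for (side in c("right", "left")) {
    sub <- df[df$laterality == side, , drop = FALSE]
    if (nrow(sub) == 0) {
      l3d_error("empty_group", paste("no", side, "eyes in the cohort"))
    }
    for (mname in names(metrics)) {
      cols <- metrics[[mname]]
      for (k in 1:2) {
        orient <- c("NT", "SI")[k]
        s <- summarize_values(sub[[cols[k]]], "mm")
        f <- format(s)
        cells[[length(cells) + 1L]] <- data.frame(
          metric = mname, orientation = orient, side = side, n = s$n,
          mean = s$mean, std = s$std, min = s$min, max = s$max,
          mean_std = f[1], min_max = f[2])
      }
      if (nrow(sub) >= 2) {
        tt <- two_sample_t(sub[[cols[1]]], sub[[cols[2]]])
        pv[[length(pv) + 1L]] <- data.frame(
          metric = mname, comparison = "NT vs SI", side = side, p = tt$p)
      }
    }
  }
  right <- df[df$laterality == "right", , drop = FALSE]
  left <- df[df$laterality == "left", , drop = FALSE]
  for (mname in names(metrics)) {
    cols <- metrics[[mname]]
    for (k in 1:2) {
      if (nrow(right) >= 2 && nrow(left) >= 2) {
        tt <- two_sample_t(right[[cols[k]]], left[[cols[k]]])
        pv[[length(pv) + 1L]] <- data.frame(
          metric = mname, comparison = "right vs left",
          side = c("NT", "SI")[k], p = tt$p)
      }
    }
  }
  list(summary = do.call(rbind, cells), p_values = do.call(rbind, pv))
}

#' Write a cohort table to CSV
#'
#' @param table result of [cohort_table()].
#' @param path output path; p-values go to a sibling `*_pvalues.csv`.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  write.csv(table$summary, path, row.names = FALSE)
  write.csv(table$p_values,
            sub("\\.csv$", "_pvalues.csv", path), row.names = FALSE)
  invisible(path)
}
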