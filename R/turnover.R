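#' Mean intensities over Z-disc and sarcomere-body regions of interest
#'
#' Z-disc ROIs are axis-aligned rectangles (the narrow bright bands); body
#' ROIs are polygons covering the sarcomere body between Z-discs. Pixels from
#' all ROIs of a class are pooled and averaged.
#'
#' @param image Numeric matrix; pixel centers at `(index - 1) * pixel_size`.
#' @param z_rois List of length-4 numeric vectors `c(x0, y0, x1, y1)`, um.
#' @param body_rois List of polygons (n x 2 matrices of x, y in um).
#' @param pixel_size Um per pixel; defaults to the image attribute.
#' @return List with `z` and `body` mean intensities, a.u.
#' @export
quantify_rois <- function(image, z_rois, body_rois,
                          pixel_size = attr(image, "pixel_size")) {
  stopifnot(is.matrix(image))
  if (is.null(pixel_size)) stop("pixel_size is required")
  xs <- (seq_len(ncol(image)) - 1L) * pixel_size
  ys <- (seq_len(nrow(image)) - 1L) * pixel_size
  rect_pixels <- function(r) {
    stopifnot(length(r) == 4)
    if (r[1] < min(xs) - 1e-9 || r[3] > max(xs) + 1e-9 ||
        r[2] < min(ys) - 1e-9 || r[4] > max(ys) + 1e-9) {
      stop("ROI outside image bounds")
    }
    jj <- which(xs >= r[1] & xs <= r[3])
    ii <- which(ys >= r[2] & ys <= r[4])
    if (!length(jj) || !length(ii)) stop("empty ROI")
    as.numeric(image[ii, jj])
  }
  poly_pixels <- function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 3) stop("polygon ROI needs at least 3 vertices")
    if (min(p[, 1]) < min(xs) - 1e-9 || max(p[, 1]) > max(xs) + 1e-9 ||
        min(p[, 2]) < min(ys) - 1e-9 || max(p[, 2]) > max(ys) + 1e-9) {
      stop("ROI outside image bounds")
    }
    jj <- which(xs >= min(p[, 1]) & xs <= max(p[, 1]))
    ii <- which(ys >= min(p[, 2]) & ys <= max(p[, 2]))
    vals <- c()
    for (i in ii) {
      inside <- vapply(jj, function(j) point_in_polygon(xs[j], ys[i], p), TRUE)
      vals <- c(vals, image[i, jj[inside]])
    }
    if (!length(vals)) stop("empty ROI")
    vals
  }
  z_vals <- unlist(lapply(z_rois, rect_pixels))
  body_vals <- unlist(lapply(body_rois, poly_pixels))
  list(z = mean(z_vals), body = mean(body_vals))
}

# Ray-crossing point-in-polygon test (boundary counts as inside).
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y)) {
      xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
      if (x < xint + 1e-12) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Z-disc to sarcomere-body intensity ratio
#'
#' @param z Mean Z-disc intensity, a.u.
#' @param body Mean sarcomere-body intensity, a.u. (> 0).
#' @return The ratio `z / body`; `NA` with a warning when `body` is 0.
#' @export
zbody_ratio <- function(z, body) {
  if (body == 0) {
    warning("body intensity is zero: ratio undefined")
    return(NA_real_)
  }
  z / body
}

#' Detect the incorporation onset in a pulse-chase series
#'
#' The onset is the earliest timepoint whose mean Z-disc intensity exceeds the
#' first-timepoint baseline by a one-sided two-sample t-test at `alpha`, with
#' every later pre-peak timepoint also significant (a sustained rise, robust
#' to single-timepoint noise).
#'
#' @param series A [pulse_chase_series()].
#' @param alpha One-sided significance level.
#' @return Onset time in hours, or `NA` when no sustained rise is found.
#' @export
detect_onset <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "pulse_chase_series"))
  k <- length(series$timepoints)
  if (k < 2) stop("need at least two timepoints")
  sizes <- vapply(series$z_intensity, length, 1L)
  if (any(sizes < 2)) stop("need at least two samples per timepoint")
  base <- series$z_intensity[[1]]
  sig <- vapply(2:k, function(i) {
    samp <- series$z_intensity[[i]]
    if (stats::sd(samp) == 0 && stats::sd(base) == 0) {
      return(mean(samp) > mean(base))
    }
    ht <- stats::t.test(samp, base, alternative = "greater")
    ht$p.value < alpha
  }, TRUE)
  peak_idx <- detect_peak_index(series)
  for (i in 2:k) {
    upto <- seq(i, max(i, peak_idx))
    upto <- upto[upto <= k]
    if (all(sig[upto - 1L])) {
      return(series$timepoints[i])
    }
  }
  NA_real_
}

detect_peak_index <- function(series) {
  means <- vapply(series$z_intensity, mean, 1.0)
  which.max(means) # which.max returns the earliest maximum on ties
}

#' Timepoint of maximal mean Z-disc intensity
#'
#' @param series A [pulse_chase_series()] with at least three timepoints.
#' @return Peak time, hours (ties resolved to the earliest timepoint).
#' @export
detect_peak <- function(series) {
  stopifnot(inherits(series, "pulse_chase_series"))
  if (length(series$timepoints) < 3) stop("need at least three timepoints")
  series$timepoints[detect_peak_index(series)]
}

#' Post-peak decay half-life
#'
#' Fits `log(mean - baseline)` against time by least squares over the
#' timepoints after the detected peak (baseline = mean intensity at the first
#' timepoint, a single-exponential decay assumption). The half-life is
#' `ln 2 / |slope|`; a non-negative slope (no decay, e.g. a stable label)
#' yields `NA`.
#'
#' @param series A [pulse_chase_series()].
#' @param min_points Minimum number of usable post-peak timepoints.
#' @return Half-life in hours, or `NA`.
#' @export
estimate_halflife <- function(series, min_points = 3) {
  stopifnot(inherits(series, "pulse_chase_series"))
  means <- vapply(series$z_intensity, mean, 1.0)
  baseline <- means[1]
  peak_idx <- detect_peak_index(series)
  post <- which(seq_along(means) > peak_idx & means > baseline)
  if (length(post) < min_points) return(NA_real_)
  t <- series$timepoints[post]
  ly <- log(means[post] - baseline)
  slope <- stats::coef(stats::lm(ly ~ t))[["t"]]
  if (slope >= 0) return(NA_real_)
  log(2) / abs(slope)
}

#' Summarize a pulse-chase turnover experiment
#'
#' @param series A [pulse_chase_series()].
#' @param alpha Significance level for onset detection.
#' @return Object of class `turnover_summary`: `onset`, `peak_time`,
#'   `halflife` (hours; `NA` where undefined) and `ratio_series`, a data frame
#'   of the per-timepoint Z-disc / body ratio mean and sem.
#' @export
summarize_turnover <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "pulse_chase_series"))
  ratio <- lapply(seq_along(series$timepoints), function(i) {
    z <- series$z_intensity[[i]]
    b <- series$body_intensity[[i]]
    r <- z[b > 0] / b[b > 0]
    n <- length(r)
    data.frame(
      timepoint_h = series$timepoints[i],
      ratio_mean = if (n) mean(r) else NA_real_,
      ratio_sem = if (n > 1) stats::sd(r) / sqrt(n) else NA_real_,
      n = n
    )
  })
  onset <- detect_onset(series, alpha)
  peak <- detect_peak(series)
  structure(
    list(onset = onset, peak_time = peak,
         halflife = estimate_halflife(series),
         ratio_series = do.call(rbind, ratio), label = series$label),
    class = "turnover_summary"
  )
}

#' @export
print.turnover_summary <- function(x, ...) {
  cat(sprintf("Turnover summary '%s':\n", x$label))
  cat(sprintf("  onset: %s h, peak: %g h, half-life: %s h\n",
              ifelse(is.na(x$onset), "none", format(x$onset)), x$peak_time,
              ifelse(is.na(x$halflife), "none (no decay)",
                     format(signif(x$halflife, 4)))))
  invisible(x)
}
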