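#' Extract an intensity profile along a polyline in an image
#'
#' Re-implements the standard line-profile measurement: the image is sampled
#' at `pixel_size` steps along the polyline, and at each step the intensity is
#' averaged over `width_px` bilinear samples perpendicular to the line.
#'
#' @param image Numeric matrix (rows = y, columns = x); pixel centers at
#'   `(index - 1) * pixel_size` um. If the matrix carries a `pixel_size`
#'   attribute (as images from [gen_striation_image()] do) it is used unless
#'   overridden.
#' @param polyline Numeric matrix with two columns (x, y) in um; at least two
#'   distinct points.
#' @param width_px Averaging width perpendicular to the line, pixels (>= 1).
#' @param pixel_size Um per pixel; defaults to the image attribute.
#' @param channel Channel tag for the resulting profile.
#' @return An [intensity_profile()].
#' @export
extract_line_profile <- function(image, polyline, width_px = 1,
                                 pixel_size = attr(image, "pixel_size"),
                                 channel = "phalloidin") {
  stopifnot(is.matrix(image), is.numeric(image))
  if (is.null(pixel_size)) stop("pixel_size is required")
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2 || ncol(polyline) != 2) {
    stop("polyline must be an n x 2 matrix of (x, y) points")
  }
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) <= 0) stop("degenerate (zero-length) polyline")
  ps <- pixel_size
  total <- sum(seg_len)
  s <- seq(0, total, by = ps)
  cum <- c(0, cumsum(seg_len))
  # point and unit direction at each arc-length position
  pts <- matrix(0, nrow = length(s), ncol = 2)
  dirs <- matrix(0, nrow = length(s), ncol = 2)
  for (i in seq_along(s)) {
    j <- max(which(cum <= s[i] + 1e-12 & cum < total))
    f <- (s[i] - cum[j]) / seg_len[j]
    pts[i, ] <- polyline[j, ] + f * seg[j, ]
    dirs[i, ] <- seg[j, ] / seg_len[j]
  }
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * ps
  vals <- vapply(seq_along(s), function(i) {
    perp <- c(-dirs[i, 2], dirs[i, 1])
    mean(vapply(offs, function(o) {
      bilinear_at(image, pts[i, 1] + o * perp[1], pts[i, 2] + o * perp[2], ps)
    }, 1.0))
  }, 1.0)
  intensity_profile(s, pmax(vals, 0), ps, channel)
}

# Bilinear interpolation at (x, y) um; errors outside the pixel-center grid.
bilinear_at <- function(image, x, y, pixel_size) {
  cx <- x / pixel_size # 0-based pixel-center coordinates
  cy <- y / pixel_size
  nx <- ncol(image)
  ny <- nrow(image)
  if (cx < -1e-9 || cx > nx - 1 + 1e-9 || cy < -1e-9 || cy > ny - 1 + 1e-9) {
    stop("sample point outside image bounds")
  }
  cx <- min(max(cx, 0), nx - 1)
  cy <- min(max(cy, 0), ny - 1)
  j0 <- floor(cx); i0 <- floor(cy)
  j1 <- min(j0 + 1, nx - 1); i1 <- min(i0 + 1, ny - 1)
  fx <- cx - j0; fy <- cy - i0
  (1 - fy) * ((1 - fx) * image[i0 + 1, j0 + 1] + fx * image[i0 + 1, j1 + 1]) +
    fy * ((1 - fx) * image[i1 + 1, j0 + 1] + fx * image[i1 + 1, j1 + 1])
}

# Local maxima of y with topographic prominence >= min_prom (absolute units).
# Returns integer indices.
find_peaks <- function(y, min_prom) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    v <- y[i]
    # walk left until terrain exceeds the peak (or the boundary)
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > v)
    lbase <- if (length(higher_l)) min(left[(max(higher_l)):(i - 1)]) else min(left)
    right <- y[(i + 1):n]
    higher_r <- which(right > v)
    rbase <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    (v - max(lbase, rbase)) >= min_prom
  }, TRUE)
  cand[keep]
}

# Sub-pixel refinement of a local extremum by parabolic interpolation.
parabolic_offset <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(min(off, 0.5), -0.5)
}

#' Detect Z-disc positions in a phalloidin profile
#'
#' Smooths the profile with a Gaussian kernel, finds local maxima whose
#' topographic prominence exceeds `min_prominence` of the smoothed dynamic
#' range, and refines each to sub-pixel precision by parabolic interpolation.
#'
#' @param profile An [intensity_profile()] (phalloidin channel).
#' @param smooth_sigma Smoothing sigma, um; defaults to one pixel.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   smoothed profile's dynamic range.
#' @return Sorted numeric vector of peak positions, um. Fewer than two
#'   detected peaks is a no-measurement outcome, reported as a short (possibly
#'   empty) vector, not an error.
#' @export
detect_z_discs <- function(profile, smooth_sigma = NULL,
                           min_prominence = 0.2) {
  stopifnot(inherits(profile, "intensity_profile"))
  ps <- profile$pixel_size
  sigma_px <- (smooth_sigma %||% ps) / ps
  ys <- gaussian_smooth(profile$intensities, sigma_px)
  rng <- diff(range(ys))
  if (rng <= 0) return(numeric(0))
  idx <- find_peaks(ys, min_prom = min_prominence * rng)
  pos <- vapply(idx, function(i) {
    profile$positions[i] + parabolic_offset(ys, i) * ps
  }, 1.0)
  sort(pos)
}

#' Detect M-line positions
#'
#' In the obscurin channel M-lines are bright and are detected exactly like
#' Z-discs. In the phalloidin channel M-lines are the dark mid-sarcomere
#' troughs: Z-discs are detected first and the deepest point between each
#' adjacent Z-disc pair is refined to sub-pixel precision.
#'
#' @inheritParams detect_z_discs
#' @return Sorted numeric vector of M-line positions, um (possibly short when
#'   detection fails; not an error).
#' @export
detect_m_lines <- function(profile, smooth_sigma = NULL,
                           min_prominence = 0.2) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (profile$channel == "obscurin") {
    return(detect_z_discs(profile, smooth_sigma, min_prominence))
  }
  ps <- profile$pixel_size
  z <- detect_z_discs(profile, smooth_sigma, min_prominence)
  if (length(z) < 2) return(numeric(0))
  sigma_px <- (smooth_sigma %||% ps) / ps
  ys <- gaussian_smooth(profile$intensities, sigma_px)
  pos <- profile$positions
  m <- vapply(seq_len(length(z) - 1), function(k) {
    in_seg <- which(pos > z[k] & pos < z[k + 1])
    if (length(in_seg) < 3) return(NA_real_)
    i <- in_seg[which.min(ys[in_seg])]
    pos[i] + parabolic_offset(-ys, i) * ps
  }, 1.0)
  sort(m[!is.na(m)])
}

#' Sarcomere lengths from consecutive landmark positions
#'
#' Consecutive differences of sorted Z-disc (or M-line) positions.
#'
#' @param positions Sorted landmark positions, um.
#' @param min_n Minimum number of intervals required for a measurement.
#' @return Numeric vector of lengths, or `NULL` (no-measurement) when fewer
#'   than `min_n` intervals are available.
#' @export
measure_sarcomere_lengths <- function(positions, min_n = 1) {
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (length(positions) < 2) return(NULL)
  lengths <- diff(positions)
  if (length(lengths) < min_n) return(NULL)
  lengths
}

#' Thin-filament length and H-zone width within one sarcomere
#'
#' Within the sarcomere bounded by the adjacent Z-disc pair `z_pair`, the
#' intensity is normalized between the H-zone minimum and the thin-filament
#' plateau level (median intensity over the plateau regions). On each side of
#' the H-zone, the position where the descending slope crosses 50% of that
#' range is found by linear sub-pixel interpolation. Thin-filament length is
#' the mean distance from each crossing to its nearer Z-disc; H-zone width is
#' the distance between the two crossings.
#'
#' @param profile An [intensity_profile()] (phalloidin channel).
#' @param z_pair Numeric length-2: positions of two adjacent detected
#'   Z-discs, um.
#' @param degenerate_depth Minimum trough depth, as a fraction of the plateau
#'   level, below which the sarcomere is treated as having no resolvable
#'   H-zone.
#' @return List with `thin_filament_length`, `h_zone_width` (um) and a
#'   logical `degenerate` flag. When no interior trough is resolvable,
#'   `h_zone_width = 0` and `thin_filament_length = SL / 2` with
#'   `degenerate = TRUE`.
#' @export
measure_thin_filament_length <- function(profile, z_pair,
                                         degenerate_depth = 0.02) {
  stopifnot(inherits(profile, "intensity_profile"), length(z_pair) == 2)
  z_pair <- sort(z_pair)
  sl <- diff(z_pair)
  if (sl <= 4 * profile$pixel_size) {
    stop("z_pair too close to be adjacent Z-discs")
  }
  pos <- profile$positions
  y <- profile$intensities
  in_seg <- which(pos >= z_pair[1] & pos <= z_pair[2])
  if (length(in_seg) < 8) stop("too few samples between the Z-disc pair")
  sp <- pos[in_seg]
  sy <- y[in_seg]
  frac <- (sp - z_pair[1]) / sl
  # plateau level: median over the quarter-regions well clear of both the
  # Z-disc peaks and the H-zone
  plateau_sel <- (frac >= 0.15 & frac <= 0.35) | (frac >= 0.65 & frac <= 0.85)
  plateau <- stats::median(sy[plateau_sel])
  # H-zone minimum: central half of the sarcomere
  central <- which(frac >= 0.25 & frac <= 0.75)
  i_min <- central[which.min(sy[central])]
  h_min <- sy[i_min]
  if (!is.finite(plateau) || (plateau - h_min) <= degenerate_depth * plateau) {
    return(list(thin_filament_length = sl / 2, h_zone_width = 0,
                degenerate = TRUE))
  }
  u <- (sy - h_min) / (plateau - h_min)
  cross <- function(side) {
    if (side == "left") {
      above <- which(u[seq_len(i_min)] >= 0.5)
      if (!length(above)) return(NA_real_)
      j <- max(above) # last sample at/above half before the trough
      if (j == i_min) return(sp[j])
      f <- (u[j] - 0.5) / (u[j] - u[j + 1])
      sp[j] + f * (sp[j + 1] - sp[j])
    } else {
      above <- which(u >= 0.5 & seq_along(u) > i_min)
      if (!length(above)) return(NA_real_)
      j <- min(above)
      if (j == i_min) return(sp[j])
      f <- (u[j] - 0.5) / (u[j] - u[j - 1])
      sp[j] - f * (sp[j] - sp[j - 1])
    }
  }
  xl <- cross("left")
  xr <- cross("right")
  if (is.na(xl) || is.na(xr) || xr <= xl) {
    return(list(thin_filament_length = sl / 2, h_zone_width = 0,
                degenerate = TRUE))
  }
  tfl <- mean(c(xl - z_pair[1], z_pair[2] - xr))
  list(thin_filament_length = tfl, h_zone_width = xr - xl, degenerate = FALSE)
}

#' Measure all sarcomeric parameters in one profile
#'
#' Detects Z-discs and, for each adjacent pair, measures sarcomere length,
#' thin-filament length and H-zone width.
#'
#' @inheritParams detect_z_discs
#' @param id,genotype,day Metadata attached to every row.
#' @return Data frame with one row per sarcomere (`sl_um`, `tfl_um`, `hz_um`,
#'   `degenerate`, plus metadata), or `NULL` when fewer than two Z-discs are
#'   found.
#' @export
measure_striation <- function(profile, smooth_sigma = NULL,
                              min_prominence = 0.2, id = NA_character_,
                              genotype = NA_character_, day = NA_real_) {
  z <- detect_z_discs(profile, smooth_sigma, min_prominence)
  if (length(z) < 2) return(NULL)
  rows <- lapply(seq_len(length(z) - 1), function(k) {
    tf <- measure_thin_filament_length(profile, z[c(k, k + 1)])
    data.frame(
      id = id, genotype = genotype, day = day,
      sl_um = z[k + 1] - z[k],
      tfl_um = tf$thin_filament_length,
      hz_um = tf$h_zone_width,
      degenerate = tf$degenerate
    )
  })
  do.call(rbind, rows)
}

#' Group summary statistics
#'
#' @param values Numeric measurements (n >= 1).
#' @return List with `n`, `mean`, `sd`, `sem` and a `single_value` flag; for
#'   n = 1 the sd is undefined and reported as 0 with the flag set.
#' @export
summarize_group <- function(values) {
  if (length(values) == 0) stop("empty input")
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else 0
  list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n),
       single_value = n == 1)
}

#' Two-sample comparison with figure-style star codes
#'
#' Two-sided Student's t-test (equal variance by default; set
#' `welch = TRUE` for the unequal-variance form) with the star convention of
#' [star_code()].
#'
#' @param a,b Numeric vectors, each with at least two values.
#' @param welch Use the Welch unequal-variance test.
#' @return List of class `group_comparison`: `statistic` (t), `df`,
#'   `p_value`, `stars`, `method`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two values")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, stars = star_code(ht$p.value),
         method = ht$method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.4g (%s)\n",
              x$method, x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Percent change between two measurements
#'
#' `100 * (after - before) / before`; the sign carries the direction.
#'
#' @param before Reference value (> 0).
#' @param after Comparison value.
#' @return Percent change (not rounded; round at report time to match the
#'   precision wanted).
#' @export
#' @examples
#' percent_change(3.41, 3.76) # +10.26...
percent_change <- function(before, after) {
  if (!is.finite(before) || before <= 0) stop("'before' must be positive")
  100 * (after - before) / before
}
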