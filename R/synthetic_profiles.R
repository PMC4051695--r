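#' Ground-truth sarcomere geometry for profile synthesis
#'
#' Describes one striated-myofibril geometry: the sarcomere period, the length
#' of the two thin-filament arrays, the actin-free H-zone between them, the
#' Z-disc peak, and the imaging parameters (point-spread blur and pixel size).
#' The identity `sarcomere_length = 2 * thin_filament_length + h_zone_width`
#' holds exactly by construction: supply any two of the three lengths (or all
#' three, which are checked for consistency).
#'
#' Default levels describe a typical phalloidin profile: a bright Z-disc peak,
#' a thin-filament plateau, a dark H-zone trough, and a low background.
#'
#' @param sarcomere_length Z-disc to Z-disc period, um.
#' @param thin_filament_length Z-disc center to end of the thin-filament
#'   array, um.
#' @param h_zone_width Actin-free gap between the two arrays, um (may be 0).
#' @param z_disc_width Full width at half maximum of the Z-disc peak, um.
#' @param z_peak_level,filament_level,h_zone_level,background Intensity levels
#'   (arbitrary units); must satisfy
#'   `z_peak_level > filament_level > h_zone_level >= background >= 0`.
#' @param psf_sigma Gaussian point-spread standard deviation, um.
#' @param pixel_size Sampling interval, um per pixel.
#' @return An object of class `striation_truth` (a named list).
#' @export
#' @examples
#' tr <- striation_truth(thin_filament_length = 1.60, h_zone_width = 0.16)
#' tr$sarcomere_length  # 3.36
striation_truth <- function(sarcomere_length = NULL,
                            thin_filament_length = NULL,
                            h_zone_width = 0.16,
                            z_disc_width = 0.25,
                            z_peak_level = 1.0,
                            filament_level = 0.55,
                            h_zone_level = 0.15,
                            background = 0.05,
                            psf_sigma = 0.05,
                            pixel_size = 0.05) {
  if (is.null(sarcomere_length) && is.null(thin_filament_length)) {
    thin_filament_length <- 1.60
  }
  if (is.null(sarcomere_length)) {
    sarcomere_length <- 2 * thin_filament_length + h_zone_width
  } else if (is.null(thin_filament_length)) {
    thin_filament_length <- (sarcomere_length - h_zone_width) / 2
  } else if (abs(sarcomere_length -
                 (2 * thin_filament_length + h_zone_width)) > 1e-12) {
    stop("sarcomere_length must equal 2 * thin_filament_length + h_zone_width")
  }
  stopifnot(
    sarcomere_length > 0, thin_filament_length > 0, h_zone_width >= 0,
    z_disc_width > 0, pixel_size > 0, psf_sigma >= 0
  )
  if (!(z_peak_level > filament_level &&
        filament_level > h_zone_level &&
        h_zone_level >= background && background >= 0)) {
    stop("levels must satisfy z_peak > filament > h_zone >= background >= 0")
  }
  structure(
    list(
      sarcomere_length = sarcomere_length,
      thin_filament_length = thin_filament_length,
      h_zone_width = h_zone_width,
      z_disc_width = z_disc_width,
      z_peak_level = z_peak_level,
      filament_level = filament_level,
      h_zone_level = h_zone_level,
      background = background,
      psf_sigma = psf_sigma,
      pixel_size = pixel_size
    ),
    class = "striation_truth"
  )
}

#' @export
print.striation_truth <- function(x, ...) {
  cat(sprintf(
    "Striation truth: SL %.3f um = 2 x TFL %.3f + HZ %.3f; Z-disc FWHM %.3f um\n",
    x$sarcomere_length, x$thin_filament_length, x$h_zone_width, x$z_disc_width
  ))
  cat(sprintf(
    "  levels (a.u.): Z %.3g / filament %.3g / H-zone %.3g / background %.3g\n",
    x$z_peak_level, x$filament_level, x$h_zone_level, x$background
  ))
  cat(sprintf("  psf sigma %.3f um, pixel %.3f um\n", x$psf_sigma, x$pixel_size))
  invisible(x)
}

#' Calibrated one-dimensional fluorescence intensity profile
#'
#' @param positions Positions along the myofibril axis, um; strictly
#'   increasing and uniformly spaced.
#' @param intensities Non-negative intensities, arbitrary units.
#' @param pixel_size Sampling interval, um per pixel.
#' @param channel One of `"phalloidin"`, `"obscurin"`, `"gfp"`.
#' @return Object of class `intensity_profile`: a list with fields
#'   `positions`, `intensities`, `pixel_size`, `channel`.
#' @export
intensity_profile <- function(positions, intensities, pixel_size,
                              channel = c("phalloidin", "obscurin", "gfp")) {
  channel <- match.arg(channel)
  stopifnot(
    is.numeric(positions), is.numeric(intensities),
    length(positions) == length(intensities),
    length(positions) >= 16L,
    pixel_size > 0,
    all(intensities >= 0)
  )
  dp <- diff(positions)
  if (any(dp <= 0) || max(abs(dp - pixel_size)) > 1e-9) {
    stop("positions must increase uniformly by pixel_size (within 1e-9 um)")
  }
  structure(
    list(
      positions = as.numeric(positions),
      intensities = as.numeric(intensities),
      pixel_size = pixel_size,
      channel = channel
    ),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "Intensity profile (%s): %d px over %.2f um, pixel %.3f um\n",
    x$channel, length(x$positions),
    x$positions[length(x$positions)] - x$positions[1], x$pixel_size
  ))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  plot(x$positions, x$intensities, type = "l",
       xlab = "position (um)", ylab = "intensity (a.u.)",
       main = paste0(x$channel, " profile"), ...)
  invisible(x)
}

# Continuous noise-free phalloidin template at positions x (um).
# The myofibril is periodic across the whole sampled window (the margins
# contain the continuation of the fibril, so every recorded Z-disc is
# interior and unbiased): thin-filament plateaus tile each period with an
# H-zone trough centered mid-period, and Gaussian Z peaks sit at every
# period boundary, including those in the margins.
striation_template <- function(x, truth, z_positions) {
  sl <- truth$sarcomere_length
  tfl <- truth$thin_filament_length
  x0 <- z_positions[1]
  phase <- (x - x0) %% sl
  on_filament <- phase <= tfl | phase >= sl - tfl
  y <- ifelse(on_filament, truth$filament_level, truth$h_zone_level)
  sigma_z <- truth$z_disc_width / (2 * sqrt(2 * log(2)))
  amp <- truth$z_peak_level - truth$filament_level
  # periodic peaks: cover every boundary within (and just beyond) the range
  k_lo <- floor((min(x) - x0) / sl) - 1
  k_hi <- ceiling((max(x) - x0) / sl) + 1
  for (k in k_lo:k_hi) {
    y <- y + amp * exp(-(x - (x0 + k * sl))^2 / (2 * sigma_z^2))
  }
  y
}

# M-line channel template: Gaussian peaks at mid-period positions only,
# periodic across the whole sampled window like the phalloidin template.
mline_template <- function(x, truth, m_positions) {
  sl <- truth$sarcomere_length
  sigma_m <- truth$z_disc_width / (2 * sqrt(2 * log(2)))
  amp <- truth$z_peak_level - truth$background
  y <- rep(truth$background, length(x))
  m0 <- m_positions[1]
  k_lo <- floor((min(x) - m0) / sl) - 1
  k_hi <- ceiling((max(x) - m0) / sl) + 1
  for (k in k_lo:k_hi) {
    y <- y + amp * exp(-(x - (m0 + k * sl))^2 / (2 * sigma_m^2))
  }
  y
}

check_profile_args <- function(truth, n_sarcomeres, noise_sd) {
  stopifnot(inherits(truth, "striation_truth"))
  if (n_sarcomeres < 2) stop("n_sarcomeres must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (truth$h_zone_width > 0 && truth$pixel_size >= truth$h_zone_width) {
    stop("pixel_size >= h_zone_width: H-zone trough is unresolvable")
  }
  invisible(TRUE)
}

# Sample a continuous template, apply Gaussian PSF (in pixels) and noise,
# and wrap as an intensity_profile with the truth record attached.
sample_profile <- function(template_fun, truth, n_sarcomeres, noise_sd, seed,
                           channel) {
  sl <- truth$sarcomere_length
  ps <- truth$pixel_size
  margin <- sl # one full period of margin at each end
  total <- n_sarcomeres * sl + 2 * margin
  n_px <- floor(total / ps) + 1L
  positions <- (seq_len(n_px) - 1L) * ps
  z_positions <- margin + (0:n_sarcomeres) * sl
  m_positions <- margin + ((0:(n_sarcomeres - 1)) + 0.5) * sl
  y <- template_fun(positions, truth,
                    if (channel == "obscurin") m_positions else z_positions)
  y <- gaussian_smooth(y, truth$psf_sigma / ps)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(n_px, sd = noise_sd))
  }
  y <- pmax(y, 0)
  prof <- intensity_profile(positions, y, ps, channel)
  attr(prof, "truth") <- truth
  attr(prof, "z_positions") <- z_positions
  attr(prof, "m_positions") <- m_positions
  prof
}

#' Generate a synthetic phalloidin striation profile
#'
#' Builds a noise-free piecewise template — a Gaussian Z-disc peak at each
#' period boundary, a thin-filament plateau over each array, and an H-zone
#' trough centered mid-period — convolves it with a Gaussian point-spread
#' function, samples it at `pixel_size`, and adds Gaussian noise. The ground
#' truth (and the true Z-disc / M-line positions) are attached as attributes
#' so downstream measurements can be checked against them.
#'
#' @param truth A [striation_truth()] record.
#' @param n_sarcomeres Number of full periods (>= 2).
#' @param noise_sd Additive Gaussian noise standard deviation, a.u.
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @return An [intensity_profile()] (channel `"phalloidin"`) with attributes
#'   `truth`, `z_positions` and `m_positions`.
#' @export
#' @examples
#' tr <- striation_truth(thin_filament_length = 1.6, h_zone_width = 0.16)
#' p <- gen_striation_profile(tr, n_sarcomeres = 5, noise_sd = 0.02, seed = 1)
gen_striation_profile <- function(truth, n_sarcomeres, noise_sd = 0,
                                  seed = NULL) {
  check_profile_args(truth, n_sarcomeres, noise_sd)
  sample_profile(striation_template, truth, n_sarcomeres, noise_sd, seed,
                 "phalloidin")
}

#' Generate a synthetic M-line (obscurin channel) profile
#'
#' Same calibration and period as [gen_striation_profile()], but with Gaussian
#' peaks at mid-period (M-line) positions only, offset from the Z-discs by
#' half a sarcomere.
#'
#' @inheritParams gen_striation_profile
#' @return An [intensity_profile()] (channel `"obscurin"`) with truth
#'   attributes as in [gen_striation_profile()].
#' @export
gen_mline_profile <- function(truth, n_sarcomeres, noise_sd = 0, seed = NULL) {
  check_profile_args(truth, n_sarcomeres, noise_sd)
  sample_profile(mline_template, truth, n_sarcomeres, noise_sd, seed,
                 "obscurin")
}

#' Generate a synthetic 2-D image of parallel striated myofibrils
#'
#' Renders `fibril_count` parallel fibril stripes whose along-axis intensity
#' equals the 1-D phalloidin template, at an arbitrary orientation, with
#' per-pixel Gaussian noise. The image is a numeric matrix (rows = y,
#' columns = x, pixel centers at `(index - 1) * pixel_size` um) with the truth
#' record and the field geometry attached.
#'
#' @inheritParams gen_striation_profile
#' @param fibril_count Number of parallel fibrils (>= 1).
#' @param fibril_width_px Width of each fibril stripe, pixels.
#' @param orientation Fibril axis angle, degrees counter-clockwise from the
#'   image x axis.
#' @param gap_px Background gap between stripes, pixels.
#' @return Numeric matrix with attributes `pixel_size`, `truth`, `geometry`.
#' @export
gen_striation_image <- function(truth, fibril_count = 3, fibril_width_px = 5,
                                orientation = 0, n_sarcomeres = 6,
                                noise_sd = 0, gap_px = 4, seed = NULL) {
  check_profile_args(truth, n_sarcomeres, noise_sd)
  stopifnot(fibril_count >= 1, fibril_width_px >= 1)
  ps <- truth$pixel_size
  sl <- truth$sarcomere_length
  margin <- sl
  lu <- n_sarcomeres * sl + 2 * margin # field length along fibril axis, um
  lv <- (fibril_count * (fibril_width_px + gap_px) + gap_px) * ps
  if (lu <= 0 || lv <= 0) stop("zero-area geometry")
  th <- orientation * pi / 180
  wx <- abs(lu * cos(th)) + abs(lv * sin(th))
  wy <- abs(lu * sin(th)) + abs(lv * cos(th))
  nx <- ceiling(wx / ps) + 1L
  ny <- ceiling(wy / ps) + 1L
  cx <- (nx - 1) / 2 * ps
  cy <- (ny - 1) / 2 * ps
  xs <- (seq_len(nx) - 1L) * ps - cx
  ys <- (seq_len(ny) - 1L) * ps - cy
  # field coordinates of every pixel center
  u <- outer(ys * sin(th), xs * cos(th), `+`) + lu / 2
  v <- outer(ys * cos(th), -xs * sin(th), `+`) + lv / 2
  z_positions <- margin + (0:n_sarcomeres) * sl
  stripe_period <- (fibril_width_px + gap_px) * ps
  v_in <- (v - gap_px * ps) %% stripe_period
  fibril_idx <- floor((v - gap_px * ps) / stripe_period)
  in_stripe <- v >= gap_px * ps & v < lv - gap_px * ps &
    v_in < fibril_width_px * ps & fibril_idx >= 0 & fibril_idx < fibril_count
  img <- matrix(truth$background, nrow = ny, ncol = nx)
  tmpl <- striation_template(as.numeric(u[in_stripe]), truth, z_positions)
  img[in_stripe] <- tmpl
  # PSF: separable Gaussian blur in pixel units
  sig_px <- truth$psf_sigma / ps
  if (sig_px > 0) {
    img <- t(apply(img, 1L, gaussian_smooth, sigma = sig_px))
    img <- apply(img, 2L, gaussian_smooth, sigma = sig_px)
  }
  if (noise_sd > 0) {
    img <- with_seed(seed,
      img + matrix(stats::rnorm(nx * ny, sd = noise_sd), nrow = ny))
  }
  img <- pmax(img, 0)
  fibril_centers_v <- gap_px * ps + ((seq_len(fibril_count) - 1) *
    stripe_period) + fibril_width_px * ps / 2
  attr(img, "pixel_size") <- ps
  attr(img, "truth") <- truth
  attr(img, "geometry") <- list(
    orientation = orientation, lu = lu, lv = lv, margin_um = margin,
    fibril_centers_v = fibril_centers_v, center_xy = c(cx, cy)
  )
  img
}

#' Polyline along the axis of one synthetic fibril
#'
#' Convenience accessor for images from [gen_striation_image()]: returns the
#' two endpoints (in image um coordinates) of a line running along the center
#' of fibril `fibril`, suitable for [extract_line_profile()].
#'
#' @param image Matrix from [gen_striation_image()].
#' @param fibril Fibril index (1-based).
#' @param inset_um Distance to pull each endpoint in from the field edge, um.
#' @return A 2 x 2 matrix of (x, y) endpoints in um.
#' @export
fibril_polyline <- function(image, fibril = 1, inset_um = 0) {
  g <- attr(image, "geometry")
  if (is.null(g)) stop("image has no attached field geometry")
  stopifnot(fibril >= 1, fibril <= length(g$fibril_centers_v))
  th <- g$orientation * pi / 180
  v <- g$fibril_centers_v[fibril]
  ends_u <- c(inset_um, g$lu - inset_um)
  x <- (ends_u - g$lu / 2) * cos(th) - (v - g$lv / 2) * sin(th) +
    g$center_xy[1]
  y <- (ends_u - g$lu / 2) * sin(th) + (v - g$lv / 2) * cos(th) +
    g$center_xy[2]
  cbind(x = x, y = y)
}
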