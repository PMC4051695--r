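test_that("line profiles extracted from images match the 1-D generator", {
  tr <- default_truth()
  img <- gen_striation_image(tr, fibril_count = 3, fibril_width_px = 5,
                             orientation = 0, n_sarcomeres = 5)
  # constant image -> constant profile
  cimg <- matrix(2.5, 40, 60)
  prof_c <- extract_line_profile(cimg, rbind(c(0.2, 1), c(2.5, 1)),
                                 width_px = 3, pixel_size = 0.05)
  expect_true(all(abs(prof_c$intensities - 2.5) < 1e-12))
  # width averaging is a no-op on translation-invariant stripes
  pl <- fibril_polyline(img, 2)
  p1 <- extract_line_profile(img, pl, width_px = 1)
  p3 <- extract_line_profile(img, pl, width_px = 3)
  expect_lt(max(abs(p1$intensities - p3$intensities)), 0.02)
  # measured geometry equals the 1-D generator's within half a pixel
  z2d <- detect_z_discs(p3)
  z1d <- detect_z_discs(gen_striation_profile(tr, 5, 0))
  expect_lt(abs(mean(diff(z2d)) - mean(diff(z1d))), tr$pixel_size / 2)
  # rotation by 90 degrees leaves the measurements unchanged
  img90 <- gen_striation_image(tr, 3, 5, orientation = 90, n_sarcomeres = 5)
  z90 <- detect_z_discs(extract_line_profile(img90,
                                             fibril_polyline(img90, 2), 3))
  expect_equal(diff(z90), diff(z2d), tolerance = 1e-6)
  # all three fibrils are independently recoverable
  for (k in 1:3) {
    zk <- detect_z_discs(extract_line_profile(img, fibril_polyline(img, k), 3))
    expect_true(all(abs(diff(zk) - tr$sarcomere_length) < tr$pixel_size / 2))
  }
  expect_error(extract_line_profile(img, rbind(c(0, 0), c(0, 0))),
               "degenerate")
  expect_error(extract_line_profile(cimg, rbind(c(-5, 0), c(5, 0)),
                                    pixel_size = 0.05), "bounds")
})

test_that("Z-disc detection is sub-pixel accurate and fails gracefully", {
  tr <- default_truth()
  # noisy profile: every detected position within one pixel of the truth grid
  p <- gen_striation_profile(tr, 8, noise_5pct(tr), seed = 1)
  z <- detect_z_discs(p)
  truth_z <- attr(p, "z_positions")
  expect_length(z, length(truth_z))
  expect_true(all(abs(z - truth_z) < tr$pixel_size))
  # flat profile: no-measurement, not an error
  flat <- intensity_profile((0:99) * 0.05, rep(1, 100), 0.05)
  expect_identical(detect_z_discs(flat), numeric(0))
  expect_null(measure_sarcomere_lengths(detect_z_discs(flat)))
})

test_that("detection is translation-invariant and intensity-scale-invariant", {
  tr <- default_truth()
  p <- gen_striation_profile(tr, 6, noise_5pct(tr), seed = 5)
  k <- 7L # shift by k pixels
  n <- length(p$positions)
  shifted <- intensity_profile(p$positions[1:(n - k)],
                               p$intensities[(k + 1):n], p$pixel_size)
  z0 <- detect_z_discs(p)
  z1 <- detect_z_discs(shifted)
  common0 <- z0[z0 > k * p$pixel_size + 1]
  expect_equal(z1[seq_along(common0)] + k * p$pixel_size, common0,
               tolerance = 1e-9)
  scaled <- intensity_profile(p$positions, p$intensities * 3.7, p$pixel_size)
  expect_equal(detect_z_discs(scaled), z0, tolerance = 1e-12)
  m <- measure_striation(p)
  ms <- measure_striation(scaled)
  expect_equal(ms[, c("sl_um", "tfl_um", "hz_um")],
               m[, c("sl_um", "tfl_um", "hz_um")], tolerance = 1e-9)
})

test_that("M-line positions sit midway between Z-discs", {
  tr <- default_truth()
  # obscurin channel, noise-free: spacing equals the period
  pm <- gen_mline_profile(tr, 5, 0)
  m <- detect_m_lines(pm)
  expect_true(all(abs(diff(m) - tr$sarcomere_length) < tr$pixel_size / 2))
  # phalloidin troughs: midway between Z positions within one pixel
  pz <- gen_striation_profile(tr, 5, 0)
  z <- detect_z_discs(pz)
  mt <- detect_m_lines(pz)
  expect_length(mt, length(z) - 1)
  mid <- (z[-1] + z[-length(z)]) / 2
  expect_true(all(abs(mt - mid) < tr$pixel_size))
  # single-peak profile: no measurement
  x <- (0:63) * 0.05
  single <- intensity_profile(x, 1 + exp(-(x - 1.6)^2 / 0.02), 0.05,
                              channel = "obscurin")
  expect_lt(length(detect_m_lines(single)), 2)
})

test_that("sarcomere lengths are consecutive landmark differences", {
  expect_equal(measure_sarcomere_lengths(c(0, 3.36, 6.72)),
               c(3.36, 3.36))
  expect_error(measure_sarcomere_lengths(c(3.36, 0, 6.72)), "increasing")
  expect_null(measure_sarcomere_lengths(c(0, 3.36, 6.72), min_n = 3))
  expect_null(measure_sarcomere_lengths(5))
})

test_that("thin-filament measurement matches the analytic ramp case", {
  # plateau 1.0 ends 1.2 um from the Z-disc, linear ramp to 0.1 over 0.2 um,
  # symmetric sarcomere of period 3.2: the half crossing is analytic at
  # 1.3 um, so TFL = 1.3 and HZ = 3.2 - 2 * 1.3 = 0.6
  ps <- 0.05
  x <- seq(0, 3.2, by = ps)
  ramp <- function(u) {
    d <- pmin(u, 3.2 - u) # distance to the nearer Z-disc
    ifelse(d <= 1.2, 1.0, ifelse(d >= 1.4, 0.1, 1.0 - (d - 1.2) * 4.5))
  }
  prof <- intensity_profile(x, ramp(x), ps)
  res <- measure_thin_filament_length(prof, c(0, 3.2))
  expect_false(res$degenerate)
  expect_equal(res$thin_filament_length, 1.3, tolerance = 1e-9)
  expect_equal(res$h_zone_width, 0.6, tolerance = 1e-9)
  expect_error(measure_thin_filament_length(prof, c(0, 0.1)), "adjacent")
})

test_that("thin-filament and H-zone widths round-trip through the generator", {
  tr <- default_truth() # TFL 1.60, HZ 0.16
  p <- gen_striation_profile(tr, 8, noise_5pct(tr), seed = 1)
  m <- measure_striation(p)
  expect_false(any(m$degenerate))
  expect_lt(abs(mean(m$sl_um) - tr$sarcomere_length), tr$pixel_size)
  expect_lt(abs(mean(m$tfl_um) - tr$thin_filament_length), tr$pixel_size)
  expect_lt(abs(mean(m$hz_um) - tr$h_zone_width), tr$pixel_size)
  # left/right symmetry on the noise-free profile
  p0 <- gen_striation_profile(tr, 4, 0)
  z <- detect_z_discs(p0)
  tf <- measure_thin_filament_length(p0, z[2:3])
  sl <- z[3] - z[2]
  # TFL is the mean of the two sides; symmetric input means both sides agree,
  # so 2 * TFL + HZ reproduces the period
  expect_equal(2 * tf$thin_filament_length + tf$h_zone_width, sl,
               tolerance = 1e-3)
})

test_that("group summaries and comparisons follow the textbook formulas", {
  s <- summarize_group(c(3, 3, 3))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 0)
  s1 <- summarize_group(5)
  expect_true(s1$single_value)
  expect_equal(s1$sd, 0)
  expect_error(summarize_group(numeric(0)), "empty")
  # sampling: mean of n = 30 draws within 3 sem of truth
  set.seed(30)
  draws <- rnorm(30, 3.36, 0.1)
  sg <- summarize_group(draws)
  expect_lt(abs(sg$mean - 3.36), 3 * sg$sem + 3 * 0.1 / sqrt(30))

  # hand-computed 3-vs-3 equal-variance t statistic
  a <- c(3.1, 3.3, 3.5); b <- c(3.6, 3.8, 4.0)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  cmp <- compare_groups(a, b)
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 4)
  # identical groups: p in the non-significant region
  cmp0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_identical(cmp0$stars, "ns")
  expect_error(compare_groups(1, c(1, 2)), "two values")
})

test_that("star codes follow the figure thresholds", {
  expect_identical(star_code(0.01), "*")
  expect_identical(star_code(0.001), "**")
  expect_identical(star_code(1e-5), "***")
  expect_identical(star_code(0.2), "ns")
  # boundary values are exclusive
  expect_identical(star_code(0.05), "ns")
  expect_identical(star_code(0.005), "*")
  expect_identical(star_code(0.0005), "**")
})

test_that("percent change reproduces the reporting convention", {
  expect_equal(round(percent_change(3.41, 3.76), 1), 10.3)
  expect_equal(percent_change(2, 2), 0)
  expect_equal(round(percent_change(3.36, 3.33)), -1)
  expect_error(percent_change(0, 1), "positive")
})
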