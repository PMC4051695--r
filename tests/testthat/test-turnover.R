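test_that("ROI quantification averages the intended pixels", {
  cimg <- matrix(4, 50, 50)
  attr(cimg, "pixel_size") <- 0.1
  r <- quantify_rois(cimg, list(c(0.5, 0.5, 1.5, 1.0)),
                     list(rbind(c(2, 2), c(4, 2), c(3, 4))))
  expect_equal(r$z, 4)
  expect_equal(r$body, 4)
  expect_error(quantify_rois(cimg, list(c(0, 0, 20, 20)), list()), "bounds")
  # synthetic stripes with Z-disc amplitude about twice the body level
  tr <- striation_truth(thin_filament_length = 1.6, h_zone_width = 0.16,
                        z_peak_level = 1.0, filament_level = 0.5,
                        h_zone_level = 0.45, background = 0.02)
  img <- gen_striation_image(tr, fibril_count = 1, fibril_width_px = 7,
                             orientation = 0, n_sarcomeres = 4)
  g <- attr(img, "geometry")
  pl <- fibril_polyline(img, 1)
  v_um <- pl[1, 2] # fibril center y
  prof <- extract_line_profile(img, pl, width_px = 3)
  z <- detect_z_discs(prof)
  zx <- pl[1, 1] + (z[2] - prof$positions[1]) # image x of second Z-disc
  zw <- tr$z_disc_width / 2
  roi <- quantify_rois(
    img,
    z_rois = list(c(zx - zw, v_um - 0.1, zx + zw, v_um + 0.1)),
    body_rois = list(rbind(c(zx + 0.5, v_um - 0.1), c(zx + 1.2, v_um - 0.1),
                           c(zx + 1.2, v_um + 0.1), c(zx + 0.5, v_um + 0.1)))
  )
  expect_gt(zbody_ratio(roi$z, roi$body), 1.5)
})

test_that("the Z/body ratio is scale-invariant and flags a zero body", {
  expect_equal(zbody_ratio(10, 10), 1)
  expect_equal(zbody_ratio(20, 10), 2)
  expect_equal(zbody_ratio(20 * 3.3, 10 * 3.3), 2)
  expect_warning(r <- zbody_ratio(5, 0), "undefined")
  expect_true(is.na(r))
})

test_that("Z-disc enrichment separates sarcomeric from cytoplasmic labels", {
  # sarcomeric label concentrates at the Z-disc (body fraction 0.4); a
  # cytoplasmic label is uniform (body fraction ~ 1). At 40 sarcomeres the
  # ratio contrast is significant.
  tp <- seq(0, 100, by = 20)
  act <- gen_pulse_chase(turnover_kinetics(body_fraction = 0.4),
                         tp, n_sarcomeres_per_tp = 40, noise_sd = 2,
                         seed = 21, label = "Act88F_GFP")
  egfp <- gen_pulse_chase(turnover_kinetics(body_fraction = 0.99),
                          tp, n_sarcomeres_per_tp = 40, noise_sd = 2,
                          seed = 22, label = "eGFP")
  late <- length(tp)
  ra <- act$z_intensity[[late]] / act$body_intensity[[late]]
  re <- egfp$z_intensity[[late]] / egfp$body_intensity[[late]]
  expect_gt(mean(ra), mean(re))
  expect_lt(stats::t.test(ra, re)$p.value, 0.05)
  expect_gt(mean(re), 0.9)
  expect_lt(mean(re), 1.1)
})

test_that("onset detection requires a sustained significant rise", {
  # flat series: no onset
  flat <- gen_pulse_chase(
    turnover_kinetics(lag = 90, rise_end = 95, baseline = 10, peak = 11),
    seq(0, 80, 10), 5, noise_sd = 1, seed = 1
  )
  expect_true(is.na(detect_onset(flat)))
  # lag recovery within one grid step, for both the 20 h and 15 h designs,
  # at the study's sampling depth of 40 sarcomeres per timepoint
  for (lag in c(20, 15)) {
    kin <- turnover_kinetics(lag = lag, rise_end = 95)
    s <- gen_pulse_chase(kin, seq(0, 150, 5), 40, noise_sd = 5, seed = 31)
    expect_lte(abs(detect_onset(s) - lag), 5)
  }
})

test_that("peak detection takes the earliest maximal timepoint", {
  rising <- pulse_chase_series(c(0, 10, 20),
                               list(c(1, 1), c(2, 2), c(3, 3)),
                               list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(detect_peak(rising), 20)
  const <- pulse_chase_series(c(0, 10, 20),
                              list(c(2, 2), c(2, 2), c(2, 2)),
                              list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(detect_peak(const), 0)
  kin <- turnover_kinetics(lag = 20, rise_end = 95)
  s <- gen_pulse_chase(kin, seq(0, 200, 5), 10, noise_sd = 3, seed = 12)
  expect_lte(abs(detect_peak(s) - 95), 5)
})

test_that("half-life estimation recovers exponential decay", {
  kin <- turnover_kinetics(lag = 10, rise_end = 30, decay_halflife = 48)
  exact <- gen_pulse_chase(kin, seq(0, 300, 10), 4, noise_sd = 0)
  expect_equal(estimate_halflife(exact), 48, tolerance = 1e-6)
  # plateau (no decay): none
  stable <- gen_pulse_chase(turnover_kinetics(decays = FALSE),
                            seq(0, 300, 10), 4, noise_sd = 0)
  expect_true(is.na(estimate_halflife(stable)))
  # noisy recovery within 15% over a chase window of ~3 half-lives at the
  # study's 40-sarcomere sampling depth
  kin72 <- turnover_kinetics(lag = 20, rise_end = 95, decay_halflife = 72)
  noisy <- gen_pulse_chase(kin72, seq(0, 320, 10), 40, noise_sd = 2,
                           seed = 14)
  expect_lt(abs(estimate_halflife(noisy) - 72) / 72, 0.15)
  # too few post-peak points: none
  short <- gen_pulse_chase(kin, c(0, 20, 30, 40), 4, noise_sd = 0)
  expect_true(is.na(estimate_halflife(short)))
})

test_that("turnover summaries assemble onset, peak, half-life and ratios", {
  kin <- turnover_kinetics(lag = 20, rise_end = 95, decay_halflife = 72,
                           body_fraction = 0.4)
  s <- gen_pulse_chase(kin, seq(0, 400, 5), 20, noise_sd = 2, seed = 2)
  su <- summarize_turnover(s)
  expect_s3_class(su, "turnover_summary")
  expect_lte(abs(su$onset - 20), 5)
  expect_lte(abs(su$peak_time - 95), 5)
  expect_lt(abs(su$halflife - 72) / 72, 0.15)
  expect_true(su$onset <= su$peak_time)
  expect_equal(nrow(su$ratio_series), length(s$timepoints))
  late <- su$ratio_series$ratio_mean[su$ratio_series$timepoint_h == 95]
  expect_gt(late, 2) # 1 / body_fraction = 2.5, noisy
})
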