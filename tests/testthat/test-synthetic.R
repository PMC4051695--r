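test_that("truth records enforce the sarcomere geometry identity", {
  tr <- striation_truth(thin_filament_length = 1.6, h_zone_width = 0.16)
  expect_equal(tr$sarcomere_length, 2 * 1.6 + 0.16)
  tr2 <- striation_truth(sarcomere_length = 3.10, h_zone_width = 0.30)
  expect_equal(2 * tr2$thin_filament_length + tr2$h_zone_width, 3.10)
  # inconsistent triple is rejected
  expect_error(striation_truth(sarcomere_length = 3.5,
                               thin_filament_length = 1.6,
                               h_zone_width = 0.16),
               "must equal")
  # level ordering is enforced
  expect_error(striation_truth(filament_level = 1.2), "levels")
  # identity holds across a parameter grid
  for (tfl in c(1.2, 1.5, 1.8)) {
    for (hz in c(0, 0.1, 0.3)) {
      tr <- striation_truth(thin_filament_length = tfl, h_zone_width = hz)
      expect_identical(tr$sarcomere_length, 2 * tfl + hz)
    }
  }
})

test_that("noise-free striation profile has maxima at exact period spacing", {
  tr <- striation_truth(sarcomere_length = 3.4, h_zone_width = 0.2)
  p <- gen_striation_profile(tr, n_sarcomeres = 5, noise_sd = 0)
  z <- detect_z_discs(p)
  expect_true(length(z) >= 6)
  expect_true(all(abs(diff(z) - 3.4) < tr$pixel_size / 2))
})

test_that("degenerate H-zone leaves no interior trough below the plateau", {
  tr <- striation_truth(thin_filament_length = 1.7, h_zone_width = 0,
                        psf_sigma = 0)
  p <- gen_striation_profile(tr, 4, noise_sd = 0)
  z <- detect_z_discs(p)
  mid <- p$intensities[p$positions > z[1] + 0.5 & p$positions < z[2] - 0.5]
  expect_true(all(mid >= tr$filament_level - 1e-9))
})

test_that("profile generators reject unphysical parameters", {
  tr <- default_truth()
  expect_error(gen_striation_profile(tr, 1, 0), "n_sarcomeres")
  expect_error(gen_striation_profile(tr, 5, -1), "noise_sd")
  bad <- striation_truth(thin_filament_length = 1.6, h_zone_width = 0.04)
  expect_error(gen_striation_profile(bad, 5, 0), "unresolvable")
})

test_that("M-line profiles are offset from Z-discs by half a period", {
  tr <- default_truth()
  pz <- gen_striation_profile(tr, 5, 0)
  pm <- gen_mline_profile(tr, 5, 0)
  z <- detect_z_discs(pz)
  m <- detect_z_discs(pm) # obscurin channel: peaks
  expect_true(all(abs(diff(m) - tr$sarcomere_length) < tr$pixel_size / 2))
  # each recorded truth M position sits SL/2 from the matching Z position
  half <- tr$sarcomere_length / 2
  expect_equal(attr(pm, "m_positions") - attr(pm, "z_positions")[1:5],
               rep(half, 5))
  # noisy M-to-M mean length recovers truth within one pixel
  pmn <- gen_mline_profile(tr, 8, noise_5pct(tr), seed = 2)
  mn <- detect_z_discs(pmn)
  expect_lt(abs(mean(diff(mn)) - tr$sarcomere_length), tr$pixel_size)
})

test_that("pulse-chase generator matches its kinetic definition", {
  kin <- turnover_kinetics(lag = 20, rise_end = 95, decay_halflife = 48,
                           baseline = 10, peak = 100)
  # plateau control: late mean equals the peak exactly without noise
  kc <- turnover_kinetics(lag = 15, rise_end = 28, decays = FALSE)
  sc <- gen_pulse_chase(kc, c(0, 50, 200), 5, noise_sd = 0)
  expect_equal(mean(sc$z_intensity[[3]]), kc$peak)
  # half-life definition: one half-life past the peak sits midway
  s <- gen_pulse_chase(kin, c(0, 95, 95 + 48), 5, noise_sd = 0)
  expect_equal(mean(s$z_intensity[[3]]), 10 + (100 - 10) / 2)
  # body channel is body_fraction of the Z channel
  expect_equal(mean(s$body_intensity[[2]]), kin$body_fraction * 100)
  expect_error(gen_pulse_chase(kin, numeric(0), 5, 0), "non-empty")
})

test_that("Ct generator implements the doubling model", {
  d <- small_qpcr_design(target_rel = 0.25, replicate_sd = 0)
  ct <- gen_ct_table(d, 2)
  # sd = 0: Ct = base - log2(rel) exactly
  kd6 <- ct$ct[ct$genotype == "RNAi" & ct$day == 6 & ct$gene == "Act88F"]
  expect_equal(unique(kd6), 22 - log2(0.25))
  ref <- ct$ct[ct$gene == "GAPDH"]
  expect_equal(unique(ref), 16)
  expect_error(qpcr_design(
    genes = "a", reference = "r",
    conditions = data.frame(genotype = "g", day = 0),
    true_relative_expression = data.frame(gene = "a", genotype = "g",
                                          day = 0, rel_expr = -1),
    base_ct = c(a = 20, r = 15)
  ), "positive")
})

test_that("geotaxis generator respects the binomial design", {
  des <- climbing_design(days = c(0, 3), p_success = c(1, 0),
                         n_vials = 3, tech_reps = 2)
  g <- gen_geotaxis(des, seed = 1)
  expect_true(all(g$successes[g$day == 0] == 10))
  expect_true(all(g$successes[g$day == 3] == 0))
  # empirical mean converges to p at n * reps >= 500 (within 3 se)
  des2 <- climbing_design(days = 0, p_success = 0.6, n_vials = 20,
                          flies_per_vial = 10, tech_reps = 5)
  g2 <- gen_geotaxis(des2, seed = 11)
  frac <- g2$successes / g2$n_flies
  se <- sqrt(0.6 * 0.4 / (20 * 10 * 5))
  expect_lt(abs(mean(frac) - 0.6), 3 * se)
})

test_that("screen fixture round-trips its class structure", {
  counts <- c(Severe = 5, Intermediate = 13, Weak = 28, None = 86)
  fx <- gen_screen_fixture(counts, seed = 3)
  cls <- vapply(fx$trajectories,
                function(t) classify_severity(day_of_loss(t)), "")
  expect_equal(
    as.numeric(vapply(names(counts), function(cl) sum(cls == cl), 1L)),
    unname(counts)
  )
  # classification recomputed from trajectories equals the designed classes
  expect_identical(unname(cls), fx$genes$severity)
  # all-None fixture
  fx0 <- gen_screen_fixture(c(Severe = 0, Intermediate = 0, Weak = 0,
                              None = 10), seed = 4)
  expect_true(all(is.na(fx0$genes$day_of_loss)))
  # network size equals the designed edge count
  net <- build_network(fx$genes, fx$edges)
  expect_equal(igraph::vcount(net), nrow(fx$genes))
  expect_equal(igraph::ecount(net), nrow(fx$edges))
})

test_that("generators are bit-reproducible for a fixed seed", {
  tr <- default_truth()
  p1 <- gen_striation_profile(tr, 4, 0.05, seed = 42)
  p2 <- gen_striation_profile(tr, 4, 0.05, seed = 42)
  p3 <- gen_striation_profile(tr, 4, 0.05, seed = 43)
  expect_identical(p1$intensities, p2$intensities)
  expect_false(identical(p1$intensities, p3$intensities))
  kin <- turnover_kinetics()
  s1 <- gen_pulse_chase(kin, seq(0, 100, 10), 5, 3, seed = 9)
  s2 <- gen_pulse_chase(kin, seq(0, 100, 10), 5, 3, seed = 9)
  expect_identical(s1$z_intensity, s2$z_intensity)
  g1 <- gen_geotaxis(climbing_design(), seed = 8)
  g2 <- gen_geotaxis(climbing_design(), seed = 8)
  expect_identical(g1, g2)
  f1 <- gen_screen_fixture(seed = 6)
  f2 <- gen_screen_fixture(seed = 6)
  expect_identical(f1, f2)
  # generators do not disturb the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(gen_striation_profile(tr, 4, 0.05, seed = 1))
  expect_identical(.Random.seed, before)
})
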