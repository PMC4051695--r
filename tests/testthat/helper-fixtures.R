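# Shared fixtures: a typical flight-muscle striation geometry and small
# generators used across test files.

default_truth <- function(...) {
  striation_truth(thin_filament_length = 1.60, h_zone_width = 0.16, ...)
}

# noise at 5% of the template dynamic range (z peak to background)
noise_5pct <- function(truth) 0.05 * (truth$z_peak_level - truth$background)

# small qPCR design: one target + reference, RNAi and control arms,
# day 0 calibrator and one later day with known true expression
small_qpcr_design <- function(target_rel = 0.02, control_rel = 0.75,
                              day = 6, replicate_sd = 0.15) {
  qpcr_design(
    genes = "Act88F", reference = "GAPDH",
    conditions = data.frame(
      genotype = rep(c("RNAi", "control"), each = 2),
      day = rep(c(0, day), 2)
    ),
    true_relative_expression = data.frame(
      gene = "Act88F",
      genotype = c("RNAi", "RNAi", "control", "control"),
      day = c(0, day, 0, day),
      rel_expr = c(1, target_rel, 1, control_rel)
    ),
    base_ct = c(Act88F = 22, GAPDH = 16),
    replicate_sd = replicate_sd
  )
}
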