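# Shared fixtures: all synthetic, built in code.

# Flatten simulated tolerance plating into the long CFU table that
# frequency_curve() consumes.
cfu_table_from_spots <- function(spots, countable_range = c(3, 150)) {
  rows <- lapply(names(spots), function(cc) {
    do.call(rbind, lapply(spots[[cc]], function(s) {
      est <- estimate_cfu(s, countable_range = countable_range)
      data.frame(concentration = as.numeric(cc),
                 replicate = est$replicate_id,
                 cfu = est$cfu_per_ml,
                 censored = est$censored)
    }))
  })
  do.call(rbind, rows)
}

# Noise-free tolerance curve straight from the model (no plating noise).
model_curve <- function(model, concentrations) {
  data.frame(concentration = concentrations,
             frequency = tolerance_frequency(model, concentrations))
}

# One null draw for the slope-comparison type-I simulation: a 4-point
# log-linear curve with Gaussian noise on the log10 frequencies.
null_slope_fit <- function(true_slope = -1, sd_log10 = 0.3, concs = 1:4) {
  f <- 10^(true_slope * concs + stats::rnorm(length(concs), 0, sd_log10))
  decline_slope(data.frame(concentration = concs, frequency = f))
}
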