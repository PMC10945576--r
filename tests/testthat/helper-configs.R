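# Shared simulation configurations for the test suite.
#
# "reduced" scale: 100 trials x 125 samples (1 s at 125 Hz) x 16 channels,
# used for the decoding experiments; "tiny" scale for unit-level checks.

reduced_spontaneous <- function(n_trials = 100) {
  spontaneous_spec(n_trials = n_trials, n_times = 125, n_channels = 16,
                   fs = 125)
}

tiny_spontaneous <- function(n_trials = 20, n_times = 50, n_channels = 4) {
  spontaneous_spec(n_trials = n_trials, n_times = n_times,
                   n_channels = n_channels, fs = 125)
}

# latency diversity 0-160 ms and frequency diversity 0.1-0.2 rad/sample
# across the 16 channels of the reduced scale
latency_diverse <- round(seq(0, 20, length.out = 16))
freq_diverse <- seq(0.1, 0.2, length.out = 16)

# oscillatory response shape: rise 64 ms, fall 88 ms at 125 Hz
shape_reduced <- function(delta2 = 8, delta3 = 11) {
  response_shape(delta1 = 0, delta2 = delta2, delta3 = delta3)
}

# slow-response gate: ramps up in ~100 ms, vanishes around 800 ms
shape_slow_reduced <- function() {
  response_shape(delta1 = 0, delta2 = 12, delta3 = 88)
}

# additive oscillation + slow response with diverse frequencies/latencies
config_osc_slow <- function(n_trials = 100, slow_diff = 0.5, theta = 1 / 6,
                            freq = freq_diverse, latency = latency_diverse,
                            shape = shape_reduced(),
                            in_phase_fraction = 1,
                            phase = c(0, pi), phase_ref = "onset") {
  sim_config(
    spontaneous = reduced_spontaneous(n_trials),
    theta = theta,
    shape = shape,
    channel_freq = freq,
    channel_latency = latency,
    in_phase_fraction = in_phase_fraction,
    effects = list(
      effect_additive_osc(phase = phase, phase_ref = phase_ref),
      effect_slow(mean = c(slow_diff / 2, -slow_diff / 2),
                  shape = shape_slow_reduced())
    )
  )
}

# phase reset + entrainment with the same channel diversity
config_phase_reset <- function(n_trials = 100, theta = 1 / 6, m = NULL,
                               target_sd = 0.1) {
  effs <- list(
    effect_phase_reset(target_mean = c(0, pi), target_sd = target_sd,
                       entrain_freq = 0.15),
    effect_slow(mean = c(0.25, -0.25), shape = shape_slow_reduced())
  )
  if (!is.null(m)) effs <- c(effs, list(effect_amp_mod(m = m)))
  sim_config(
    spontaneous = reduced_spontaneous(n_trials),
    theta = theta,
    shape = shape_reduced(),
    channel_freq = freq_diverse,
    channel_latency = latency_diverse,
    effects = effs
  )
}

# circular resultant length (phase-locking value across trials)
plv <- function(phases) Mod(mean(exp(1i * phases)))
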