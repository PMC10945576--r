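test_that("polar gradient wraps onto [-pi, pi) and closes the gap to the target", {
  expect_equal(polar_gradient(3 * pi / 2, 0), -pi / 2)
  expect_equal(polar_gradient(1.3, 1.3), 0)
  # exhaustive grid oracle: bounded and consistent modulo 2*pi
  grid <- expand.grid(target = seq(-pi, pi, length.out = 100),
                      phi = seq(-3 * pi, 3 * pi, length.out = 100))
  g <- polar_gradient(grid$target, grid$phi)
  expect_true(all(abs(g) <= pi))
  expect_equal(sin(grid$phi + g), sin(grid$target), tolerance = 1e-9)
  expect_equal(cos(grid$phi + g), cos(grid$target), tolerance = 1e-9)
})

test_that("von Mises target-phase sampling matches its circular moments", {
  expect_equal(sample_target_phase(0.7, 0, 5), rep(0.7, 5))
  set.seed(5)
  draws <- sample_target_phase(1.2, 0.4, 1e4)
  circ_mean <- Arg(mean(exp(1i * draws)))
  expect_equal(circ_mean, 1.2, tolerance = 0.05)
  # increasing spread => non-increasing resultant length
  rls <- vapply(c(0.1, 0.5, 1, 2), function(s) {
    set.seed(6)
    Mod(mean(exp(1i * sample_target_phase(0, s, 4000))))
  }, 0)
  expect_true(all(diff(rls) < 0))
  # resultant length matches the wrapped-normal matching rule exp(-sd^2/2)
  set.seed(7)
  rl <- Mod(mean(exp(1i * sample_target_phase(0, 0.5, 2e4))))
  expect_equal(rl, exp(-0.5^2 / 2), tolerance = 0.02)
})

test_that("activation masks are Bernoulli(theta) on relevant channels only", {
  m1 <- sample_activations(4, relevant = 2, theta = 1, n_trials = 50)
  expect_true(all(m1[, 2]))
  expect_true(all(!m1[, -2]))
  m0 <- sample_activations(4, 1:4, theta = 0, n_trials = 50)
  expect_false(any(m0))
  set.seed(8)
  m <- sample_activations(32, 1:32, theta = 1 / 6, n_trials = 1e4)
  expect_equal(mean(m), 1 / 6, tolerance = 0.01 / (1 / 6))
  expect_error(sample_activations(4, 1:4, theta = 2, n_trials = 5))
})

test_that("phase reset pulls to the target and entrainment locks the frequency", {
  # g = 0: pure resting update
  expect_equal(phase_reset_entrain(1.0, 0.2, 0, 3, 0.5, FALSE), 1.2)
  expect_equal(phase_reset_entrain(1.0, 0.2, 0, 3, 0.5, TRUE), 1.2)
  # g = 1 before tmax: the gap closes in one step
  nxt <- phase_reset_entrain(1.0, 0.2, 1, 3, 0.5, FALSE)
  expect_equal(wrap_phase(nxt - 3), 0)
  # g = 1 after tmax: increments are exactly the entrained frequency
  expect_equal(phase_reset_entrain(1.0, 0.2, 1, 3, 0.5, TRUE), 1.5)
})

test_that("phase-reset trials converge exactly on the target at tmax when noiseless", {
  cfg <- sim_config(
    spontaneous = tiny_spontaneous(n_trials = 30, n_times = 60, n_channels = 2),
    theta = 1,
    shape = response_shape(delta1 = 0, delta2 = 10, delta3 = 10),
    effects = list(effect_phase_reset(target_mean = c(1, 1 + pi),
                                      target_sd = 0, entrain_freq = 0.2))
  )
  for (s in 1:3) {
    tr <- simulate_trial(cfg, condition = 1, seed = s)
    # gate reaches 1 at tmax (sample index 10, 0-based), so the wrapped
    # distance to the target is 0 there for every channel
    expect_equal(wrap_phase(tr$phase[11, ] - 1), rep(0, 2), tolerance = 1e-9)
  }
})

test_that("additive oscillation is damped by the gate and phased from onset", {
  g <- c(0, 0.5, 1)
  expect_equal(additive_oscillation(g, 2, 0.3, pi / 2, 0:2)[1], 0)
  expect_equal(additive_oscillation(rep(1, 3), 2, 0.3, pi / 2, c(0, 1, 2))[1],
               2 * sin(pi / 2))
  sh <- response_shape(delta1 = 4, delta2 = 6, delta3 = 8)
  tt <- 0:40
  gg <- response_gate(sh, tt)
  y <- additive_oscillation(gg, 1, 0.4, 0.3, tt)
  expect_true(all(y[gg == 0] == 0))
})

test_that("amplitude modulation scales the ongoing amplitude by 1 + g*m", {
  a <- c(2, 2, 2)
  expect_equal(amplitude_modulation(a, c(0, 0.5, 1), 0.1), c(2, 2.1, 2.2))
  # 10% increment at the gate peak; fivefold at m = 4
  expect_equal(amplitude_modulation(2, 1, 0.1), 2.2)
  expect_equal(amplitude_modulation(2, 1, 4) / 2, 5)
  expect_equal(amplitude_modulation(a, rep(0, 3), 0.7), a)
  expect_error(amplitude_modulation(a, c(0, 0, 0), -1.5))
})

test_that("slow response is the gate scaled by a per-trial level", {
  g <- response_gate(response_shape(delta1 = 0, delta2 = 5, delta3 = 20), 0:30)
  expect_equal(additive_slow(g, 0.7), 0.7 * g)
  expect_equal(additive_slow(g, 0), rep(0, 31))
})

test_that("trial composition leaves non-responding channels at their resting output", {
  sp <- tiny_spontaneous(n_trials = 6, n_times = 80, n_channels = 4)
  cfg_off <- sim_config(spontaneous = sp, effects = list())
  cfg_on <- sim_config(
    spontaneous = sp, relevant = c(1, 3), theta = 1,
    shape = response_shape(delta1 = 0, delta2 = 8, delta3 = 10),
    effects = list(effect_additive_osc(phase = c(0, pi)),
                   effect_slow(mean = c(0.3, -0.3)))
  )
  ds_off <- sample_dataset(cfg_off, seed = 21)
  ds_on <- sample_dataset(cfg_on, seed = 21)
  # non-relevant channels (2, 4) are bit-identical to the resting run
  expect_identical(ds_on$data[, , c(2, 4)], ds_off$data[, , c(2, 4)])
  expect_false(identical(ds_on$data[, , 1], ds_off$data[, , 1]))
  # effects only act inside their gate support: before onset all channels
  # match the resting run
  expect_identical(ds_on$data[, 1, ], ds_off$data[, 1, ])
})

test_that("every effect is null wherever its gate is zero", {
  sp <- tiny_spontaneous(n_trials = 4, n_times = 100, n_channels = 3)
  sh <- response_shape(delta1 = 10, delta2 = 10, delta3 = 20)
  cfg <- sim_config(
    spontaneous = sp, theta = 1, shape = sh,
    effects = list(effect_additive_osc(phase = c(0, pi)),
                   effect_amp_mod(m = 1),
                   effect_slow(mean = c(0.5, -0.5),
                               shape = response_shape(delta1 = 10, delta2 = 10,
                                                      delta3 = 30)))
  )
  tr <- simulate_trial(cfg, condition = 1, seed = 9)
  # the gate supports end at sample 40 (osc) and 50 (slow); beyond both,
  # amplitude equals resting amplitude and the additive parts vanish
  expect_true(all(tr$osc[1:10, ] == 0))
  expect_true(all(tr$osc[42:100, ] == 0))
  expect_true(all(tr$slow[1:10, ] == 0))
  expect_true(all(tr$slow[52:100, ] == 0))
})

test_that("phase reset produces cross-trial phase locking at tmax", {
  # tmax is placed 0.4 s into the trial so the resting phase (which starts
  # at 0 by construction) has decohered across trials by the time the
  # reset acts
  sp <- tiny_spontaneous(n_trials = 1, n_times = 80, n_channels = 1)
  cfg_reset <- sim_config(
    spontaneous = sp, theta = 1,
    shape = response_shape(delta1 = 40, delta2 = 10, delta3 = 10),
    effects = list(effect_phase_reset(target_mean = c(0.5, 0.5 + pi),
                                      target_sd = 0.2, entrain_freq = 0.2))
  )
  cfg_rest <- sim_config(spontaneous = sp, effects = list())
  n_per <- 60
  pvals <- vapply(1:5, function(rep_seed) {
    base <- rep_seed * 1000
    ph_reset <- vapply(1:n_per, function(i) {
      wrap_phase(simulate_trial(cfg_reset, 1, seed = base + i)$phase[51, 1])
    }, 0)
    ph_rest <- vapply(1:n_per, function(i) {
      wrap_phase(simulate_trial(cfg_rest, 1, seed = base + i)$phase[51, 1])
    }, 0)
    obs <- plv(ph_reset) - plv(ph_rest)
    pooled <- c(ph_reset, ph_rest)
    set.seed(base)
    null <- vapply(1:499, function(b) {
      idx <- sample(2 * n_per, n_per)
      plv(pooled[idx]) - plv(pooled[-idx])
    }, 0)
    (1 + sum(null >= obs)) / 500
  }, 0)
  expect_true(all(pvals < 0.01))
})

test_that("a slow response with no condition difference carries no information", {
  cfg <- config_osc_slow(n_trials = 80, slow_diff = 0)
  cfg$effects <- cfg$effects[-1]  # slow response only
  ds <- sample_dataset(cfg, seed = 13)
  tg <- compute_tgm(ds, n_folds = 5, seed = 13)
  expect_equal(mean(tg$accuracy), 0.5, tolerance = 0.03 / 0.5)
})

test_that("amplitude modulation alone (no phase effect) decodes at chance", {
  # the gate acts 0.5 s into the trial, once the ongoing phase has mixed
  # across trials; without phase locking the amplitude increase of
  # condition 1 carries no linearly decodable mean difference
  sp <- reduced_spontaneous(n_trials = 80)
  cfg <- sim_config(
    spontaneous = sp, theta = 1,
    shape = response_shape(delta1 = 60, delta2 = 8, delta3 = 11),
    effects = list(effect_amp_mod(m = c(2, 0)))
  )
  ds <- sample_dataset(cfg, seed = 14)
  tg <- compute_tgm(ds, n_folds = 5, seed = 14)
  expect_equal(mean(tg$accuracy), 0.5, tolerance = 0.03 / 0.5)
  expect_lt(max(diag(tg$accuracy)), 0.7)
})
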