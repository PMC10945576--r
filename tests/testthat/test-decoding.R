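test_that("LDA separates well-separated blobs perfectly and shuffled labels at chance", {
  set.seed(1)
  n <- 60
  x_tr <- rbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, 10), n))
  y <- rep(1:2, each = n)
  x_te <- rbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, 10), n))
  m <- fit_lda(x_tr, y)
  expect_equal(mean(predict(m, x_te) == y), 1.0)
  # shuffled labels: held-out accuracy within the binomial CI of 0.5
  y_shuf <- sample(y)
  m2 <- fit_lda(x_tr, y_shuf)
  acc <- mean(predict(m2, x_te) == sample(y))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / (2 * n)))
})

test_that("LDA accuracy matches the closed-form Bayes rate in 1-D", {
  # two Gaussians N(0, 1) and N(dmu, 1): Bayes accuracy = pnorm(dmu / 2)
  dmu <- 1.5
  set.seed(2)
  n <- 4000
  x_tr <- matrix(c(rnorm(n), rnorm(n, dmu)), ncol = 1)
  y <- rep(1:2, each = n)
  x_te <- matrix(c(rnorm(n), rnorm(n, dmu)), ncol = 1)
  m <- fit_lda(x_tr, y)
  acc <- mean(predict(m, x_te) == y)
  expect_equal(acc, pnorm(dmu / 2), tolerance = 0.02 / pnorm(dmu / 2))
})

test_that("unshrunk LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(3)
  n <- 100
  x <- rbind(matrix(rnorm(n * 6), n), matrix(rnorm(n * 6, 0.8), n))
  y <- rep(1:2, each = n)
  xt <- matrix(rnorm(50 * 6, 0.4), 50)
  ours <- predict(fit_lda(x, y, shrinkage = 0), xt)
  ref <- as.integer(predict(MASS::lda(x, grouping = y), xt)$class)
  expect_equal(ours, ref)
})

test_that("LDA input contracts are enforced and shrinkage handles singularity", {
  x <- matrix(rnorm(40), 10)
  expect_error(fit_lda(x, rep(1, 10)), "2 classes")
  expect_error(fit_lda(x, c(1, rep(2, 9))), "at least 2 trials")
  # duplicated column makes the covariance singular; analytic shrinkage
  # still yields a usable model
  xs <- cbind(x, x[, 1])
  m <- fit_lda(xs, rep(1:2, each = 5))
  expect_true(all(is.finite(m$w)))
  expect_gt(m$shrinkage, 0)
})

test_that("a no-effect dataset decodes at chance across the whole TGM", {
  cfg <- sim_config(
    spontaneous = tiny_spontaneous(n_trials = 80, n_times = 40,
                                   n_channels = 4),
    effects = list()
  )
  ds <- sample_dataset(cfg, seed = 4)
  tg <- compute_tgm(ds, n_folds = 5, seed = 4)
  expect_true(all(tg$accuracy >= 0 & tg$accuracy <= 1))
  expect_equal(mean(tg$accuracy), 0.5, tolerance = 0.03 / 0.5)
})

test_that("TGM entries aggregate Bernoulli outcomes exactly over folds", {
  cfg <- sim_config(
    spontaneous = tiny_spontaneous(n_trials = 40, n_times = 10,
                                   n_channels = 3),
    effects = list()
  )
  ds <- sample_dataset(cfg, seed = 5)
  n_folds <- 5
  tg <- compute_tgm(ds, n_folds = n_folds, seed = 5)
  # every entry is (number correct) / 40 with 8 held-out trials per fold
  counts <- tg$accuracy * 40
  expect_equal(counts, round(counts), tolerance = 1e-9)
})

test_that("TGM decoding is deterministic given data and seed", {
  cfg <- config_osc_slow(n_trials = 40)
  cfg$spontaneous <- tiny_spontaneous(n_trials = 40, n_times = 30,
                                      n_channels = 16)
  ds <- sample_dataset(cfg, seed = 6)
  t1 <- compute_tgm(ds, n_folds = 4, seed = 9)
  t2 <- compute_tgm(ds, n_folds = 4, seed = 9)
  expect_identical(t1$accuracy, t2$accuracy)
})

test_that("label shuffling destroys above-chance TGM structure", {
  cfg <- config_osc_slow(n_trials = 60, theta = 1)
  ds <- sample_dataset(cfg, seed = 7)
  tg <- compute_tgm(ds, n_folds = 5, seed = 7)
  expect_gt(max(diag(tg$accuracy)), 0.8)  # real structure present
  ds_null <- ds
  set.seed(77)
  ds_null$labels <- sample(ds$labels)
  tg_null <- compute_tgm(ds_null, n_folds = 5, seed = 7)
  # permutation-style null: with labels shuffled the maximum entry drops
  # into the chance band
  expect_lt(max(tg_null$accuracy), 0.5 + 4 * sqrt(0.25 / 60))
  expect_equal(mean(tg_null$accuracy), 0.5, tolerance = 0.03 / 0.5)
})

test_that("deliberate train/test leakage inflates accuracy on null data", {
  cfg <- sim_config(
    spontaneous = tiny_spontaneous(n_trials = 50, n_times = 25,
                                   n_channels = 8),
    effects = list()
  )
  ds <- sample_dataset(cfg, seed = 8)
  honest <- compute_tgm(ds, n_folds = 5, seed = 8)
  leaky <- compute_tgm(ds, n_folds = 5, seed = 8, .resubstitute = TRUE)
  # resubstitution overfits the null data; the honest CV path must not
  expect_gt(mean(diag(leaky$accuracy)) - mean(diag(honest$accuracy)), 0.05)
  expect_equal(mean(diag(honest$accuracy)), 0.5, tolerance = 0.05 / 0.5)
})

test_that("averaging TGMs is entrywise and reduces variance", {
  cfg <- sim_config(
    spontaneous = tiny_spontaneous(n_trials = 30, n_times = 15,
                                   n_channels = 3),
    effects = list()
  )
  ds <- sample_dataset(cfg, seed = 9)
  tg <- compute_tgm(ds, n_folds = 3, seed = 9)
  avg_same <- average_tgms(list(tg, tg, tg))
  expect_equal(avg_same$accuracy, tg$accuracy)
  comp <- tg
  comp$accuracy <- 1 - tg$accuracy
  expect_equal(average_tgms(list(tg, comp))$accuracy,
               matrix(0.5, 15, 15))
  small <- compute_tgm(sample_dataset(sim_config(
    spontaneous = tiny_spontaneous(n_trials = 30, n_times = 10,
                                   n_channels = 3)), seed = 1),
    n_folds = 3, seed = 1)
  expect_error(average_tgms(list(tg, small)), "mismatched")
  # variance reduction: across seeds, the 5-run average has lower
  # entrywise variance than single runs
  runs <- lapply(1:10, function(s) {
    compute_tgm(sample_dataset(cfg, seed = s), n_folds = 3, seed = s)
  })
  singles <- vapply(runs, function(x) x$accuracy[5, 8], 0)
  pairs <- split(runs, rep(1:2, each = 5))
  avgs <- vapply(pairs, function(g) average_tgms(g)$accuracy[5, 8], 0)
  expect_lt(stats::var(avgs), stats::var(singles))
})

test_that("stratified folds keep both classes in every fold", {
  cfg <- sim_config(
    spontaneous = tiny_spontaneous(n_trials = 21, n_times = 10,
                                   n_channels = 2)
  )
  ds <- sample_dataset(cfg, seed = 10)
  tg <- compute_tgm(ds, n_folds = 5, seed = 10)  # 21 trials still stratify
  expect_true(all(is.finite(tg$accuracy)))
  expect_error(compute_tgm(ds, n_folds = 15, seed = 1), "both classes")
})
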