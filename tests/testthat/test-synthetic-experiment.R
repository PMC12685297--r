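test_that("population sampling respects the tuning split and is seeded", {
  cfg <- population_config(n_cells = 10, frac_pref_16k = 1, seed = 1)
  pop <- sample_population(cfg)
  expect_true(all(pop$truth$amp_16k > pop$truth$amp_54k))
  expect_true(all(pop$cells$x_um >= 0 & pop$cells$x_um <= 550))

  pop2 <- sample_population(cfg)
  expect_identical(pop, pop2)

  # preferring-cell fraction within 2 binomial SEs at large n
  cfg_big <- population_config(n_cells = 10000, frac_pref_16k = 0.5,
                               seed = 11)
  frac <- mean(sample_population(cfg_big)$truth$prefers_16k)
  expect_lt(abs(frac - 0.5), 2 * sqrt(0.25 / 10000))
})

test_that("targets are the strongest co-tuned cells; shortfall errors", {
  cfg <- population_config(n_cells = 50, n_targets = 5, seed = 2)
  pop <- sample_population(cfg)
  tr <- pop$truth
  elig <- tr$id[tr$amp_16k > tr$amp_54k]
  expected <- sort(elig[order(-tr$amp_16k[match(elig, tr$id)],
                              elig)][1:5])
  expect_identical(tr$id[tr$is_target], expected)
  expect_true(all(tr$delta_n[tr$is_target] == 0))

  cfg_bad <- population_config(n_cells = 4, n_targets = 4,
                               frac_pref_16k = 0, seed = 3)
  expect_error(sample_population(cfg_bad), "co-tuned")
})

test_that("noiseless evoked responses equal the analytic kernel prediction", {
  pc <- noiseless_population(n_cells = 3, seed = 5)
  proto <- protocol_config(list(session_spec("baseline", 16, 1, c(5, 5))))
  b <- simulate_experiment(pc, proto, condition = "control", seed = 7)
  tens <- epoch_trials(
    neuropil_correct(b$sessions$baseline$F, b$sessions$baseline$Fneu),
    b$sessions$baseline$events, b$frame_rate_hz)
  w <- window_stat(tens, c(0.16, 0.66), "mean")
  pred <- b$truth$amp_16k * kernel_window_mean(0.8, c(0.16, 0.66), 30)
  expect_lt(max(abs(w[, 1] - pred)), 1e-9)
})

test_that("zero amplitudes and zero noise give identically flat dF/F", {
  # zero out true amplitudes after target selection so synthesis sees a
  # population with no evoked signal at all
  pop <- sample_population(population_config(
    n_cells = 2, n_targets = 1, frac_pref_16k = 1, noise_sd = 0,
    neuropil_noise_sd = 0, trial_gain_sd = 0, adapt = FALSE,
    amp_mean = c(0.5, 0.1), amp_sd = c(0, 0), seed = 1))
  pop$truth$amp_16k[] <- 0
  pop$truth$amp_54k[] <- 0
  pop$truth$amp_4k[] <- 0
  s <- synthesize_session(pop, session_spec("baseline", c(16, 54), 3,
                                            c(2, 2)), 30, seed = 4)
  fc <- neuropil_correct(s$F, s$Fneu)
  tens <- epoch_trials(fc, s$events, 30)
  expect_lt(max(abs(tens$dff)), 1e-12)
})

test_that("default protocol produces 30 onsets per tone within ISI bounds", {
  pc <- population_config(n_cells = 5, n_targets = 1, seed = 9)
  proto <- default_protocol()
  b <- simulate_experiment(pc, proto, condition = "control", seed = 13)
  ev <- b$sessions$baseline$events
  expect_equal(as.vector(table(ev$tone_khz)), c(30, 30))
  isi <- diff(ev$onset_s)
  snap <- 1 / b$frame_rate_hz   # onsets snapped to the frame grid
  expect_true(all(isi >= 5.8 - snap & isi <= 6.5 + snap))
  expect_true(all(diff(ev$onset_s) > 0))
  sel <- b$sessions$selection$events
  expect_equal(as.vector(table(sel$tone_khz)), c(10, 10, 10))
})

test_that("bundles are deterministic under a seed and suppression follows the condition", {
  pc <- population_config(n_cells = 12, n_targets = 2, seed = 21)
  proto <- tiny_protocol()
  b1 <- simulate_experiment(pc, proto, condition = "stim16", seed = 77)
  b2 <- simulate_experiment(pc, proto, condition = "stim16", seed = 77)
  expect_identical(b1, b2)

  ctrl <- simulate_experiment(pc, proto, condition = "control", seed = 77)
  expect_false(any(ctrl$truth$suppressed))
  expect_true(all(ctrl$truth$delta_n == 0))
  expect_false(any(ctrl$cells$is_target))

  # active condition: suppressed set is exactly the non-target co-tuned cells
  expect_true(all(b1$truth$suppressed ==
                    (b1$truth$cotuned_with_target & !b1$truth$is_target)))
})

test_that("bundle write/read round trip is lossless and validates inputs", {
  pc <- population_config(n_cells = 3, n_targets = 1, frac_pref_16k = 1,
                          seed = 31)
  proto <- protocol_config(list(
    session_spec("baseline", c(16, 54), 1, c(2, 2))))
  b <- simulate_experiment(pc, proto, condition = "stim16", seed = 33)
  d <- withr::local_tempdir()
  write_bundle(b, d)
  b2 <- read_bundle(d)
  expect_equal(b2$cells, b$cells)
  expect_equal(b2$truth, b$truth, tolerance = 1e-12)
  expect_equal(b2$sessions$baseline$F, b$sessions$baseline$F,
               tolerance = 1e-12)
  expect_equal(b2$sessions$baseline$events, b$sessions$baseline$events,
               tolerance = 1e-12)
  expect_identical(b2$condition, b$condition)

  file.remove(file.path(d, "Fneu_baseline.csv"))
  expect_error(read_bundle(d), "Fneu_baseline")
})
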