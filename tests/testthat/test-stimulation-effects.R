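test_that("session effects difference matched keys and telescope", {
  a <- data.frame(cell_id = rep(1:3, each = 2), tone_khz = rep(c(16, 54), 3),
                  amp = runif(6))
  expect_true(all(session_effect(a, a)$effect == 0))

  set.seed(11)
  b <- a; b$amp <- runif(6); c3 <- a; c3$amp <- runif(6)
  expect_equal(session_effect(a, b)$effect, -session_effect(b, a)$effect)
  # telescoping: (stim - base) + (post - stim) = post - base
  expect_equal(session_effect(b, a)$effect + session_effect(c3, b)$effect,
               session_effect(c3, a)$effect)

  bad <- b[-1, ]
  expect_error(session_effect(a, bad), "unmatched")
})

test_that("photostimulation boost is recovered exactly without noise", {
  pc <- noiseless_population(n_cells = 6, n_targets = 2, boost = 0.4,
                             seed = 23)
  proto <- two_session_protocol(repeats = 2, isi = c(25, 25))
  b <- simulate_experiment(pc, proto, condition = "stim16", regime = "none",
                           seed = 29)
  an <- suppressWarnings(analyze_experiment(list(f = b)))
  K <- kernel_window_mean(0.8)
  trg <- an$effects[an$effects$is_target, ]
  expect_lt(max(abs(trg$stim_effect - 0.4 * K)), 1e-9)
  nt <- an$effects[!an$effects$is_target, ]
  expect_lt(max(abs(nt$stim_effect)), 1e-9)
})

test_that("near-target exclusion uses a strict 20-um boundary", {
  targets <- rbind(c(0, 0), c(100, 0))
  cells <- rbind(c(10, 0), c(25, 25), c(20, 0), c(120, 0))
  flags <- exclude_near_targets(cells, targets)
  expect_identical(flags, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("distance modes agree with hand geometry", {
  targets <- rbind(c(0, 0), c(2, 0))
  cell <- matrix(c(1, 1), 1)
  expect_equal(distance_to_targets(cell, targets, "centroid"), 1)
  expect_equal(distance_to_targets(cell, targets, "nearest"), sqrt(2))
  expect_equal(distance_to_targets(matrix(c(1, 0), 1), targets, "centroid"),
               0)
})

test_that("activation summary counts positive effects per FOV", {
  eff <- data.frame(fov = "a", effect = c(0.1, -0.1, 0.2, 0.3, 0.5))
  s <- target_activation_summary(eff)
  expect_equal(s$prop_activated, 0.8)
  expect_equal(s$per_fov$mean_effect, 0.2)

  # symmetric-noise generator (no boost): pooled proportion ~ 0.5
  proto <- two_session_protocol(repeats = 3, isi = c(2, 2))
  effs <- lapply(1:60, function(i) {
    pc <- population_config(n_cells = 12, n_targets = 2, adapt = FALSE,
                            frac_pref_16k = 0.8, boost = 0, seed = 100 + i)
    b <- simulate_experiment(pc, proto, condition = "stim16",
                             regime = "none", seed = 500 + i)
    an <- analyze_experiment(list(f = b))
    trg <- an$effects[an$effects$is_target, ]
    data.frame(fov = i, effect = tapply(trg$stim_effect, trg$cell_id, mean))
  })
  pooled <- target_activation_summary(do.call(rbind, effs))
  n <- 120
  expect_lt(abs(pooled$prop_activated - 0.5), 2.5 * sqrt(0.25 / n))
})

test_that("permutation p-values follow the add-one formula", {
  fr <- 30
  # strong locked response: observed far above any surrogate
  pc <- population_config(n_cells = 1, n_targets = 1, frac_pref_16k = 1,
                          noise_sd = 0.01, neuropil_noise_sd = 0,
                          trial_gain_sd = 0, adapt = FALSE,
                          amp_mean = c(0.5, 0.1), amp_sd = c(0, 0),
                          seed = 31)
  proto <- protocol_config(list(session_spec("baseline", 16, 4, c(4, 4))))
  b <- simulate_experiment(pc, proto, condition = "control", seed = 37)
  fc <- neuropil_correct(b$sessions$baseline$F, b$sessions$baseline$Fneu)
  pt <- permutation_null(fc, b$sessions$baseline$events, fr, n_iter = 100,
                         seed = 5)
  expect_equal(pt$p, 1 / 101)
  expect_true(all(pt$null < pt$observed))

  # completely flat trace: every surrogate ties the observed statistic
  flat <- matrix(100, 1, 1200)
  ev <- data.frame(onset_s = c(5, 15), tone_khz = 16)
  pt0 <- permutation_null(flat, ev, fr, n_iter = 50, seed = 6)
  expect_equal(pt0$p, 1)

  # saturated session: no event-free time left
  busy <- data.frame(onset_s = seq(1, 38, by = 1.1), tone_khz = 16)
  expect_error(permutation_null(flat, busy, fr, n_iter = 10, seed = 7),
               "event-free")
})

test_that("trial effects recover constant suppression exactly", {
  delta <- 0.1
  pc <- noiseless_population(n_cells = 8, n_targets = 2, delta = delta,
                             boost = 0.3, seed = 41)
  proto <- two_session_protocol(repeats = 5, isi = c(25, 25))
  b <- simulate_experiment(pc, proto, condition = "stim16", seed = 43)
  an <- suppressWarnings(analyze_experiment(list(f = b)))
  te <- an$trial_effects
  K <- kernel_window_mean(0.8)
  sup <- te[te$group == "pref16" & te$tone_khz == 16, ]
  expect_equal(nrow(sup), 5)
  expect_lt(max(abs(sup$effect + delta * K)), 1e-9)
  other <- te[te$group == "pref16" & te$tone_khz == 54, ]
  expect_lt(max(abs(other$effect)), 1e-9)
})
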