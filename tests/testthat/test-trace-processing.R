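test_that("neuropil correction is exact, linear, and shape-checked", {
  expect_equal(neuropil_correct(c(100, 110), c(50, 50)), c(60, 70))
  f <- c(1.5, 2.5, 3)
  expect_equal(neuropil_correct(f, rep(0, 3)), f)

  set.seed(41)
  f <- runif(1000, 50, 150)
  fneu <- runif(1000, 10, 40)
  r <- 0.73
  oracle <- vapply(seq_along(f), function(i) f[i] - r * fneu[i], numeric(1))
  expect_lt(max(abs(neuropil_correct(f, fneu, r) - oracle)), 1e-12)

  # linear in both arguments
  a <- runif(50); b <- runif(50)
  expect_equal(neuropil_correct(f[1:50] + a, fneu[1:50] + b, r),
               neuropil_correct(f[1:50], fneu[1:50], r) +
                 neuropil_correct(a, b, r))
  expect_error(neuropil_correct(1:5, 1:4), "shape")
})

test_that("dF/F normalisation follows its defining ratio", {
  fr <- 30
  const <- rep(2.5, 90)
  d <- compute_dff(const, onset_s = 2, frame_rate_hz = fr)
  expect_true(all(d == 0))

  tr <- rep(1, 90); tr[70] <- 1.5
  d <- compute_dff(tr, onset_s = 2, frame_rate_hz = fr)
  expect_equal(d[70], 0.5)

  expect_error(compute_dff(rep(-1, 90), 2, fr), "non-positive")

  # invariance under positive rescaling of the raw trace
  set.seed(5)
  tr <- 100 + cumsum(rnorm(300, 0, 0.5))
  expect_equal(as.numeric(compute_dff(3.7 * tr, 5, fr)),
               as.numeric(compute_dff(tr, 5, fr)), tolerance = 1e-12)
})

test_that("epoching yields the documented frame counts and is equivariant", {
  fr <- 30
  f <- matrix(100 + rnorm(2 * 600), 2)
  ev <- data.frame(onset_s = c(5, 12), tone_khz = c(16, 54))
  tens <- epoch_trials(f, ev, fr, pre = 0.3, post = 1.0)
  expect_equal(dim(tens$dff), c(2, 2, 39))

  empty <- epoch_trials(f, ev[0, ], fr)
  expect_equal(dim(empty$dff)[2], 0)

  shuf <- epoch_trials(f, ev[2:1, ], fr)
  expect_equal(shuf$dff[, 1, ], tens$dff[, 2, ])
  expect_equal(shuf$tone_khz, rev(tens$tone_khz))

  expect_error(epoch_trials(f, data.frame(onset_s = 19.9, tone_khz = 16),
                            fr), "out of bounds")
})

test_that("baseline means of self-normalised trials are exactly zero and QC flags fire", {
  fr <- 30
  f <- matrix(100 + rnorm(3 * 600), 3)
  f[2, ] <- -5   # pathological cell: negative baseline
  ev <- data.frame(onset_s = c(5, 12), tone_khz = c(16, 16))
  tens <- epoch_trials(f, ev, fr)
  base <- window_stat(tens, c(-0.3, 0), "mean")
  expect_lt(max(abs(base[c(1, 3), ])), 1e-13)
  expect_true(all(is.na(tens$dff[2, , ])))
  expect_true(all(tens$qc$cell == 2))
  expect_match(tens$qc$reason[1], "non-positive")
})

test_that("window statistics match direct computation and the analytic kernel", {
  fr <- 30
  f <- matrix(100, 1, 300)
  ev <- data.frame(onset_s = 5, tone_khz = 16)
  tens <- epoch_trials(f, ev, fr)
  tens$dff[1, 1, ] <- 0.3
  expect_equal(window_stat(tens, c(0.16, 0.66), "mean")[1, 1], 0.3)
  expect_equal(window_stat(tens, c(0.16, 0.66), "peak")[1, 1], 0.3)
  tens$dff[1, 1, ] <- seq(0, 1, length.out = 39)
  expect_equal(window_stat(tens, c(-0.3, 1.0), "peak")[1, 1], 1)

  # noiseless generator trial: mean over the evoked window equals the
  # analytic kernel mean scaled by the true amplitude
  pc <- noiseless_population(n_cells = 2, seed = 8)
  proto <- protocol_config(list(session_spec("baseline", 16, 1, c(4, 4))))
  b <- simulate_experiment(pc, proto, condition = "control", seed = 15)
  tens <- epoch_trials(
    neuropil_correct(b$sessions$baseline$F, b$sessions$baseline$Fneu),
    b$sessions$baseline$events, b$frame_rate_hz)
  got <- window_stat(tens, c(0.16, 0.66), "mean")[, 1]
  want <- b$truth$amp_16k * kernel_window_mean(0.8)
  expect_lt(max(abs(got - want)), 1e-9)

  expect_error(window_stat(tens, c(2, 3)), "not covered")
})
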