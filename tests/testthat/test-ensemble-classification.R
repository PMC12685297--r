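test_that("the 2-SD responsiveness criterion behaves at and around threshold", {
  expect_true(is_sound_responsive(rep(1, 5), rep(0, 5)))
  expect_false(is_sound_responsive(rep(0.2, 5), rep(0.2, 5)))
  expect_error(is_sound_responsive(1, c(0, 0)), "2 trials")

  # constructed baselines with known mean/SD: evoked at mean + k*SD crosses
  # the criterion only for k > 2
  b <- c(-0.1, 0.1, -0.1, 0.1, -0.1, 0.1)
  thr <- mean(b) + 2 * sd(b)
  for (k in c(1, 3)) {
    ev <- rep(mean(b) + k * sd(b), 6)
    expect_identical(is_sound_responsive(ev, b), k > 2)
  }
})

test_that("preference index is the signed difference and antisymmetric", {
  expect_equal(preference_index(0.5, 0.2), 0.3)
  expect_equal(preference_index(0.4, 0.4), 0)
  set.seed(2)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(preference_index(a, b), -preference_index(b, a))
  expect_error(preference_index(NA_real_, 1), "finite")
})

test_that("group assignment partitions by the sign of the index", {
  expect_identical(assign_group(0.3), "pref16")
  expect_identical(assign_group(-0.01), "pref54")
  expect_identical(assign_group(0), "none")
  set.seed(3)
  idx <- c(rnorm(50), 0)
  g <- assign_group(idx)
  expect_true(all((g == "pref16") == (idx > 0)))
  expect_true(all((g == "pref54") == (idx < 0)))
})

test_that("selectivity tertiles split evenly and prune extreme outliers", {
  bins <- selectivity_bins(seq(1, 9))
  expect_equal(as.vector(table(bins)[c("low", "mid", "high")]), c(3, 3, 3))
  expect_identical(as.character(bins[1:3]), rep("low", 3))
  expect_identical(as.character(bins[7:9]), rep("high", 3))

  set.seed(4)
  x <- rnorm(100)
  x[100] <- median(x) + 10 * sd(x)
  bins <- selectivity_bins(x)
  expect_identical(as.character(bins[100]), "excluded_outlier")
  # survivors still split near-evenly
  sizes <- table(bins)[c("low", "mid", "high")]
  expect_lte(diff(range(sizes)), 1)

  expect_warning(b2 <- selectivity_bins(rep(0.5, 6)), "degenerate")
  expect_true(all(b2 == "mid"))
})

test_that("outlier pruning removes about 1% on a matched heavy-tailed mixture", {
  set.seed(6)
  x <- c(rnorm(3000), rnorm(36, 0, 12))   # ~1.2% gross contamination
  frac <- mean(selectivity_bins(x) == "excluded_outlier")
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.02)
})

test_that("target selection keeps single-tone responders ranked by amplitude", {
  resp <- data.frame(id = 1:5, responsive_16 = TRUE, responsive_54 = FALSE,
                     responsive_4 = FALSE,
                     evoked_16 = c(0.2, 0.5, 0.3, 0.9, 0.1))
  expect_identical(select_target_cells(resp, 16, n = 5), 1:5)

  # tie at the cut: lower id wins
  resp$evoked_16 <- c(0.5, 0.5, 0.5, 0.5, 0.4)
  expect_identical(select_target_cells(resp, 16, n = 4), 1:4)

  # brute-force oracle on 100 cells with mixed responsiveness
  set.seed(7)
  resp <- data.frame(id = 1:100,
                     responsive_16 = runif(100) < 0.7,
                     responsive_54 = runif(100) < 0.3,
                     responsive_4 = runif(100) < 0.2,
                     evoked_16 = round(runif(100), 2))
  elig <- resp[resp$responsive_16 & !resp$responsive_54 & !resp$responsive_4, ]
  oracle <- sort(elig$id[order(-elig$evoked_16, elig$id)][1:5])
  expect_identical(select_target_cells(resp, 16), oracle)

  few <- data.frame(id = 1:4, responsive_16 = c(TRUE, TRUE, TRUE, FALSE),
                    responsive_54 = FALSE, responsive_4 = FALSE,
                    evoked_16 = c(0.4, 0.3, 0.2, 0.9))
  expect_error(select_target_cells(few, 16), "short by")
})

test_that("classify_cells profiles generator cells faithfully", {
  pc <- population_config(n_cells = 60, n_targets = 3, seed = 17)
  proto <- two_session_protocol(repeats = 15)
  b <- simulate_experiment(pc, proto, condition = "control", seed = 19)
  tens <- epoch_trials(
    neuropil_correct(b$sessions$baseline$F, b$sessions$baseline$Fneu),
    b$sessions$baseline$events, b$frame_rate_hz)
  prof <- classify_cells(tens)
  expect_equal(nrow(prof), 60)
  expect_equal(prof$preference_index, prof$evoked_16 - prof$evoked_54)
  # groups partition responsive cells
  expect_true(all(prof$group[!prof$responsive] == "none"))
  expect_true(all(prof$group %in% c("pref16", "pref54", "none")))
  # with well-separated amplitude distributions the measured group matches
  # the ground-truth tuning for responsive cells
  resp <- prof$responsive
  expect_gt(mean((prof$group[resp] == "pref16") ==
                   b$truth$prefers_16k[resp]), 0.9)
})
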