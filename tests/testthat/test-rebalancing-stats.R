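# Constructed effect table with controllable cell means and FOV offsets.
make_effect_data <- function(n_fov = 6, cells_per_cell = 8, sd = 1,
                             fov_sd = 0.1,
                             mean_fn = function(g, cond, tone) 0,
                             conditions = c("control", "stim16", "stim54"),
                             seed = NULL) {
  gen <- function() {
    fovs <- sprintf("f%02d", seq_len(n_fov))
    cond_of_fov <- rep_len(conditions, n_fov)
    fov_eff <- rnorm(n_fov, 0, fov_sd)
    rows <- list()
    for (i in seq_len(n_fov)) {
      grid <- expand.grid(cell = seq_len(cells_per_cell),
                          tone_khz = c(16, 54),
                          group = c("pref16", "pref54"),
                          stringsAsFactors = FALSE)
      grid$fov <- fovs[i]
      grid$condition <- cond_of_fov[i]
      mu <- mapply(mean_fn, grid$group, grid$condition, grid$tone_khz)
      grid$effect <- mu + fov_eff[i] + rnorm(nrow(grid), 0, sd)
      rows[[i]] <- grid
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) gen() else cotune:::with_seed(seed, gen())
}

test_that("mixed ANOVA flags degenerate input and detects a built-in interaction", {
  d <- make_effect_data(seed = 1)
  d$effect <- 1   # constant response
  res <- quiet_anova(d)
  expect_true(all(res$terms$F[is.finite(res$terms$F)] < 1e-6))

  # strong three-way interaction: co-tuned group suppressed at the matched
  # tone in its matching stimulation condition only
  mean_fn <- function(g, cond, tone) {
    if (cond == "stim16" && g == "pref16" && tone == 16) return(-0.8)
    if (cond == "stim54" && g == "pref54" && tone == 54) return(-0.8)
    0
  }
  d <- make_effect_data(n_fov = 9, cells_per_cell = 30, sd = 0.5,
                        mean_fn = mean_fn, seed = 2)
  res <- quiet_anova(d)
  p3 <- res$terms$p[res$terms$term == "group:condition:tone_khz"]
  expect_lt(p3, 0.05)
  expect_true(all(res$terms$p >= 0 & res$terms$p <= 1))
  expect_true(all(res$terms$df1 > 0))
})

test_that("EMM contrasts recover built-in condition differences", {
  # near-noiseless: contrast estimates converge on the built-in difference
  mean_fn <- function(g, cond, tone)
    if (cond == "stim16" && g == "pref16" && tone == 16) -0.5 else 0
  d <- make_effect_data(n_fov = 6, cells_per_cell = 20, sd = 1e-4,
                        fov_sd = 0, mean_fn = mean_fn, seed = 3,
                        conditions = c("control", "stim16"))
  res <- quiet_anova(d)
  ct <- emm_contrasts(res, specs = ~ condition | group * tone_khz)$contrasts
  hit <- ct[ct$group == "pref16" & ct$tone_khz == 16, ]
  expect_equal(hit$estimate, 0.5, tolerance = 1e-2)
  off <- ct[!(ct$group == "pref16" & ct$tone_khz == 16), ]
  expect_lt(max(abs(off$estimate)), 1e-2)

  # identical conditions: adjusted p near 1; and Tukey adjustment is
  # never more liberal than unadjusted
  d0 <- make_effect_data(n_fov = 6, cells_per_cell = 10, sd = 1, seed = 4)
  res0 <- quiet_anova(d0)
  tuk <- emm_contrasts(res0)$contrasts
  raw <- emm_contrasts(res0, adjust = "none")$contrasts
  expect_true(all(tuk$p.value >= raw$p.value - 1e-12))
})

test_that("Holm ladder matches p.adjust and flags only the built-in bin", {
  expect_equal(stats::p.adjust(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))

  d <- make_effect_data(n_fov = 6, cells_per_cell = 30, sd = 0.3,
                        fov_sd = 0, seed = 5,
                        conditions = c("control", "stim16"))
  set.seed(6)
  d$selectivity_bin <- sample(c("low", "mid", "high"), nrow(d), TRUE)
  sel <- d$group == "pref16" & d$selectivity_bin == "high" &
    d$condition == "stim16"
  d$effect[sel] <- d$effect[sel] - 0.8
  ph <- tertile_posthoc(d)
  hi <- ph[ph$group == "pref16" & ph$bin == "high", ]
  expect_true(all(hi$p_holm < 0.05))
  lo <- ph[ph$group == "pref16" & ph$bin %in% c("low", "mid"), ]
  expect_true(all(lo$p_holm > 0.05))
  # monotone: adjusted never below raw
  expect_true(all(ph$p_holm >= ph$p - 1e-12, na.rm = TRUE))

  d1 <- d[d$condition == "stim16", ]
  ph1 <- tertile_posthoc(d1)
  expect_true(all(grepl("single condition", ph1$note)))

  expect_equal(tertile_posthoc(within(d, effect <- 0))$p_holm[1], 1)
})

test_that("three-parameter decay fit recovers exact curves and degenerates safely", {
  x <- seq(0, 10, length.out = 40)
  y <- 2 + 3 * exp(-0.5 * x)
  fit <- fit_three_param_decay(x, y)
  expect_equal(unname(coef(fit)), c(2, 3, 0.5), tolerance = 1e-6)
  expect_lt(fit$ss, 1e-12)
  expect_equal(predict(fit, c(0, 10)), c(5, 2 + 3 * exp(-5)),
               tolerance = 1e-5)

  cst <- fit_three_param_decay(x, rep(1.3, 40))
  expect_equal(unname(coef(cst)["plateau"]), 1.3, tolerance = 1e-9)
  expect_equal(unname(coef(cst)["span"]), 0)

  # nested-model guarantee: decay SS never above constant SS
  set.seed(7)
  for (i in 1:20) {
    yy <- rnorm(15)
    expect_lte(fit_three_param_decay(x[1:15], yy)$ss,
               fit_constant_model(x[1:15], yy)$ss + 1e-12)
  }
})

test_that("extra sum-of-squares F statistic follows its formula", {
  f0 <- structure(list(ss = 5, df = 27L, n = 30L), class = "decay_fit")
  n0 <- structure(list(ss = 10, df = 29L, n = 30L), class = "constant_fit")
  ft <- extra_ss_ftest(f0, n0)
  expect_equal(ft$F, 13.5)
  expect_equal(ft$p, pf(13.5, 2, 27, lower.tail = FALSE))

  n1 <- structure(list(ss = 5, df = 29L, n = 30L), class = "constant_fit")
  ft1 <- extra_ss_ftest(f0, n1)
  expect_equal(ft1$F, 0)
  expect_equal(ft1$p, 1)

  perfect <- structure(list(ss = 0, df = 27L, n = 30L), class = "decay_fit")
  ftp <- extra_ss_ftest(perfect, n0)
  expect_equal(ftp$p, 0)
  expect_true(ftp$perfect_fit)

  f2 <- structure(list(ss = 5, df = 27L, n = 31L), class = "decay_fit")
  expect_error(extra_ss_ftest(f2, n0), "same data")
})
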