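test_that("dispersion with tau = 0 is the identity", {
  bc <- blood_curve(seq(0, 5, by = 1 / 60), stats::runif(301), "auto")
  expect_identical(dispersion_convolve(bc, 0)$activity, bc$activity)
  expect_identical(dispersion_correct(bc, dispersion_model(tau_s = 0))$activity,
                   bc$activity)
})

test_that("deconvolution recovers a dispersed step", {
  dt <- 1 / 60
  tt <- seq(0, 5, by = dt)
  t0 <- 1
  h <- 8
  g_true <- ifelse(tt >= t0, h, 0)
  m <- dispersion_convolve(blood_curve(tt, g_true, "auto"), 16)
  rec <- dispersion_correct(m, dispersion_model(tau_s = 16))
  rms <- sqrt(mean((rec$activity - g_true)^2))
  expect_lt(rms / h, 0.01)
  # against the continuous-kernel closed form the only disagreement is the
  # intrinsically ambiguous jump sample itself
  m_cont <- ifelse(tt >= t0, h * (1 - exp(-(tt - t0) / (16 / 60))), 0)
  rec2 <- dispersion_correct(blood_curve(tt, m_cont, "auto"),
                             dispersion_model(tau_s = 16))
  off_jump <- abs(tt - t0) > 1.5 * dt
  expect_lt(sqrt(mean((rec2$activity - g_true)[off_jump]^2)) / h, 0.01)
})

test_that("convolve-then-deconvolve round trip is tight for smooth curves", {
  dt <- 1 / 60
  tt <- seq(0, 20, by = dt)
  curves <- list(
    100 * pmin(tt / 0.75, 1) * exp(-0.25 * pmax(tt - 0.75, 0)),
    50 * (1 - exp(-2 * tt)) * exp(-0.05 * tt),
    rep(3, length(tt))
  )
  for (tau in c(8, 16, 30)) {
    for (cv in curves) {
      bc <- blood_curve(tt, cv, "auto")
      m <- dispersion_convolve(bc, tau)
      g <- dispersion_correct(m, dispersion_model(tau_s = tau))
      # deconv recovers the original
      expect_lt(sqrt(mean((g$activity - cv)^2)) / max(cv), 0.005)
      # re-convolving the output reproduces the measurement
      m2 <- dispersion_convolve(g, tau)
      expect_lt(sqrt(mean((m2$activity - m$activity)^2)) / max(m$activity), 0.005)
    }
  }
})

test_that("iterative and analytic-inverse deconvolution agree on smooth data", {
  dt <- 1 / 60
  tt <- seq(0, 20, by = dt)
  cv <- 80 * pmin(tt / 1, 1) * exp(-0.3 * pmax(tt - 1, 0)) + 5
  m <- dispersion_convolve(blood_curve(tt, cv, "auto"), 16)
  g_it <- dispersion_correct(m, dispersion_model(tau_s = 16))
  g_an <- dispersion_correct(m, dispersion_model(tau_s = 16), method = "direct")
  # the analytic inverse differs appreciably only at the bolus-onset kink
  expect_lt(sqrt(mean((g_it$activity - g_an$activity)^2)) / max(cv), 0.005)
})

test_that("bi-exponential blood-to-plasma fit recovers known coefficients", {
  tt <- c(2.5, 7, 12, 15, 30, 45, 60, 90, 120)
  truth <- b2p_model(0.4, 0.25, 0.8, 0.002)
  fit <- fit_blood_to_plasma(tt, predict(truth, tt))
  grid <- seq(0, 125, by = 0.5)
  expect_lt(max(abs(predict(fit, grid) - predict(truth, grid)) /
                  predict(truth, grid)), 1e-4)
})

test_that("constant ratios give a constant predicted curve", {
  fit <- fit_blood_to_plasma(c(1, 10, 50, 100), rep(1.2, 4))
  expect_lt(max(abs(predict(fit, seq(0, 120, 5)) - 1.2)), 1e-6)
})

test_that("blood-to-plasma fit input validation", {
  expect_error(fit_blood_to_plasma(c(1, 2, 3), c(1, 1, 1)), "4 observations")
  expect_error(fit_blood_to_plasma(1:4, c(1, 1, -0.1, 1)), "positive")
})

test_that("Hill parent-fraction fit recovers a known model", {
  tt <- c(2.5, 7, 12, 15, 30, 45, 60, 90, 120)
  truth <- hill_model(0.9, 2, 400)
  fit <- fit_hill_parent_fraction(tt, predict(truth, tt))
  grid <- seq(0, 125, by = 0.5)
  expect_lt(max(abs(predict(fit, grid) - predict(truth, grid))), 1e-3)
})

test_that("all-parent observations give no metabolism (a = 0, fp == 1)", {
  fit <- fit_hill_parent_fraction(c(1, 10, 60, 120), rep(1, 4))
  expect_equal(fit$a, 0)
  expect_equal(predict(fit, c(0, 30, 125)), c(1, 1, 1))
})

test_that("parent fractions outside [0, 1] are rejected", {
  expect_error(fit_hill_parent_fraction(1:4, c(1, 0.9, 1.3, 0.5)), "\\[0, 1\\]")
})

test_that("fitted parent-fraction curves are monotone non-increasing in [0, 1]", {
  set.seed(31)
  tt <- c(2.5, 7, 12, 15, 30, 45, 60, 90, 120)
  grid <- seq(0, 125, by = 0.25)
  for (i in 1:10) {
    truth <- hill_model(stats::runif(1, 0.5, 1), stats::runif(1, 0.8, 3),
                        stats::runif(1, 50, 1500))
    obs <- pmin(pmax(predict(truth, tt) + stats::rnorm(9, 0, 0.02), 0), 1)
    fit <- fit_hill_parent_fraction(tt, obs)
    fp <- predict(fit, grid)
    expect_true(all(fp >= 0 & fp <= 1))
    expect_true(all(diff(fp) <= 1e-12))
    expect_equal(predict(fit, 0), 1)
  }
})

test_that("merging uses the auto curve on its support and needs a tail beyond", {
  tt <- seq(0, 22.5, by = 1 / 60)
  act <- 10 * exp(-0.05 * tt) + 2
  auto <- blood_curve(tt, act, "auto")
  # grid inside the auto window: merged equals auto
  g1 <- merge_blood_samples(auto, NULL, grid = seq(0, 22, by = 0.25))
  expect_equal(g1$activity, stats::approx(tt, act, seq(0, 22, by = 0.25))$y,
               tolerance = 1e-9)
  # no manual samples beyond the window: extrapolation must error
  expect_error(merge_blood_samples(auto, NULL, grid = seq(0, 60, by = 0.5)),
               "tail")
})

test_that("a manual sample at the auto boundary rescales for continuity", {
  tt <- seq(0, 22.5, by = 1 / 60)
  act <- 10 * exp(-0.05 * tt)
  auto <- blood_curve(tt, 0.8 * act, "auto")  # mis-calibrated sampler
  manual <- data.frame(time = c(22.5, 30, 45, 60, 90),
                       activity = 10 * exp(-0.05 * c(22.5, 30, 45, 60, 90)))
  merged <- merge_blood_samples(auto, manual, grid = seq(0, 90, by = 0.5))
  # scaling to the first overlapping manual sample restores the true level
  expect_equal(merged$activity[merged$time == 10], 10 * exp(-0.5),
               tolerance = 1e-6)
  # continuity at the boundary
  i <- which.min(abs(merged$time - 22.5))
  expect_lt(abs(merged$activity[i] - 10 * exp(-0.05 * 22.5)), 0.05)
})

test_that("plasma input construction applies ratio and parent-fraction models", {
  tt <- seq(0, 10, by = 1 / 60)
  wb <- 20 * exp(-0.1 * tt) + 1
  bc <- blood_curve(tt, wb, "auto")
  ident <- b2p_model(1, 0, 0, 0)
  no_met <- hill_model(0, 1, 1)
  inp <- build_plasma_input(bc, ident, no_met, grid = tt)
  expect_equal(inp$cp, wb, tolerance = 1e-12)
  # constant half parent fraction scales cp by 0.5
  half <- structure(list(a = 0.5, b = 1, c = 1e-12), class = "hill_model")
  inp2 <- build_plasma_input(bc, ident, half, grid = tt)
  expect_equal(inp2$cp[-1], wb[-1] / 2, tolerance = 1e-6)
  # metabolite correction only removes signal: cp <= plasma
  mods <- feppa_plasma_models()
  inp3 <- build_plasma_input(bc, mods$b2p, mods$parent_fraction, grid = tt)
  plasma <- wb / predict(mods$b2p, tt)
  expect_true(all(inp3$cp <= plasma + 1e-12))
  # a ratio model that crosses zero on the grid is rejected
  bad <- b2p_model(1, 0.5, -0.5, 0)
  expect_error(build_plasma_input(bc, bad, no_met, grid = seq(0, 10, 1 / 60)),
               "non-positive")
})

test_that("the full synthetic blood chain recovers true parent plasma within 5%", {
  sim <- simulate_input_function(seed = 7, auto_noise = 0, manual_noise = 0)
  est <- estimate_input_function(sim$observations$auto, sim$observations$manual)
  ix <- est$time >= 1
  rel <- abs(est$cp[ix] - sim$truth$cp[ix]) / pmax(sim$truth$cp[ix], 1e-9)
  expect_lt(max(rel), 0.05)
  # whole-blood reconstruction itself stays within 5% over [1, 120] min
  ix2 <- est$time >= 1 & est$time <= 120
  relb <- abs(est$whole_blood[ix2] - sim$truth$whole_blood[ix2]) /
    pmax(sim$truth$whole_blood[ix2], 1e-9)
  expect_lt(max(relb), 0.05)
})

test_that("blood tables round-trip", {
  sim <- simulate_input_function(seed = 3)
  f <- tempfile(fileext = ".csv")
  obs <- sim$observations
  df <- rbind(
    data.frame(time_min = obs$auto$time, activity_kBq_ml = obs$auto$activity,
               source = "auto", plasma_activity_kBq_ml = NA,
               parent_fraction = NA),
    data.frame(time_min = obs$manual$time, activity_kBq_ml = obs$manual$activity,
               source = "manual", plasma_activity_kBq_ml = obs$manual$plasma,
               parent_fraction = obs$manual$parent_fraction))
  utils::write.table(df, f, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  back <- read_blood_table(f)
  expect_equal(back$auto$activity, obs$auto$activity, tolerance = 1e-6)
  expect_equal(back$manual$parent_fraction, obs$manual$parent_fraction,
               tolerance = 1e-6)
})
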