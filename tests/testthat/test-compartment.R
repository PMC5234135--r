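test_that("VT identity and its degenerate cases", {
  expect_equal(compute_vt(two_tissue_params(0.2, 0.1, 0, 0)), 2)
  expect_equal(compute_vt(two_tissue_params(0.1, 0.05, 0.03, 0.015)), 6)
  expect_error(compute_vt(list(K1 = 0.1, k2 = 0.05, k3 = 0.02, k4 = 0)),
               "irreversible")
  expect_error(compute_vt(list(K1 = 0.1, k2 = 0, k3 = 0, k4 = 0)), "k2")
  # k3 = 0 reduces to K1/k2 regardless of k4
  expect_equal(compute_vt(list(K1 = 0.3, k2 = 0.12, k3 = 0, k4 = 0.05)), 2.5)
})

test_that("VT equals K1/k2 (1 + k3/k4) on a 1000-draw grid, exactly", {
  set.seed(101)
  K1 <- stats::runif(1000, 0.01, 2)
  k2 <- stats::runif(1000, 0.01, 1)
  k3 <- stats::runif(1000, 0.001, 1)
  k4 <- stats::runif(1000, 0.001, 1)
  for (i in seq_len(1000)) {
    expect_identical(compute_vt(list(K1 = K1[i], k2 = k2[i], k3 = k3[i], k4 = k4[i])),
                     K1[i] / k2[i] * (1 + k3[i] / k4[i]))
  }
})

test_that("VT is invariant under joint scaling of (k3, k4)", {
  set.seed(102)
  for (i in 1:50) {
    p <- list(K1 = stats::runif(1, 0.05, 1), k2 = stats::runif(1, 0.02, 0.5),
              k3 = stats::runif(1, 0.01, 0.3), k4 = stats::runif(1, 0.01, 0.3))
    for (cc in c(0.5, 2, 7.3)) {
      ps <- list(K1 = p$K1, k2 = p$k2, k3 = cc * p$k3, k4 = cc * p$k4)
      expect_equal(compute_vt(ps), compute_vt(p), tolerance = 1e-14)
    }
  }
})

test_that("simulated TAC reduces to the vascular term when K1 = 0", {
  inp <- fixture_input()
  sch <- fixture_schedule()
  tc <- simulate_2tcm(two_tissue_params(0, 0.1, vb = 0.05), inp, sch)
  wb <- tspoquant:::frame_average(inp$time, inp$whole_blood, sch)
  expect_equal(tc$activity, 0.05 * wb, tolerance = 1e-12)
  # vb = 1 gives the frame-averaged whole-blood curve itself
  tc2 <- simulate_2tcm(two_tissue_params(0.2, 0.1, vb = 1), inp, sch)
  expect_equal(tc2$activity, wb, tolerance = 1e-12)
})

test_that("1-TCM limit matches an independent fine-grid convolution oracle", {
  inp <- fixture_input()
  sch <- fixture_schedule()
  K1 <- 0.2; k2 <- 0.1
  tc <- simulate_2tcm(two_tissue_params(K1, k2, vb = 0), inp, sch)
  # oracle: trapezoid convolution on a 10x finer grid, then frame-averaged
  dtf <- 1 / 600
  ttf <- seq(0, max(inp$time), by = dtf)
  cpf <- stats::approx(inp$time, inp$cp, ttf)$y
  ctf <- numeric(length(ttf))
  a <- exp(-k2 * dtf)
  for (i in 2:length(ttf)) {
    ctf[i] <- ctf[i - 1] * a + dtf / 2 * (cpf[i] + a * cpf[i - 1])
  }
  ctf <- K1 * ctf
  oracle <- tspoquant:::frame_average(ttf, ctf, sch)
  expect_lt(max(abs(tc$activity - oracle) / pmax(oracle, 1e-9)), 0.001)
})

test_that("matrix-exponential and adaptive-integrator solutions agree", {
  skip_if_not_installed("deSolve")
  inp <- fixture_input()
  p <- two_tissue_params(0.12, 0.09, 0.05, 0.025, vb = 0)
  sch <- fixture_schedule()
  tc <- simulate_2tcm(p, inp, sch)
  cpfun <- stats::approxfun(inp$time, inp$cp, rule = 2)
  rhs <- function(t, y, parms) {
    list(c(p$K1 * cpfun(t) - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  # pointwise agreement of the two solvers on the dense solution
  probe_t <- seq(1, 120, by = 1)
  out <- deSolve::ode(c(0, 0), c(0, probe_t), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  ct_ode <- rowSums(out[-1, 2:3])
  ct_mine <- tspoquant:::tissue_response(p$K1, p$k2, p$k3, p$k4, inp$cp,
                                         inp$time[2] - inp$time[1])
  mine_at <- stats::approx(inp$time, ct_mine, probe_t)$y
  expect_lt(max(abs(mine_at - ct_ode) / pmax(ct_ode, 1e-9)), 5e-4)
  # and the frame-averaged TAC is consistent with the dense solution
  expect_true(all(tc$activity > 0))
})

test_that("noise-free fits recover VT within 1% with tiny %COV", {
  inp <- fixture_input()
  sch <- fixture_schedule()
  set.seed(103)
  for (i in 1:5) {
    p <- params_for_target_vt(stats::runif(1, 5, 25))
    tc <- simulate_2tcm(p, inp, sch)
    fit <- fit_2tcm(tc, inp, vb = 0.05)
    expect_lt(abs(fit$vt - compute_vt(p)) / compute_vt(p), 0.01)
    expect_lt(fit$pct_cov, 1)
    expect_true(fit$converged)
    expect_true(isSymmetric(fit$covariance, tol = 1e-8))
  }
})

test_that("an all-zero TAC collapses to zero uptake", {
  inp <- fixture_input()
  sch <- fixture_schedule()
  tc <- tac(sch, rep(0, n_frames(sch)), noisy = TRUE)
  fit <- fit_2tcm(tc, inp, vb = 0)
  expect_true(fit$vt < 0.01 || !fit$converged)
})

test_that("noisy replicates have small median VT bias and a %COV spread", {
  inp <- fixture_input()
  sch <- fixture_schedule()
  p <- params_for_target_vt(12, seed = 104)
  clean <- simulate_2tcm(p, inp, sch)
  dur <- frame_durations(sch)
  set.seed(105)
  n_rep <- 25
  vts <- pcs <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sdv <- 0.05 * clean$activity * sqrt(mean(dur) / dur)
    act <- clean$activity + stats::rnorm(length(sdv), 0, sdv)
    fit <- fit_2tcm(tac(sch, act, noisy = TRUE), inp, vb = 0.05)
    vts[i] <- fit$vt; pcs[i] <- fit$pct_cov
  }
  true_vt <- compute_vt(p)
  expect_lt(abs(stats::median(vts) - true_vt) / true_vt, 0.05)
  expect_gt(stats::sd(pcs), 0)
  expect_true(all(pcs > 0))
})

test_that("QC filter is boundary-inclusive and reports per-ROI effective n", {
  df <- cohort_table(data.frame(
    subject_id = c("a", "b", "c"), disease = "HC", genotype = "HAB",
    roi = "frontal", vt = c(10, 11, 12), pct_cov = c(10, 20, 25)))
  kept <- qc_filter(df, 20)
  expect_equal(nrow(kept), 2L)
  expect_equal(sort(kept$pct_cov), c(10, 20))
  expect_equal(unname(effective_n(kept)["frontal"]), 2L)
  # empty input passes through empty
  empty <- df[0, ]
  expect_equal(nrow(qc_filter(empty, 20)), 0L)
  expect_error(qc_filter(df, -1), "positive")
})

test_that("fit options: duration weights and free vb still recover VT", {
  inp <- fixture_input()
  sch <- fixture_schedule()
  p <- params_for_target_vt(10, seed = 106)
  tc <- simulate_2tcm(p, inp, sch)
  fw <- fit_2tcm(tc, inp, vb = 0.05, weights = "duration")
  expect_lt(abs(fw$vt - 10) / 10, 0.01)
  fv <- fit_2tcm(tc, inp, vb = 0.03, fit_vb = TRUE)
  expect_lt(abs(fv$vt - 10) / 10, 0.02)
  expect_lt(abs(fv$params$vb - 0.05), 0.02)
})
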