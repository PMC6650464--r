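test_that("a Milstein step degenerates correctly", {
  p <- regime1()
  # sigma2 = 0: deterministic Euler step
  p0 <- regime1(sigma2 = 0)
  a <- sir_drift(0.4, 0.3, p0, 0.002)
  expect_equal(milstein_step(0.4, 0.3, p0, 0.002, dt = 0.01, dB = 0.17),
               c(S = 0.4, I = 0.3) + a * 0.01)
  # dB = +/- sqrt(dt): the correction vanishes, step equals Euler-Maruyama
  for (sgn in c(-1, 1)) {
    dB <- sgn * sqrt(0.01)
    a <- sir_drift(0.4, 0.3, p, 0.002)
    b <- sir_diffusion(0.4, 0.3, p, 0.002)
    expect_equal(milstein_step(0.4, 0.3, p, 0.002, 0.01, dB),
                 c(S = 0.4, I = 0.3) + a * 0.01 + b * dB)
  }
  expect_error(milstein_step(Inf, 0.3, p, 1, 0.01, 0), "finite")
})

test_that("the step conserves the drift-only recursion for the total population", {
  p <- regime1()
  st <- random_states(200)
  set.seed(33)
  dBs <- rnorm(200, sd = 0.1)
  for (k in seq_len(nrow(st))) {
    x <- milstein_step(st$S[k], st$I[k], p, 0.002, 0.01, dBs[k])
    a <- sir_drift(st$S[k], st$I[k], p, 0.002)
    expect_equal(unname(x[1] + x[2]),
                 st$S[k] + st$I[k] + unname(a[1] + a[2]) * 0.01,
                 tolerance = 1e-13)
  }
})

test_that("paths are reproducible and respect the absorbing boundary", {
  model <- example31("a")$model
  tr1 <- simulate_path(model, 0.3, 0.2, 1, T = 10, dt = 0.01, seed = 42)
  tr2 <- simulate_path(model, 0.3, 0.2, 1, T = 10, dt = 0.01, seed = 42)
  expect_identical(tr1$S, tr2$S)
  expect_identical(tr1$I, tr2$I)
  expect_identical(tr1$regime, tr2$regime)
  expect_true(all(tr1$S > 0))
  expect_true(all(tr1$I >= 0))

  # I0 = 0 is absorbing: I stays 0 and S follows the switching ODE
  tr0 <- simulate_path(model, 0.3, 0, 1, T = 10, dt = 0.001, seed = 7)
  expect_true(all(tr0$I == 0))
  # with I = 0 the S-equation is linear within each regime segment; compare
  # against the piecewise closed form on the path's own regime skeleton
  set.seed(7)
  path <- sample_regime_path(model$generator, 1, 10)
  bounds <- c(path$jump_times, 10)
  S_exact <- 0.3
  for (seg in seq_along(path$states)) {
    p <- model$regimes[[path$states[seg]]]
    len <- bounds[seg + 1] - bounds[seg]
    S_exact <- p$Lambda / p$mu + (S_exact - p$Lambda / p$mu) * exp(-p$mu * len)
  }
  expect_equal(tr0$S[length(tr0$S)], S_exact, tolerance = 1e-3)

  # once I hits the floor it stays 0
  trb <- simulate_path(example31("b")$model, 0.3, 0.2, 1, T = 400, dt = 0.01,
                       seed = 5, dt_out = 0.1)
  if (trb$absorbed) {
    first0 <- which(trb$I == 0)[1]
    expect_true(all(trb$I[first0:length(trb$I)] == 0))
  }
})

test_that("the noise-free switching path matches the deterministic integrator", {
  # h = 1 keeps the endemic state in the interior; at h = 0.002 the endemic
  # susceptible level is below machine scale and boundary conventions differ
  p0 <- regime1(sigma2 = 0)
  m0 <- one_regime_model(p0, h = 1)
  tr <- simulate_path(m0, 0.3, 0.2, 1, T = 10, dt = 0.001, seed = 1)
  ref <- integrate_sir(p0, 1, 0.3, 0.2, T = 10, dt = 0.001)
  # Euler vs fourth-order: agreement to O(dt)
  expect_lt(max(abs(tr$S - ref$S)), 0.01)
  expect_lt(max(abs(tr$I - ref$I)), 0.01)
})

test_that("total population follows the drift-only recursion along paths", {
  model <- example31("a")$model
  tr <- simulate_path(model, 0.3, 0.2, 1, T = 5, dt = 0.01, seed = 11)
  expect_identical(tr$n_clamped, 0L)
  # reconstruct the per-step sums on the stored grid: between stored points
  # the sum increments come only from the drift, which we cannot re-derive
  # without the noise; but over any single step the identity is algebraic.
  # Check it by re-stepping from each stored state with the R stepper at
  # matching regimes and arbitrary dB: the sum update is dB-independent.
  idx <- seq(1, 400, by = 25)
  for (k in idx) {
    p <- model$regimes[[tr$regime[k]]]
    a <- sir_drift(tr$S[k], tr$I[k], p, model$h)
    for (dB in c(-0.3, 0, 0.14)) {
      x <- milstein_step(tr$S[k], tr$I[k], p, model$h, 0.01, dB)
      expect_equal(unname(x[1] + x[2]),
                   tr$S[k] + tr$I[k] + unname(a[1] + a[2]) * 0.01,
                   tolerance = 1e-13)
    }
  }
})

test_that("trajectory regime occupation converges to the stationary law", {
  model <- example31("a")$model
  tr <- simulate_path(model, 0.3, 0.2, 1, T = 10000, dt = 0.05, seed = 9,
                      dt_out = 0.5)
  occ <- tabulate(tr$regime, 2) / length(tr$regime)
  expect_lt(max(abs(occ - c(0.8, 0.2))), 0.02)
})

test_that("ensembles aggregate paths reproducibly with stable per-path seeds", {
  model <- example31("a")$model
  e1 <- simulate_ensemble(model, 0.3, 0.2, 1, T = 20, dt = 0.01, n_paths = 4,
                          seed = 3, dt_out = 0.1)
  e2 <- simulate_ensemble(model, 0.3, 0.2, 1, T = 20, dt = 0.01, n_paths = 6,
                          seed = 3, dt_out = 0.1)
  # growing the ensemble must not change earlier paths
  expect_identical(e1$I_final, e2$I_final[1:4])
  expect_identical(e1$time_avg_I, e2$time_avg_I[1:4])
  expect_true(e1$extinction_fraction >= 0 && e1$extinction_fraction <= 1)

  # n_paths = 1 reduces to a single path's summary
  single <- simulate_ensemble(model, 0.3, 0.2, 1, T = 20, dt = 0.01,
                              n_paths = 1, seed = 3, dt_out = 0.1)
  tr <- simulate_path(model, 0.3, 0.2, 1, T = 20, dt = 0.01,
                      seed = switchsir:::derive_seed(3, 1), dt_out = 0.1)
  expect_identical(single$I_final, tr$I[length(tr$I)])
  expect_equal(single$mean_time_average_I, mean(tr$I[tr$times >= 10]))

  # histogram mass is normalised per regime-conditional histogram
  e3 <- simulate_ensemble(model, 0.3, 0.2, 1, T = 50, dt = 0.01, n_paths = 3,
                          seed = 3, dt_out = 0.1,
                          hist_windows = list(w = c(10, 50)))
  for (hm in e3$histograms$w) expect_equal(sum(hm), 1)
})

test_that("strong order of the coupled refinement is about one", {
  model <- example31("a")$model
  so <- strong_order_estimate(model, 0.3, 0.2, 1, T = 2,
                              dt_list = c(0.02, 0.01, 0.005, 0.0025),
                              n_paths = 40, seed = 2)
  expect_gt(so$order, 0.6)
  expect_lt(so$order, 1.5)
  expect_true(all(diff(so$errors) < 0))
  expect_error(strong_order_estimate(model, 0.3, 0.2, 1, T = 2,
                                     dt_list = c(0.02, 0.015, 0.0025),
                                     n_paths = 2, seed = 1),
               "integer multiple")
})

test_that("noise-free refinement error shows first-order Euler truncation", {
  # against the exact (high-accuracy fourth-order) reference the endpoint
  # error of the noise-free Milstein scheme is O(dt)
  p0 <- regime1(sigma2 = 0)
  m0 <- one_regime_model(p0)
  ref <- integrate_sir(p0, 0.002, 0.3, 0.2, T = 5, dt = 0.001)
  endS <- ref$S[length(ref$S)]
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    tr <- simulate_path(m0, 0.3, 0.2, 1, T = 5, dt = dt, seed = 1,
                        dt_out = dt)
    abs(tr$S[length(tr$S)] - endS)
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(c(0.02, 0.01, 0.005))))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("stationarity diagnostic: late windows are closer than early-late", {
  model <- example31("a")$model
  ens <- simulate_ensemble(model, 0.3, 0.2, 1, T = 400, dt = 0.01,
                           n_paths = 30, seed = 1, dt_out = 0.2,
                           avg_window = c(200, 400),
                           hist_windows = list(early = c(0, 100),
                                               mid = c(200, 300),
                                               late = c(300, 400)))
  for (rg in 1:2) {
    d_late <- l1_distance(ens$histograms$mid[[rg]], ens$histograms$late[[rg]])
    d_early <- l1_distance(ens$histograms$early[[rg]],
                           ens$histograms$late[[rg]])
    expect_lt(d_late, d_early)
  }
})
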