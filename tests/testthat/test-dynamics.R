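test_that("drift matches the incidence decomposition and worked values", {
  p1 <- regime1()
  # disease-free equilibrium is a fixed point
  expect_equal(sir_drift(p1$Lambda / p1$mu, 0, p1, 0.002),
               c(S = 0, I = 0))
  # benchmark regime-1 point: aI = g(0.3, 0.2) - 0.5 * 0.2 (frozen from the
  # high-precision incidence oracle)
  a <- sir_drift(0.3, 0.2, p1, 0.002)
  expect_equal(unname(a["I"]), 0.033351349133965, tolerance = 1e-12)
})

test_that("drift components sum to the population balance identity", {
  st <- random_states(300)
  p <- regime2(0.3)
  for (k in seq_len(nrow(st))) {
    a <- sir_drift(st$S[k], st$I[k], p, 0.7)
    balance <- p$Lambda - p$mu * (st$S[k] + st$I[k]) -
      (p$gamma + p$epsilon) * st$I[k]
    expect_lt(abs(unname(a["S"] + a["I"]) - balance), 1e-13)
  }
})

test_that("diffusion is degenerate: components cancel and vanish correctly", {
  st <- random_states(200)
  p <- regime1()
  for (k in seq_len(nrow(st))) {
    b <- sir_diffusion(st$S[k], st$I[k], p, 0.002)
    expect_identical(unname(b["S"] + b["I"]), 0)
  }
  expect_equal(sir_diffusion(2, 0, p, 1), c(S = 0, I = 0))
  expect_equal(sir_diffusion(2, 1, regime1(sigma2 = 0), 1), c(S = 0, I = 0))
})

test_that("Milstein correction cancels in the sum and matches finite differences", {
  p <- regime1()
  st <- random_states(100)
  for (k in seq_len(nrow(st))) {
    cc <- milstein_correction(st$S[k], st$I[k], p, 0.002)
    expect_identical(unname(cc["S"] + cc["I"]), 0)
  }
  expect_equal(milstein_correction(1, 1, regime1(sigma2 = 0), 1),
               c(S = 0, I = 0))
  expect_equal(milstein_correction(0, 1, p, 1), c(S = 0, I = 0))
  # central finite differences of the diffusion field at the benchmark point
  fd_correction <- function(S, I, p, h, eps = 1e-7) {
    b <- sir_diffusion(S, I, p, h)
    dbdS <- (sir_diffusion(S + eps, I, p, h) -
             sir_diffusion(S - eps, I, p, h)) / (2 * eps)
    dbdI <- (sir_diffusion(S, I + eps, p, h) -
             sir_diffusion(S, I - eps, p, h)) / (2 * eps)
    c(S = unname(b["S"] * dbdS["S"] + b["I"] * dbdI["S"]),
      I = unname(b["S"] * dbdS["I"] + b["I"] * dbdI["I"]))
  }
  for (h in c(0.002, 1, 1.8)) {
    got <- milstein_correction(0.3, 0.2, p, h)
    want <- fd_correction(0.3, 0.2, p, h)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("deterministic R0 and equilibria reproduce the benchmark", {
  expect_equal(deterministic_R0(regime1()), 1.6)
  expect_equal(deterministic_R0(regime2()), 1.0)
  expect_equal(deterministic_R0(
    regime_parameters(1, 0.2, 0.7, 1, 0.3, 0.2)), 1.0)

  eq <- equilibria(regime1(), h = 1)
  expect_equal(eq$E0, c(S = 3, I = 0))
  expect_equal(eq$E_star, c(S = 0.1875, I = 0.5625))
  expect_equal(unname(sir_drift(eq$E_star[1], eq$E_star[2], regime1(), 1)),
               c(0, 0), tolerance = 1e-10)

  # R0 <= 1: no endemic equilibrium
  expect_null(equilibria(regime2(), h = 1)$E_star)

  # drift vanishes at the computed endemic point for other exponents too
  for (h in c(0.5, 2)) {
    es <- equilibria(regime1(), h)$E_star
    expect_equal(unname(sir_drift(es[1], es[2], regime1(), h)), c(0, 0),
                 tolerance = 1e-10)
  }
})

test_that("unrepresentable endemic equilibria are reported with a diagnostic", {
  # (R0 - 1) / alpha large and 1/h enormous: k overflows
  p <- regime_parameters(1, 0.1, 5, 0.01, 0.2, 0.2)
  eq <- equilibria(p, h = 1e-4)
  expect_null(eq$E_star)
  expect_match(eq$diagnostic, "not representable")
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(regime_parameters(0, 0.1, 0.8, 0.2, 0.3, 0.1),
               "strictly positive")
  expect_error(regime_parameters(0.3, 0.1, 0.8, 0.2, 0.3, 0.1, sigma2 = -1),
               "sigma2")
  expect_warning(switching_model(list(regime1()), matrix(0, 1, 1), h = 0.5),
                 class = "switchsir_h_warning")
  expect_error(switching_model(list(regime1(), regime2()),
                               rbind(c(-1, 1, 0), c(1, -1, 0), c(0, 0, 0)),
                               h = 1),
               "dimension")
  expect_error(suppressWarnings(
    switching_model(list(regime1(), regime2()),
                    rbind(c(0, 0), c(0, 0)), h = 1)),
    "irreducible")
})
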