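#' Drift field of the switching SIR system
#'
#' Deterministic part of the dynamics under one regime's parameters:
#' dS/dt = Lambda - mu * S - g(S, I) and
#' dI/dt = g(S, I) - (mu + gamma + epsilon) * I, where g is the
#' ratio-dependent incidence. The total population satisfies
#' d(S + I)/dt = Lambda - mu * (S + I) - (gamma + epsilon) * I exactly,
#' since the incidence term cancels in the sum.
#'
#' @param S,I State (>= 0).
#' @param p A [regime_parameters()] object.
#' @param h Incidence exponent (> 0).
#' @return Named numeric vector `c(S = dS/dt, I = dI/dt)`.
#' @export
sir_drift <- function(S, I, p, h) {
  stopifnot(inherits(p, "regime_parameters"))
  g <- ratio_dependent_incidence(S, I, p$beta, p$alpha, h)
  c(S = p$Lambda - p$mu * S - g,
    I = g - (p$mu + p$gamma + p$epsilon) * I)
}

#' Diffusion coefficients of the switching SIR system
#'
#' The white noise perturbs the transmission coefficient, so a single
#' Brownian motion enters both compartments through the incidence with
#' opposite signs: b_S = -sigma * S^h * I / (S^h + alpha * I^h) and
#' b_I = -b_S. The diffusion is therefore degenerate (rank one) and the
#' total population S + I carries no noise.
#'
#' @inheritParams sir_drift
#' @return Named numeric vector `c(S = b_S, I = b_I)` with `b_S + b_I = 0`.
#' @export
sir_diffusion <- function(S, I, p, h) {
  stopifnot(inherits(p, "regime_parameters"))
  f <- sqrt(p$sigma2) / p$beta *
    ratio_dependent_incidence(S, I, p$beta, p$alpha, h)
  c(S = -f, I = f)
}

#' Milstein correction term (b . grad) b
#'
#' Analytic gradient product of the diffusion coefficient, the correction
#' that upgrades an Euler-Maruyama step to a strong-order-one Milstein step
#' for this scalar-noise system. Because b_I = -b_S the components cancel:
#' c_S + c_I = 0 identically, so the correction (like the noise itself)
#' never moves the total population.
#'
#' On the boundary (S = 0 or I = 0) the correction is set to (0, 0) by the
#' same continuity convention as the incidence.
#'
#' @inheritParams sir_drift
#' @return Named numeric vector `c(S = c_S, I = c_I)` with `c_S + c_I = 0`.
#' @export
milstein_correction <- function(S, I, p, h) {
  stopifnot(inherits(p, "regime_parameters"))
  if (S <= 0 || I <= 0 || p$sigma2 == 0) return(c(S = 0, I = 0))
  sigma <- sqrt(p$sigma2)
  Sh <- S^h
  Ih <- I^h
  D <- Sh + p$alpha * Ih
  f <- sigma * Sh * I / D
  # partials of f(S, I) = sigma S^h I / (S^h + alpha I^h)
  fS <- sigma * I * h * S^(h - 1) * p$alpha * Ih / D^2
  fI <- sigma * Sh * (Sh + p$alpha * Ih - p$alpha * h * Ih) / D^2
  # b = (-f, f), so c_S = b_S f_S' * (-1)... expanded: c_i = sum_j b_j d b_i/d x_j
  cS <- f * (fS - fI)
  c(S = cS, I = -cS)
}

#' Per-regime basic reproduction number
#'
#' For the deterministic skeleton under a single regime the basic
#' reproduction number is beta / (mu + gamma + epsilon): the transmission
#' coefficient over the total per-capita removal rate of infecteds.
#'
#' @param p A [regime_parameters()] object.
#' @return A single number; the disease-free equilibrium is stable when it
#'   is below 1 and an endemic equilibrium appears when it exceeds 1.
#' @export
deterministic_R0 <- function(p) {
  stopifnot(inherits(p, "regime_parameters"))
  p$beta / (p$mu + p$gamma + p$epsilon)
}

#' Equilibria of the deterministic skeleton
#'
#' The disease-free equilibrium E0 = (Lambda / mu, 0) always exists. When
#' the basic reproduction number R0 exceeds 1 there is a unique endemic
#' equilibrium with I* = k S*, k = ((R0 - 1) / alpha)^(1/h), and S* solving
#' the population balance Lambda - mu S* - (mu + gamma + epsilon) I* = 0,
#' i.e. S* = Lambda / (mu + k (mu + gamma + epsilon)). The returned endemic
#' state is verified to annihilate the drift to within 1e-10.
#'
#' For very small h the exponent 1/h can overflow k; in that case the
#' endemic equilibrium is reported as not representable.
#'
#' @inheritParams sir_drift
#' @return A list with `E0` (length-2 vector), `E_star` (length-2 vector or
#'   `NULL` when R0 <= 1), `R0`, and `diagnostic` (a message when E_star is
#'   not representable in floating point).
#' @export
equilibria <- function(p, h) {
  stopifnot(inherits(p, "regime_parameters"))
  R0 <- deterministic_R0(p)
  out <- list(E0 = c(S = p$Lambda / p$mu, I = 0), E_star = NULL, R0 = R0,
              diagnostic = NULL)
  if (R0 <= 1) return(out)
  k <- ((R0 - 1) / p$alpha)^(1 / h)
  d <- p$mu + p$gamma + p$epsilon
  S_star <- p$Lambda / (p$mu + k * d)
  I_star <- k * S_star
  if (!is.finite(k) || !is.finite(S_star) || !is.finite(I_star) ||
      S_star <= 0 || I_star <= 0) {
    out$diagnostic <- sprintf(
      "endemic equilibrium not representable: k = ((R0-1)/alpha)^(1/h) = %g with 1/h = %g",
      k, 1 / h)
    return(out)
  }
  resid <- sir_drift(S_star, I_star, p, h)
  if (max(abs(resid)) > 1e-10) {
    out$diagnostic <- sprintf(
      "endemic equilibrium failed the drift-zero check (max residual %g)",
      max(abs(resid)))
  }
  out$E_star <- c(S = S_star, I = I_star)
  out
}
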