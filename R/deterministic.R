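#' Integrate the deterministic skeleton
#'
#' Classical fixed-step fourth-order Runge-Kutta integration of the
#' noise-free, single-regime SIR system
#' dS/dt = Lambda - mu S - g(S, I), dI/dt = g(S, I) - (mu + gamma + epsilon) I
#' with ratio-dependent incidence g. A fixed step is used instead of an
#' adaptive solver so that runs are bit-reproducible and the fourth-order
#' convergence rate can be checked directly by halving `dt`.
#'
#' `I = 0` is invariant for the exact flow; if a step undershoots I below 0
#' (a discretisation artifact) it is clamped to 0 and the event is counted
#' in the trajectory's `n_clamped` field.
#'
#' @param p A [regime_parameters()] object (its `sigma2` is ignored).
#' @param h Incidence exponent (> 0).
#' @param S0,I0 Initial state (>= 0).
#' @param T Horizon (> 0).
#' @param dt Step size (> 0, < T).
#' @return An object of class `ode_trajectory`: list with `times` (uniform
#'   grid), `S`, `I`, `params`, `h`, `dt` and `n_clamped`.
#' @export
integrate_sir <- function(p, h, S0, I0, T, dt) {
  stopifnot(inherits(p, "regime_parameters"))
  if (S0 < 0 || I0 < 0) stop("S0 and I0 must be non-negative", call. = FALSE)
  if (T <= 0 || dt <= 0 || dt >= T) {
    stop("need 0 < dt < T", call. = FALSE)
  }
  n <- as.integer(round(T / dt))
  times <- (0:n) * dt
  S <- numeric(n + 1L)
  I <- numeric(n + 1L)
  S[1] <- S0
  I[1] <- I0
  n_clamped <- 0L
  Lambda <- p$Lambda; mu <- p$mu; beta <- p$beta; alpha <- p$alpha
  d <- p$mu + p$gamma + p$epsilon
  f <- function(s, i) {
    g <- if (s > 0 && i > 0) beta * s^h * i / (s^h + alpha * i^h) else 0
    c(Lambda - mu * s - g, g - d * i)
  }
  x <- c(S0, I0)
  for (k in seq_len(n)) {
    k1 <- f(x[1], x[2])
    x2 <- x + dt / 2 * k1
    k2 <- f(x2[1], x2[2])
    x3 <- x + dt / 2 * k2
    k3 <- f(x3[1], x3[2])
    x4 <- x + dt * k3
    k4 <- f(x4[1], x4[2])
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(x))) {
      stop(sprintf("non-finite state at t = %g (S = %g, I = %g)",
                   times[k + 1L], x[1], x[2]), call. = FALSE)
    }
    if (x[2] < 0) {
      x[2] <- 0
      n_clamped <- n_clamped + 1L
    }
    if (x[1] < 0) {
      x[1] <- 0
      n_clamped <- n_clamped + 1L
    }
    S[k + 1L] <- x[1]
    I[k + 1L] <- x[2]
  }
  structure(list(times = times, S = S, I = I, params = p, h = h, dt = dt,
                 n_clamped = n_clamped),
            class = "ode_trajectory")
}

#' @export
print.ode_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Deterministic SIR trajectory: %d points on [0, %g], dt = %g\n",
              n, x$times[n], x$dt))
  cat(sprintf("  endpoint: S = %.6g, I = %.6g\n", x$S[n], x$I[n]))
  invisible(x)
}

#' @export
as.data.frame.ode_trajectory <- function(x, ...) {
  data.frame(t = x$times, S = x$S, I = x$I)
}

#' Check a trajectory against the invariant region
#'
#' The deterministic flow leaves the region
#' Lambda / (mu + gamma + epsilon) <= S + I <= Lambda / mu invariant.
#' This verifies that every stored point of a trajectory started inside the
#' region stays inside it, up to a numerical tolerance.
#'
#' @param traj An `ode_trajectory` from [integrate_sir()].
#' @param p The regime parameters defining the region bounds; defaults to
#'   the trajectory's own parameters.
#' @param tol Tolerance on the bounds (default 1e-6).
#' @return A list with `ok` (logical), the region `lower` and `upper`
#'   bounds, and when violated, `first_violation` (a list with `t`,
#'   `S_plus_I` and which bound was crossed).
#' @export
invariant_region_check <- function(traj, p = traj$params, tol = 1e-6) {
  stopifnot(inherits(traj, "ode_trajectory"))
  lower <- p$Lambda / (p$mu + p$gamma + p$epsilon)
  upper <- p$Lambda / p$mu
  tot <- traj$S + traj$I
  bad <- which(tot < lower - tol | tot > upper + tol)
  if (length(bad) == 0L) {
    return(list(ok = TRUE, lower = lower, upper = upper,
                first_violation = NULL))
  }
  j <- bad[1]
  list(ok = FALSE, lower = lower, upper = upper,
       first_violation = list(
         t = traj$times[j], S_plus_I = tot[j],
         bound = if (tot[j] < lower - tol) "lower" else "upper"))
}
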