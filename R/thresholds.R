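#' Stochastic reproduction number of the switching model
#'
#' The stationary-distribution-weighted ratio of transmission to removal
#' plus half the white-noise intensity:
#' R0S = sum_i(pi_i beta_i) / sum_i(pi_i (mu_i + gamma_i + epsilon_i +
#' sigma_i^2 / 2)). When R0S > 1 the switching diffusion admits a unique
#' ergodic stationary distribution and the disease persists; with a single
#' regime and no noise it reduces to the deterministic R0.
#'
#' @param model A [switching_model()].
#' @param pi Stationary distribution of the switching chain; computed from
#'   the model's generator when omitted. Must sum to 1 within 1e-10.
#' @return A single number.
#' @export
stochastic_R0S <- function(model, pi = NULL) {
  stopifnot(inherits(model, "switching_model"))
  pi <- check_pi(pi, model)
  pm <- param_matrix(model)
  num <- sum(pi * pm[, 3])
  den <- sum(pi * (pm[, 2] + pm[, 5] + pm[, 6] + pm[, 7] / 2))
  num / den
}

#' Extinction index of the switching model
#'
#' Rbar = sum_i(pi_i beta_i^2 / (2 sigma_i^2)) /
#' sum_i(pi_i (mu_i + gamma_i + epsilon_i)). When Rbar < 1 the disease goes
#' extinct with probability one regardless of the value of the stochastic
#' reproduction number: large noise suppresses the outbreak. The index is
#' undefined when any regime is noise-free.
#'
#' @inheritParams stochastic_R0S
#' @return A single number.
#' @export
extinction_index <- function(model, pi = NULL) {
  stopifnot(inherits(model, "switching_model"))
  pm <- param_matrix(model)
  if (any(pm[, 7] <= 0)) {
    stop("extinction index requires sigma2 > 0 in every regime",
         call. = FALSE)
  }
  pi <- check_pi(pi, model)
  num <- sum(pi * pm[, 3]^2 / (2 * pm[, 7]))
  den <- sum(pi * (pm[, 2] + pm[, 5] + pm[, 6]))
  num / den
}

check_pi <- function(pi, model) {
  if (is.null(pi)) return(stationary_distribution(model$generator))
  if (!is.numeric(pi) || length(pi) != model$N || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-10) {
    stop("`pi` must be a probability vector of length N (sum 1 within 1e-10)",
         call. = FALSE)
  }
  pi
}

#' Classify the long-run dynamics of a switching SIR model
#'
#' Computes the stationary distribution of the switching chain, the
#' per-regime deterministic reproduction numbers, the stochastic
#' reproduction number R0S and (when all noise intensities are positive) the
#' extinction index Rbar, then applies the threshold dichotomy:
#'
#' * `persistent` when R0S > 1 (unique ergodic stationary distribution;
#'   the densities of the solutions converge to an invariant density);
#' * `extinct_i` when Rbar < 1 (almost-sure extinction driven by large
#'   noise); takes precedence over `extinct_ii` when both hold;
#' * `extinct_ii` when R0S < 1 and sigma_i^2 <= beta_i in every regime
#'   (almost-sure extinction under moderate noise);
#' * `indeterminate` otherwise (the theory is silent, e.g. R0S < 1 with
#'   some sigma_i^2 > beta_i and Rbar >= 1).
#'
#' @param model A [switching_model()] with an irreducible generator.
#' @return An object of class `threshold_report`: a list with `pi`,
#'   `R0_per_regime`, `R0S`, `Rbar` (`NA` when undefined),
#'   `noise_dominance` (logical vector, sigma_i^2 <= beta_i) and
#'   `classification`.
#' @export
classify_dynamics <- function(model) {
  stopifnot(inherits(model, "switching_model"))
  pi <- stationary_distribution(model$generator)
  pm <- param_matrix(model)
  R0 <- vapply(model$regimes, deterministic_R0, numeric(1))
  R0S <- stochastic_R0S(model, pi)
  Rbar <- if (all(pm[, 7] > 0)) extinction_index(model, pi) else NA_real_
  nd <- pm[, 7] <= pm[, 3]
  classification <- if (R0S > 1) {
    "persistent"
  } else if (!is.na(Rbar) && Rbar < 1) {
    "extinct_i"
  } else if (R0S < 1 && all(nd)) {
    "extinct_ii"
  } else {
    "indeterminate"
  }
  structure(list(pi = pi, R0_per_regime = R0, R0S = R0S, Rbar = Rbar,
                 noise_dominance = nd, classification = classification),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Threshold report\n")
  cat("  stationary distribution pi:",
      paste(formatC(x$pi, digits = 6, format = "g"), collapse = ", "), "\n")
  cat("  deterministic R0 per regime:",
      paste(formatC(x$R0_per_regime, digits = 6, format = "g"),
            collapse = ", "), "\n")
  cat(sprintf("  stochastic R0S  = %.6g %s\n", x$R0S,
              if (x$R0S > 1) "(> 1)" else "(< 1)"))
  if (is.na(x$Rbar)) {
    cat("  extinction index Rbar: undefined (a regime has sigma2 = 0)\n")
  } else {
    cat(sprintf("  extinction index Rbar = %.6g %s\n", x$Rbar,
                if (x$Rbar < 1) "(< 1)" else "(>= 1)"))
  }
  cat("  sigma_i^2 <= beta_i:",
      paste(x$noise_dominance, collapse = ", "), "\n")
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' @export
format.threshold_report <- function(x, ...) {
  utils::capture.output(print(x))
}
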