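#' Ratio-dependent incidence rate
#'
#' Force of infection beta * S^h * I / (S^h + alpha * I^h): transmission is
#' approximately beta * I while I/S is small and saturates through the
#' inhibition parameter alpha as the infected-to-susceptible ratio grows,
#' capturing crowding effects and behavioural change during an epidemic.
#'
#' The rate is defined as 0 on the boundary (I = 0, or S = 0 with I > 0),
#' the continuous limit for h > 0, so the vector field is defined on the
#' whole closed positive quadrant.
#'
#' @param S Susceptible count (>= 0). Vectorised with `I`.
#' @param I Infected count (>= 0).
#' @param beta Transmission coefficient (> 0).
#' @param alpha Inhibition parameter (> 0).
#' @param h Incidence exponent (> 0).
#'
#' @return Transmission rate (individuals/time), in `[0, beta * I]`.
#' @examples
#' ratio_dependent_incidence(1, 1, beta = 1, alpha = 1, h = 1)  # 0.5
#' @export
ratio_dependent_incidence <- function(S, I, beta, alpha, h) {
  check_incidence_args(S, I, beta, alpha, h)
  S <- rep_len(as.numeric(S), n <- max(length(S), length(I)))
  I <- rep_len(as.numeric(I), n)
  out <- numeric(n)
  pos <- S > 0 & I > 0
  out[pos] <- beta * S[pos]^h * I[pos] / (S[pos]^h + alpha * I[pos]^h)
  out
}

#' General ratio-dependent incidence rate
#'
#' The two-exponent incidence family
#' beta * S^(h - l + 1) * I^l / (S^h + alpha * I^h). With `l = 1` it reduces
#' to [ratio_dependent_incidence()]; with `alpha = h = l = 1` it is the
#' frequency-dependent (standard) incidence beta * S * I / (S + I).
#'
#' @inheritParams ratio_dependent_incidence
#' @param l Second incidence exponent (> 0).
#' @return Transmission rate (individuals/time).
#' @export
general_incidence <- function(S, I, beta, alpha, h, l) {
  check_incidence_args(S, I, beta, alpha, h)
  if (!is.numeric(l) || any(l <= 0) || anyNA(l)) {
    stop("`l` must be positive", call. = FALSE)
  }
  S <- rep_len(as.numeric(S), n <- max(length(S), length(I)))
  I <- rep_len(as.numeric(I), n)
  out <- numeric(n)
  pos <- S > 0 & I > 0
  out[pos] <- beta * S[pos]^(h - l + 1) * I[pos]^l /
    (S[pos]^h + alpha * I[pos]^h)
  out
}

check_incidence_args <- function(S, I, beta, alpha, h) {
  if (anyNA(S) || anyNA(I) || any(S < 0) || any(I < 0)) {
    stop("S and I must be non-negative", call. = FALSE)
  }
  if (!is.numeric(beta) || any(beta <= 0) || anyNA(beta)) {
    stop("`beta` must be positive", call. = FALSE)
  }
  if (!is.numeric(alpha) || any(alpha <= 0) || anyNA(alpha)) {
    stop("`alpha` must be positive", call. = FALSE)
  }
  if (!is.numeric(h) || any(h <= 0) || anyNA(h)) {
    stop("`h` must be positive", call. = FALSE)
  }
  invisible(TRUE)
}
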