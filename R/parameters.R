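#' Rate constants for one environmental regime
#'
#' Bundles the demographic and epidemiological rate constants that are in
#' force while the environment sits in one state of the switching chain.
#'
#' @param Lambda Influx of individuals into the susceptible class
#'   (individuals/time, > 0).
#' @param mu Natural death rate (1/time, > 0).
#' @param beta Disease transmission coefficient (1/time, > 0).
#' @param alpha Inhibition parameter of the ratio-dependent incidence
#'   (dimensionless, > 0); larger values mean stronger saturation of
#'   transmission as the infected-to-susceptible ratio grows.
#' @param gamma Recovery rate (1/time, > 0).
#' @param epsilon Disease-induced death rate (1/time, > 0).
#' @param sigma2 Intensity of the white noise perturbing `beta`
#'   (1/time, >= 0). `sigma2 = 0` recovers the deterministic regime.
#'
#' @return An object of class `regime_parameters`: a named list of the seven
#'   rate constants.
#' @examples
#' regime_parameters(Lambda = 0.3, mu = 0.1, beta = 0.8, alpha = 0.2,
#'                   gamma = 0.3, epsilon = 0.1, sigma2 = 0.4)
#' @export
regime_parameters <- function(Lambda, mu, beta, alpha, gamma, epsilon,
                              sigma2 = 0) {
  vals <- c(Lambda = Lambda, mu = mu, beta = beta, alpha = alpha,
            gamma = gamma, epsilon = epsilon, sigma2 = sigma2)
  if (!is.numeric(vals) || length(vals) != 7L || anyNA(vals) ||
      any(!is.finite(vals))) {
    stop("all regime parameters must be finite numbers", call. = FALSE)
  }
  strict <- vals[c("Lambda", "mu", "beta", "alpha", "gamma", "epsilon")]
  if (any(strict <= 0)) {
    stop("Lambda, mu, beta, alpha, gamma and epsilon must be strictly positive",
         call. = FALSE)
  }
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "regime_parameters")
}

#' @export
print.regime_parameters <- function(x, ...) {
  cat("Regime parameters:\n")
  cat(sprintf("  Lambda = %g, mu = %g, beta = %g, alpha = %g\n",
              x$Lambda, x$mu, x$beta, x$alpha))
  cat(sprintf("  gamma = %g, epsilon = %g, sigma2 = %g\n",
              x$gamma, x$epsilon, x$sigma2))
  invisible(x)
}

#' Regime-switching SIR model
#'
#' Assembles N regime parameter sets, the generator of the continuous-time
#' Markov chain that drives the switching, and the shared incidence exponent
#' into a single validated model object.
#'
#' The generator must have non-negative off-diagonal entries, rows summing to
#' zero, and an irreducible positive-rate digraph, so that the chain has a
#' unique stationary distribution with strictly positive mass on every state.
#'
#' Values of `h` below 1 are accepted with a warning (condition class
#' `"switchsir_h_warning"`): the incidence family is usually stated for
#' h >= 1, but small exponents are used in practice to make transmission
#' nearly frequency-independent.
#'
#' @param regimes A list of [regime_parameters()] objects, one per
#'   environmental state, in state order.
#' @param generator N x N transition-rate matrix of the switching chain.
#' @param h Incidence exponent (dimensionless, > 0) shared by all regimes.
#' @param l Optional second incidence exponent for the general incidence
#'   family; `NULL` (the default) selects the ratio-dependent form with
#'   l = 1.
#'
#' @return An object of class `switching_model` with elements `regimes`,
#'   `generator` (validated), `h`, `l` and `N`.
#' @seealso [classify_dynamics()], [simulate_path()], [example31()]
#' @export
switching_model <- function(regimes, generator, h, l = NULL) {
  if (inherits(regimes, "regime_parameters")) regimes <- list(regimes)
  if (!is.list(regimes) || length(regimes) < 1L ||
      !all(vapply(regimes, inherits, logical(1), "regime_parameters"))) {
    stop("`regimes` must be a non-empty list of regime_parameters objects",
         call. = FALSE)
  }
  generator <- validate_generator(generator)
  if (nrow(generator) != length(regimes)) {
    stop("generator dimension must match the number of regimes", call. = FALSE)
  }
  if (!is_irreducible(generator)) {
    stop("the switching generator must be irreducible", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("`h` must be a single positive number", call. = FALSE)
  }
  if (h < 1) {
    warning(warningCondition(
      sprintf("incidence exponent h = %g is below 1; the incidence family is usually stated for h >= 1", h),
      class = "switchsir_h_warning"))
  }
  if (!is.null(l)) {
    if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0) {
      stop("`l` must be a single positive number or NULL", call. = FALSE)
    }
  }
  structure(list(regimes = regimes, generator = generator, h = h, l = l,
                 N = length(regimes)),
            class = "switching_model")
}

#' @export
print.switching_model <- function(x, ...) {
  cat(sprintf("Regime-switching SIR model with %d regime(s), h = %g\n",
              x$N, x$h))
  for (i in seq_len(x$N)) {
    p <- x$regimes[[i]]
    cat(sprintf("  regime %d: Lambda=%g mu=%g beta=%g alpha=%g gamma=%g epsilon=%g sigma2=%g\n",
                i, p$Lambda, p$mu, p$beta, p$alpha, p$gamma, p$epsilon,
                p$sigma2))
  }
  cat("Generator:\n")
  print(unclass(x$generator))
  invisible(x)
}

# Regime parameters as an N x 7 matrix (column order fixed for the C++ core).
param_matrix <- function(model) {
  t(vapply(model$regimes, function(p) {
    c(p$Lambda, p$mu, p$beta, p$alpha, p$gamma, p$epsilon, p$sigma2)
  }, numeric(7)))
}
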