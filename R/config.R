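#' Experiment configuration
#'
#' Bundles a switching model, an initial condition and the numerical
#' settings of a simulation experiment into one validated, serialisable
#' object. Configurations round-trip losslessly through
#' [write_config()] / [load_config()].
#'
#' @param model A [switching_model()].
#' @param S0,I0 Initial state.
#' @param r0 Initial regime.
#' @param T,dt,n_paths,seed Numerical settings (horizon, Milstein step,
#'   ensemble size, master seed).
#' @param extinction_floor Threshold on I(T) for counting a path extinct.
#' @param bins,S_range,I_range Histogram grid settings.
#' @param avg_window Analysis window for time averages; defaults to the
#'   second half of the horizon.
#' @param note Optional free-text annotation carried with the configuration.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model, S0, I0, r0 = 1, T = 1000, dt = 0.01,
                              n_paths = 200, seed = 1,
                              extinction_floor = 1e-4,
                              bins = c(40, 40),
                              S_range = c(0, 4), I_range = c(0, 2),
                              avg_window = c(T / 2, T), note = NULL) {
  stopifnot(inherits(model, "switching_model"))
  if (S0 <= 0 || I0 < 0) stop("need S0 > 0 and I0 >= 0", call. = FALSE)
  if (r0 < 1 || r0 > model$N) stop("`r0` out of range", call. = FALSE)
  structure(list(model = model,
                 initial = list(S0 = S0, I0 = I0, r0 = as.integer(r0)),
                 numerics = list(T = T, dt = dt, n_paths = as.integer(n_paths),
                                 seed = as.integer(seed),
                                 extinction_floor = extinction_floor,
                                 bins = as.integer(bins),
                                 S_range = S_range, I_range = I_range,
                                 avg_window = avg_window),
                 note = note),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration\n")
  print(x$model)
  cat(sprintf("  initial: S0 = %g, I0 = %g, r0 = %d\n",
              x$initial$S0, x$initial$I0, x$initial$r0))
  cat(sprintf("  numerics: T = %g, dt = %g, n_paths = %d, seed = %d\n",
              x$numerics$T, x$numerics$dt, x$numerics$n_paths,
              x$numerics$seed))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

config_to_list <- function(config) {
  m <- config$model
  out <- list(
    model = list(
      regimes = lapply(m$regimes, unclass),
      generator = unclass(m$generator),
      h = m$h),
    initial = config$initial,
    numerics = config$numerics)
  if (!is.null(m$l)) out$model$l <- m$l
  if (!is.null(config$note)) out$note <- config$note
  out
}

#' Write a configuration to JSON
#'
#' @param config An [experiment_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate a configuration from JSON
#'
#' All structural and model invariants are re-checked on load (generator row
#' sums and irreducibility, parameter positivity); unknown keys at any level
#' are rejected with a message naming the offending field.
#'
#' @param path Path to a JSON configuration written by [write_config()] (or
#'   by hand to the same schema).
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(raw, c("model", "initial", "numerics", "note"), "top level")
  for (req in c("model", "initial", "numerics")) {
    if (is.null(raw[[req]])) {
      stop(sprintf("configuration is missing the `%s` block", req),
           call. = FALSE)
    }
  }
  check_keys(raw$model, c("regimes", "generator", "h", "l"), "model")
  check_keys(raw$initial, c("S0", "I0", "r0"), "initial")
  check_keys(raw$numerics,
             c("T", "dt", "n_paths", "seed", "extinction_floor", "bins",
               "S_range", "I_range", "avg_window"), "numerics")
  regs <- raw$model$regimes
  if (is.data.frame(regs)) {
    regs <- lapply(seq_len(nrow(regs)), function(i) as.list(regs[i, ]))
  }
  regimes <- lapply(regs, function(r) {
    check_keys(r, c("Lambda", "mu", "beta", "alpha", "gamma", "epsilon",
                    "sigma2"), "regime")
    do.call(regime_parameters, r)
  })
  gen <- raw$model$generator
  if (is.list(gen)) gen <- do.call(rbind, gen)
  gen <- tryCatch(validate_generator(gen), error = function(e) {
    stop(sprintf("invalid `model$generator`: %s", conditionMessage(e)),
         call. = FALSE)
  })
  model <- switching_model(regimes, gen, raw$model$h, raw$model$l)
  num <- raw$numerics
  experiment_config(model,
                    S0 = raw$initial$S0, I0 = raw$initial$I0,
                    r0 = raw$initial$r0,
                    T = num$T, dt = num$dt, n_paths = num$n_paths,
                    seed = num$seed,
                    extinction_floor = num$extinction_floor,
                    bins = num$bins, S_range = num$S_range,
                    I_range = num$I_range, avg_window = num$avg_window,
                    note = raw$note)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("unknown field(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Benchmark two-regime parameterisation
#'
#' The two-regime switching SIR parameterisation used throughout the package
#' as a worked example and test fixture. The regime-independent values are
#' Lambda = (0.3, 0.5), mu = (0.1, 0.2), beta = (0.8, 0.6),
#' alpha = (0.2, 0.1), gamma = (0.3, 0.2), epsilon = (0.1, 0.2), h = 0.002,
#' generator `rbind(c(-0.2, 0.2), c(0.8, -0.8))` (stationary distribution
#' (4/5, 1/5)) and initial state (S0, I0) = (0.3, 0.2). Three noise settings
#' select qualitatively different long-run behaviour:
#'
#' * case `"a"`: sigma^2 = (0.4, 0.2) — stochastic reproduction number
#'   about 1.086 > 1, so the disease persists with a unique ergodic
#'   stationary distribution;
#' * case `"b"`: sigma^2 = (0.8, 0.6) — extinction index about 0.731 < 1,
#'   so the disease dies out almost surely (noise-driven extinction);
#' * case `"c"`: sigma^2 = (0.4, 0.4) — direct evaluation of the threshold
#'   formula gives R0S = 19/18 (about 1.056); the configuration carries a
#'   note flagging that published discussions of this noise setting quote a
#'   different value (0.76, which equals the numerator of the formula
#'   alone), so its classification should be read with care.
#'
#' The fixture uses h = 0.002 deliberately (nearly frequency-independent
#' transmission); the sub-unit-exponent warning from [switching_model()] is
#' muffled here because the value is intentional.
#'
#' @param case One of `"a"`, `"b"`, `"c"`.
#' @return An [experiment_config()] with the default numerics
#'   (T = 1000, dt = 0.01, n_paths = 200).
#' @examples
#' cfg <- example31("a")
#' classify_dynamics(cfg$model)
#' @export
example31 <- function(case = c("a", "b", "c")) {
  case <- match.arg(case)
  sigma2 <- switch(case,
                   a = c(0.4, 0.2),
                   b = c(0.8, 0.6),
                   c = c(0.4, 0.4))
  regimes <- list(
    regime_parameters(Lambda = 0.3, mu = 0.1, beta = 0.8, alpha = 0.2,
                      gamma = 0.3, epsilon = 0.1, sigma2 = sigma2[1]),
    regime_parameters(Lambda = 0.5, mu = 0.2, beta = 0.6, alpha = 0.1,
                      gamma = 0.2, epsilon = 0.2, sigma2 = sigma2[2]))
  gen <- rbind(c(-0.2, 0.2), c(0.8, -0.8))
  model <- withCallingHandlers(
    switching_model(regimes, gen, h = 0.002),
    switchsir_h_warning = function(w) invokeRestart("muffleWarning"))
  note <- if (case == "c") {
    paste("direct evaluation of the stochastic reproduction number for this",
          "noise setting gives 19/18 (about 1.056); the value 0.76 sometimes",
          "quoted for it equals the numerator of the formula alone")
  } else NULL
  experiment_config(model, S0 = 0.3, I0 = 0.2, r0 = 1, note = note)
}
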