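#' Single Milstein step
#'
#' One strong-order-one step of the scalar-noise switching SIR diffusion:
#' X' = X + a dt + b dB + (1/2) c (dB^2 - dt), with drift `a`
#' ([sir_drift()]), diffusion `b` ([sir_diffusion()]) and analytic gradient
#' product `c` ([milstein_correction()]). Because the system is driven by a
#' single Brownian motion no Levy-area approximation is needed. With
#' `sigma2 = 0` the step reduces to a deterministic Euler step, and with
#' `dB = +/- sqrt(dt)` the correction vanishes and the step equals
#' Euler-Maruyama.
#'
#' The noise and correction enter S and I with opposite signs, so the update
#' conserves `S' + I' = S + I + (aS + aI) dt` exactly (up to floating-point
#' rounding): the total population follows the drift-only recursion.
#'
#' For small incidence exponents the diffusion coefficient is not Lipschitz
#' at the S = 0 boundary and its S-derivative (hence the correction) grows
#' like S^(h-1). The correction is therefore tamed: it is dropped on steps
#' where `|c| * dt > |b|`, i.e. where it would no longer be a small
#' refinement of the Euler-Maruyama step. In the interior of the state
#' space the rule never triggers and the scheme is plain Milstein.
#'
#' @param S,I Current state (in the closed positive quadrant).
#' @param p A [regime_parameters()] object.
#' @param h Incidence exponent.
#' @param dt Step length (> 0).
#' @param dB Brownian increment over the step.
#' @return Named numeric vector `c(S = S', I = I')`.
#' @export
milstein_step <- function(S, I, p, h, dt, dB) {
  if (!is.finite(S) || !is.finite(I) || !is.finite(dB) || dt <= 0) {
    stop("milstein_step requires finite S, I, dB and dt > 0", call. = FALSE)
  }
  a <- sir_drift(S, I, p, h)
  b <- sir_diffusion(S, I, p, h)
  cc <- milstein_correction(S, I, p, h)
  if (abs(cc[[1]]) * dt > abs(b[[2]])) cc <- c(S = 0, I = 0)
  x <- c(S, I) + a * dt + b * dB + 0.5 * cc * (dB^2 - dt)
  c(S = unname(x[1]), I = unname(x[2]))
}

# Merge the uniform output grid with the chain's jump times; returns the
# sub-step boundaries, the regime on each sub-interval, and the indices of
# the grid points inside the merged schedule.
build_schedule <- function(path, T, dt) {
  n <- as.integer(round(T / dt))
  grid <- (0:n) * dt
  jumps <- path$jump_times[path$jump_times > 0 & path$jump_times < T]
  t_sub <- sort(unique(c(grid, jumps)))
  list(t_sub = t_sub,
       regime_sub = regime_at(path, t_sub[-length(t_sub)]),
       grid_idx = match(grid, t_sub),
       grid = grid)
}

#' Simulate one path of the regime-switching SIR diffusion
#'
#' The switching chain is simulated exactly first (exponential holding
#' times); the SDE is then advanced by Milstein steps of size at most `dt`
#' inside each regime segment, with the final step of every segment
#' truncated at the jump time so that parameters switch exactly when the
#' chain jumps. Brownian increments are drawn with variance equal to the
#' actual sub-step length.
#'
#' Boundary policy: the exact solution stays positive, so violations are
#' discretisation artifacts. If a step takes I below `floor_I` it is set to
#' 0 and stays there (extinction is absorbing); if a step takes S below 0
#' its increment is resampled once and then clamped at 1e-12 (counted in
#' `n_clamped`).
#'
#' @param model A [switching_model()].
#' @param S0,I0 Initial state (`S0 > 0`, `I0 >= 0`).
#' @param r0 Initial regime.
#' @param T Horizon.
#' @param dt Maximum Milstein step (default 0.01).
#' @param seed Integer seed; the whole trajectory (chain and diffusion) is a
#'   deterministic function of `(model, S0, I0, r0, T, dt, seed)`.
#' @param dt_out Spacing of the stored output grid; must be a multiple of
#'   `dt` (default `dt`, i.e. store every step).
#' @param floor_I Absorption floor for I during stepping (default 1e-12).
#' @return An object of class `sir_trajectory`: list with `times`, `S`, `I`,
#'   `regime` (state at each output time), `seed`, `dt`, and the boundary
#'   counters `n_resampled`, `n_clamped`, `absorbed`, `min_I`.
#' @export
simulate_path <- function(model, S0, I0, r0 = 1, T = 1000, dt = 0.01,
                          seed = NULL, dt_out = dt, floor_I = 1e-12) {
  stopifnot(inherits(model, "switching_model"))
  if (S0 <= 0 || I0 < 0) stop("need S0 > 0 and I0 >= 0", call. = FALSE)
  if (dt <= 0 || dt >= T) stop("need 0 < dt < T", call. = FALSE)
  thin <- round(dt_out / dt)
  if (thin < 1 || abs(thin * dt - dt_out) > 1e-9 * dt) {
    stop("`dt_out` must be a positive multiple of `dt`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  path <- sample_regime_path(model$generator, r0, T)
  sch <- build_schedule(path, T, dt)
  res <- milstein_path_cpp(sch$t_sub, sch$regime_sub, param_matrix(model),
                           model$h, S0, I0, floor_I)
  keep <- sch$grid_idx[seq(1, length(sch$grid_idx), by = thin)]
  times <- sch$grid[seq(1, length(sch$grid), by = thin)]
  structure(list(times = times,
                 S = res$S[keep], I = res$I[keep],
                 regime = regime_at(path, times),
                 seed = seed, dt = dt,
                 n_resampled = res$n_resampled, n_clamped = res$n_clamped,
                 absorbed = res$absorbed, min_I = res$min_I,
                 regime_path = path),
            class = "sir_trajectory")
}

#' @export
print.sir_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Switching SIR trajectory: %d points on [0, %g], dt = %g\n",
              n, x$times[n], x$dt))
  cat(sprintf("  endpoint: S = %.6g, I = %.6g, regime = %d%s\n",
              x$S[n], x$I[n], x$regime[n],
              if (x$absorbed) " (I absorbed at 0)" else ""))
  invisible(x)
}

#' @export
as.data.frame.sir_trajectory <- function(x, ...) {
  data.frame(t = x$times, S = x$S, I = x$I, regime = x$regime)
}

# Counter-based per-path seed: path i of a master seed gets a fixed value
# that does not change when n_paths grows. Kept below 2^31 - 1.
derive_seed <- function(master, i) {
  m <- 2147483647
  as.integer((((master %% m) * 48271) %% m + (i * 1664525) %% m) %% m)
}

# 2-D histogram counts of (S, I) samples on a fixed grid.
hist2d_counts <- function(S, I, bins, S_range, I_range) {
  bx <- seq(S_range[1], S_range[2], length.out = bins[1] + 1L)
  by <- seq(I_range[1], I_range[2], length.out = bins[2] + 1L)
  ix <- findInterval(pmin(pmax(S, S_range[1]), S_range[2]), bx,
                     rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(pmin(pmax(I, I_range[1]), I_range[2]), by,
                     rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins[1], bins[2])
  tab <- table(factor(ix, levels = seq_len(bins[1])),
               factor(iy, levels = seq_len(bins[2])))
  counts + as.matrix(unclass(tab))
}

#' L1 distance between two normalised histograms
#'
#' Sum of absolute cell differences of two histograms over the same grid;
#' the empirical counterpart of the L1 distance between densities used to
#' diagnose convergence to the invariant density.
#'
#' @param h1,h2 Arrays of equal dimension with non-negative mass.
#' @return A single number in `[0, 2]` when both inputs sum to 1.
#' @export
l1_distance <- function(h1, h2) {
  stopifnot(all(dim(h1) == dim(h2)))
  sum(abs(h1 - h2))
}

#' Simulate an ensemble of switching SIR paths
#'
#' Runs `n_paths` independent trajectories, each from a per-path seed
#' derived from the master seed by a counter scheme (so growing `n_paths`
#' never changes earlier paths), and accumulates the ensemble summaries used
#' by the persistence/extinction diagnostics: the fraction of paths whose
#' final infected count is below the extinction floor, per-path time
#' averages of I over an analysis window, and regime-conditional 2-D
#' histograms of (S, I) over one or more time windows (the empirical
#' counterpart of the invariant density of the switching diffusion).
#'
#' @inheritParams simulate_path
#' @param n_paths Number of paths (>= 1).
#' @param seed Master seed.
#' @param extinction_floor Threshold on I(T) below which a path is counted
#'   extinct (default 1e-4).
#' @param avg_window Length-2 time window over which per-path time averages
#'   of I are taken (default the second half, `c(T/2, T)`).
#' @param hist_windows Named list of length-2 time windows over which
#'   regime-conditional (S, I) histograms are accumulated across paths
#'   (default the `avg_window`).
#' @param bins Histogram bins per axis (default `c(40, 40)`).
#' @param S_range,I_range Fixed histogram ranges (defaults `c(0, 4)` and
#'   `c(0, 2)`), shared by all windows so histograms are comparable.
#' @param dt_out Output grid spacing used for summaries (default 0.1).
#' @return An object of class `sir_ensemble`: list with `n_paths`,
#'   `extinction_fraction`, `I_final`, `time_avg_I`, `mean_time_average_I`,
#'   `min_I` (per path, over the whole path), `n_absorbed`, `histograms`
#'   (per window, per regime, each normalised to total mass 1), histogram
#'   metadata, and the master `seed`.
#' @export
simulate_ensemble <- function(model, S0, I0, r0 = 1, T = 1000, dt = 0.01,
                              n_paths = 200, seed = 1,
                              extinction_floor = 1e-4,
                              avg_window = c(T / 2, T),
                              hist_windows = NULL,
                              bins = c(40, 40),
                              S_range = c(0, 4), I_range = c(0, 2),
                              dt_out = 0.1, floor_I = 1e-12) {
  stopifnot(inherits(model, "switching_model"), n_paths >= 1)
  if (is.null(hist_windows)) hist_windows <- list(window = avg_window)
  if (is.null(names(hist_windows))) {
    names(hist_windows) <- paste0("window", seq_along(hist_windows))
  }
  N <- model$N
  counts <- lapply(hist_windows, function(w) {
    lapply(seq_len(N), function(i) matrix(0, bins[1], bins[2]))
  })
  I_final <- numeric(n_paths)
  time_avg_I <- numeric(n_paths)
  min_I <- numeric(n_paths)
  n_absorbed <- 0L
  for (ipath in seq_len(n_paths)) {
    tr <- simulate_path(model, S0, I0, r0, T, dt,
                        seed = derive_seed(seed, ipath),
                        dt_out = dt_out, floor_I = floor_I)
    np <- length(tr$times)
    I_final[ipath] <- tr$I[np]
    min_I[ipath] <- tr$min_I
    if (tr$absorbed) n_absorbed <- n_absorbed + 1L
    in_avg <- tr$times >= avg_window[1] & tr$times <= avg_window[2]
    time_avg_I[ipath] <- mean(tr$I[in_avg])
    for (w in names(hist_windows)) {
      win <- hist_windows[[w]]
      sel <- tr$times >= win[1] & tr$times <= win[2]
      for (rg in seq_len(N)) {
        srg <- sel & tr$regime == rg
        if (any(srg)) {
          counts[[w]][[rg]] <- counts[[w]][[rg]] +
            hist2d_counts(tr$S[srg], tr$I[srg], bins, S_range, I_range)
        }
      }
    }
  }
  histograms <- lapply(counts, function(per_regime) {
    lapply(per_regime, function(m) {
      tot <- sum(m)
      if (tot > 0) m / tot else m
    })
  })
  structure(list(n_paths = n_paths,
                 extinction_fraction = mean(I_final < extinction_floor),
                 I_final = I_final,
                 time_avg_I = time_avg_I,
                 mean_time_average_I = mean(time_avg_I),
                 min_I = min_I,
                 n_absorbed = n_absorbed,
                 histograms = histograms,
                 hist_windows = hist_windows,
                 bins = bins, S_range = S_range, I_range = I_range,
                 extinction_floor = extinction_floor,
                 avg_window = avg_window,
                 T = T, dt = dt, dt_out = dt_out, seed = seed),
            class = "sir_ensemble")
}

#' @export
print.sir_ensemble <- function(x, ...) {
  cat(sprintf("Switching SIR ensemble: %d paths, T = %g, dt = %g, seed = %s\n",
              x$n_paths, x$T, x$dt, format(x$seed)))
  cat(sprintf("  extinction fraction (I(T) < %g): %.3f\n",
              x$extinction_floor, x$extinction_fraction))
  cat(sprintf("  mean time-average of I over [%g, %g]: %.5g\n",
              x$avg_window[1], x$avg_window[2], x$mean_time_average_I))
  cat(sprintf("  paths absorbed at I = 0: %d\n", x$n_absorbed))
  invisible(x)
}

#' Strong-order estimate by coupled refinement
#'
#' Estimates the strong convergence order of the Milstein integrator on the
#' switching model. For each path one chain realisation and one set of
#' Brownian increments are drawn on the finest grid; coarser resolutions
#' re-use the same chain and aggregate the fine increments over their steps,
#' so all resolutions are driven by the same noise. The endpoint strong
#' error of each coarse resolution against the finest one is averaged over
#' paths and regressed on log(dt).
#'
#' @param model A [switching_model()].
#' @param S0,I0,r0 Initial condition.
#' @param T Horizon (short horizons suffice; the estimate is local in time).
#' @param dt_list Decreasing step sizes; every entry must be an integer
#'   multiple of the smallest, which serves as the reference resolution.
#' @param n_paths Number of coupled paths (default 100).
#' @param seed Master seed.
#' @return A list with `order` (the fitted log-log slope over the coarse
#'   resolutions), `dt` (the coarse step sizes), `errors` (mean endpoint
#'   errors), and `fit` (the `lm` object).
#' @export
strong_order_estimate <- function(model, S0, I0, r0 = 1, T = 5,
                                  dt_list = c(0.02, 0.01, 0.005, 0.0025),
                                  n_paths = 100, seed = 1) {
  stopifnot(inherits(model, "switching_model"))
  dt_list <- sort(dt_list, decreasing = TRUE)
  if (length(dt_list) < 3L) stop("need at least 3 step sizes", call. = FALSE)
  dt_fine <- dt_list[length(dt_list)]
  mult <- dt_list / dt_fine
  if (any(abs(mult - round(mult)) > 1e-9)) {
    stop("every step size must be an integer multiple of the finest",
         call. = FALSE)
  }
  mult <- as.integer(round(mult))
  pm <- param_matrix(model)
  n_coarse <- length(dt_list) - 1L
  err <- matrix(0, n_paths, n_coarse)
  n_fine <- as.integer(round(T / dt_fine))
  if (abs(n_fine * dt_fine - T) > 1e-9 || any(n_fine %% mult != 0)) {
    stop(paste("step sizes are not nested: each must be an integer multiple",
               "of the finest and divide the horizon evenly"), call. = FALSE)
  }
  for (ipath in seq_len(n_paths)) {
    set.seed(derive_seed(seed, ipath))
    path <- sample_regime_path(model$generator, r0, T)
    sch_f <- build_schedule(path, T, dt_fine)
    m_f <- length(sch_f$t_sub) - 1L
    dB_f <- stats::rnorm(m_f, sd = sqrt(diff(sch_f$t_sub)))
    ref <- milstein_path_cpp(sch_f$t_sub, sch_f$regime_sub, pm, model$h,
                             S0, I0, 1e-12, dB_f)
    x_ref <- c(ref$S[m_f + 1L], ref$I[m_f + 1L])
    csum <- c(0, cumsum(dB_f))
    for (j in seq_len(n_coarse)) {
      # coarse grid as a subset of the fine grid, so boundaries match exactly
      grid_c <- sch_f$grid[seq(1, n_fine + 1L, by = mult[j])]
      jumps <- path$jump_times[path$jump_times > 0 & path$jump_times < T]
      t_c <- sort(unique(c(grid_c, jumps)))
      idx <- match(t_c, sch_f$t_sub)
      if (anyNA(idx)) stop("sub-step schedules are not nested", call. = FALSE)
      dB_c <- diff(csum[idx])
      reg_c <- regime_at(path, t_c[-length(t_c)])
      res <- milstein_path_cpp(t_c, reg_c, pm, model$h, S0, I0, 1e-12, dB_c)
      mc <- length(t_c) - 1L
      err[ipath, j] <- sqrt((res$S[mc + 1L] - x_ref[1])^2 +
                            (res$I[mc + 1L] - x_ref[2])^2)
    }
  }
  mean_err <- colMeans(err)
  fit <- stats::lm(log(mean_err) ~ log(dt_list[seq_len(n_coarse)]))
  list(order = unname(stats::coef(fit)[2]),
       dt = dt_list[seq_len(n_coarse)],
       errors = mean_err,
       fit = fit)
}
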