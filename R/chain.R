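#' Validate a continuous-time Markov chain generator
#'
#' A generator has non-negative off-diagonal transition rates and each
#' diagonal entry equal to minus the sum of the other entries in its row
#' (rows sum to zero, checked to 1e-12).
#'
#' @param rates Square numeric matrix of transition rates (1/time).
#' @return The matrix, with class `generator_matrix` prepended, invisibly
#'   unchanged otherwise.
#' @examples
#' validate_generator(rbind(c(-0.2, 0.2), c(0.8, -0.8)))
#' @export
validate_generator <- function(rates) {
  if (inherits(rates, "generator_matrix")) return(rates)
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates) || !is.numeric(rates) || anyNA(rates)) {
    stop("generator must be a square numeric matrix", call. = FALSE)
  }
  off <- rates
  diag(off) <- 0
  if (any(off < 0)) {
    stop("generator off-diagonal entries must be non-negative", call. = FALSE)
  }
  rs <- rowSums(rates)
  if (any(abs(rs) > 1e-12)) {
    stop(sprintf("generator rows must sum to zero (max |row sum| = %g)",
                 max(abs(rs))), call. = FALSE)
  }
  structure(rates, class = c("generator_matrix", class(rates)))
}

#' Irreducibility of a generator
#'
#' A chain is irreducible when the directed graph whose edges are the
#' strictly positive off-diagonal rates is strongly connected. Positivity of
#' every individual off-diagonal rate is not required. A one-state chain is
#' irreducible.
#'
#' @param G A generator matrix (validated by [validate_generator()]).
#' @return `TRUE` or `FALSE`.
#' @export
is_irreducible <- function(G) {
  G <- validate_generator(G)
  n <- nrow(G)
  if (n == 1L) return(TRUE)
  adj <- (G > 0) * 1
  diag(adj) <- 0
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::is_connected(gr, mode = "strong")
}

#' Stationary distribution of the switching chain
#'
#' Solves pi %*% G = 0 with sum(pi) = 1 by replacing the last balance
#' equation with the normalisation and solving the resulting linear system,
#' which is deterministic and avoids eigen-solver sign/scale ambiguity.
#'
#' @param G A generator matrix; must be irreducible.
#' @return Probability vector `pi` with all entries > 0, `pi %*% G = 0`
#'   within 1e-10.
#' @examples
#' stationary_distribution(rbind(c(-0.2, 0.2), c(0.8, -0.8)))  # (0.8, 0.2)
#' @export
stationary_distribution <- function(G) {
  G <- validate_generator(G)
  if (!is_irreducible(G)) {
    stop("generator is reducible: stationary distribution is not unique",
         call. = FALSE)
  }
  n <- nrow(G)
  if (n == 1L) return(1)
  A <- t(unclass(G))
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- drop(solve(A, b))
  resid <- max(abs(drop(pi %*% unclass(G))))
  if (resid > 1e-10 || any(pi <= 0)) {
    stop(sprintf("stationary solve failed (residual %g)", resid),
         call. = FALSE)
  }
  pi
}

#' Sample a path of the switching chain
#'
#' Exact simulation: the holding time in state i is exponential with rate
#' -G[i, i], and the next state j != i is chosen with probability
#' G[i, j] / (-G[i, i]). A state with zero exit rate (in particular the
#' one-state chain) is absorbing and the path holds it to the horizon.
#'
#' @param G Generator matrix.
#' @param r0 Initial state index in `1:N`.
#' @param T Time horizon (> 0).
#' @param seed Optional integer seed; when supplied, `set.seed(seed)` is
#'   called so the path is reproducible.
#' @return An object of class `regime_path`: a list with `jump_times`
#'   (starting at 0, strictly increasing, all < `T`), `states` (state held
#'   from each jump time, right-continuous), and `horizon`.
#' @export
sample_regime_path <- function(G, r0, T, seed = NULL) {
  G <- validate_generator(G)
  n <- nrow(G)
  if (!is.numeric(r0) || length(r0) != 1L || r0 < 1 || r0 > n ||
      r0 != round(r0)) {
    stop("`r0` must be a state index in 1..N", call. = FALSE)
  }
  if (!is.numeric(T) || T <= 0) stop("`T` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cap <- 256L
  times <- numeric(cap)
  states <- integer(cap)
  times[1] <- 0
  states[1] <- as.integer(r0)
  m <- 1L
  t_now <- 0
  i <- as.integer(r0)
  repeat {
    rate <- -G[i, i]
    if (rate <= 0) break
    t_now <- t_now + stats::rexp(1, rate)
    if (t_now >= T) break
    probs <- G[i, ]
    probs[i] <- 0
    i <- sample.int(n, 1L, prob = probs)
    if (m == cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(states) <- cap
    }
    m <- m + 1L
    times[m] <- t_now
    states[m] <- i
  }
  structure(list(jump_times = times[seq_len(m)], states = states[seq_len(m)],
                 horizon = T),
            class = "regime_path")
}

#' State of a regime path at given times
#'
#' @param path A `regime_path`.
#' @param t Vector of times in `[0, horizon]`.
#' @return Integer vector of states (right-continuous at jumps).
#' @export
regime_at <- function(path, t) {
  stopifnot(inherits(path, "regime_path"))
  path$states[findInterval(t, path$jump_times)]
}

#' Occupation fractions of a regime path
#'
#' Fraction of `[0, horizon]` spent in each state; the empirical counterpart
#' of the stationary distribution, to which it converges for long horizons
#' by the ergodic theorem.
#'
#' @param path A `regime_path`.
#' @param N Number of states; defaults to the largest state seen.
#' @return Numeric vector of length `N` summing to 1.
#' @export
occupation_fractions <- function(path, N = max(path$states)) {
  stopifnot(inherits(path, "regime_path"))
  bounds <- c(path$jump_times, path$horizon)
  lens <- diff(bounds)
  occ <- vapply(seq_len(N), function(s) sum(lens[path$states == s]),
                numeric(1))
  occ / sum(occ)
}

#' @export
print.regime_path <- function(x, ...) {
  cat(sprintf("Regime path on [0, %g]: %d segment(s), states {%s}\n",
              x$horizon, length(x$states),
              paste(sort(unique(x$states)), collapse = ", ")))
  invisible(x)
}
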