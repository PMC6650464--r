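# Shared fixtures: the two-regime benchmark and single-regime reductions.

bench_generator <- function() rbind(c(-0.2, 0.2), c(0.8, -0.8))

regime1 <- function(sigma2 = 0.4) {
  regime_parameters(Lambda = 0.3, mu = 0.1, beta = 0.8, alpha = 0.2,
                    gamma = 0.3, epsilon = 0.1, sigma2 = sigma2)
}

regime2 <- function(sigma2 = 0.2) {
  regime_parameters(Lambda = 0.5, mu = 0.2, beta = 0.6, alpha = 0.1,
                    gamma = 0.2, epsilon = 0.2, sigma2 = sigma2)
}

# single-regime switching model (N = 1, no jumps)
one_regime_model <- function(p, h = 0.002) {
  suppressWarnings(switching_model(list(p), matrix(0, 1, 1), h = h))
}

# random interior states for property-style checks
random_states <- function(n, seed = 101) {
  set.seed(seed)
  data.frame(S = runif(n, 0.01, 4), I = runif(n, 0.01, 2))
}
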