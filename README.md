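# switchsir

Tools for studying an SIR epidemic whose transmission saturates in the
infected-to-susceptible ratio and whose environment switches randomly
between discrete regimes. The package is aimed at modellers who want to
ask, for a given parameterisation: *does the infection persist or die out
in the long run, and what does the stochastic steady state look like?*

## The model

Within one environmental regime the dynamics of susceptibles S and
infecteds I are

    dS = [ Λ − μS − g(S, I) ] dt − σ g(S, I)/β dB
    dI = [ g(S, I) − (μ + γ + ε) I ] dt + σ g(S, I)/β dB

with ratio-dependent incidence

    g(S, I) = β S^h I / (S^h + α I^h) ,

so transmission is ≈ βI early in an outbreak and is throttled by the
inhibition parameter α (crowding, behavioural change) as I/S grows. A
single Brownian motion B perturbs the transmission coefficient and enters
both compartments with opposite signs (degenerate diffusion: S + I carries
no noise). All rate constants (Λ, μ, β, α, γ, ε, σ²) jump between N
regimes driven by an irreducible continuous-time Markov chain with
generator Γ̃ and stationary distribution π.

Closed-form threshold quantities classify the long-run behaviour:

* per-regime basic reproduction number `R0 = β/(μ+γ+ε)`;
* stochastic reproduction number
  `R0S = Σᵢ πᵢβᵢ / Σᵢ πᵢ(μᵢ+γᵢ+εᵢ+σᵢ²/2)` — above 1 the switching
  diffusion is ergodic with a unique invariant density (persistence);
* extinction index
  `Rbar = Σᵢ πᵢβᵢ²/(2σᵢ²) / Σᵢ πᵢ(μᵢ+γᵢ+εᵢ)` — below 1 the disease dies
  out almost surely however large R0S is (large noise suppresses the
  outbreak).

Around these the package provides exact chain-path simulation, a
fixed-step fourth-order integrator for the deterministic skeleton, a
strong-order-one Milstein integrator for the switching SDE with exact
switching times, ensemble summaries with regime-conditional (S, I)
histograms, a coupled-refinement strong-order diagnostic, and a JSON
configuration interface with a command-line driver
(`inst/scripts/switchsir`).

## Worked example

The built-in two-regime benchmark `example31()` ships three noise
settings. Case "a" has moderate noise:

```r
library(switchsir)
cfg <- example31("a")
classify_dynamics(cfg$model)
#> Threshold report
#>   stationary distribution pi:     0.8,     0.2
#>   deterministic R0 per regime:     1.6,       1
#>   stochastic R0S  = 1.08571 (> 1)
#>   extinction index Rbar = 1.57692 (>= 1)
#>   sigma_i^2 <= beta_i: TRUE, TRUE
#>   classification: persistent
```

The chain spends 80% of its time in regime 1 (R0 = 1.6, supercritical) and
20% in regime 2 (R0 = 1, critical); the noise-corrected reproduction
number 1.086 > 1 classifies the disease as stochastically persistent.
Raising the noise to case "b" (σ² = (0.8, 0.6)) drops the extinction index
to 0.731 < 1, and ensembles die out accordingly:

```r
ens <- simulate_ensemble(example31("b")$model, S0 = 0.3, I0 = 0.2, r0 = 1,
                         T = 1000, dt = 0.01, n_paths = 50, seed = 1,
                         dt_out = 0.5)
ens
#> Switching SIR ensemble: 50 paths, T = 1000, dt = 0.01, seed = 1
#>   extinction fraction (I(T) < 0.0001): 1.000
#>   mean time-average of I over [500, 1000]: 0
#>   paths absorbed at I = 0: 50
```

Every one of the 50 paths is extinct by t = 1000: almost-sure extinction
driven purely by environmental noise, despite both regimes having
deterministic R0 ≥ 1. Single trajectories are just as direct:

```r
tr <- simulate_path(cfg$model, S0 = 0.3, I0 = 0.2, r0 = 1,
                    T = 1000, dt = 0.01, seed = 42, dt_out = 1)
as.data.frame(tr)   # columns t, S, I, regime
```

The same operations are scriptable from a shell:

```sh
Rscript inst/scripts/switchsir thresholds --example 3.1a
Rscript inst/scripts/switchsir simulate --example 3.1a --seed 42 -T 10 --dt 0.01 --out path.csv
Rscript inst/scripts/switchsir chain --example 3.1a --seed 4 -T 100
```

The methods vignette (`vignettes/regime-switching-sir.Rmd`) documents the
numerical schemes, the boundary policy, and an important caveat about how
slowly the ratio-dependent saturation engages when h is very small.

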