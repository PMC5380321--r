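# turingbranch

Turing-instability analysis of a reaction–diffusion model of lung
branching morphogenesis.

The mammalian lung grows by two branching modes that occur in sequence:
side branching (new branches sprout laterally from a stalk) and tip
bifurcation (an advancing tip splits in two). `turingbranch` implements a
computational study of the mathematical mechanism behind that switch: the
branching model's activator–inhibitor core undergoes a Turing instability
at the growing tips, the underlying stationary patterns are spots, and the
Turing wavelength — not any new biochemical ingredient — decides which
branching mode appears.

## The model

Four fields on a 2-D domain: activator $A$, inhibitor $H$, substrate $S$,
and an irreversible cell-differentiation state $Y$,

$$
\begin{aligned}
\partial_t A &= cA^2S/H - \mu A + \rho_A Y + D_A \nabla^2 A\\
\partial_t H &= cA^2S - vH + \rho_H Y + D_H \nabla^2 H\\
\partial_t S &= c_0 - \gamma S - \varepsilon YS + D_S \nabla^2 S\\
\partial_t Y &= dA - eY + Y^2/(1+fY^2).
\end{aligned}
$$

Freezing $(S, Y)$ decouples the Gierer–Meinhardt activator–inhibitor core;
each point of the $(S, Y)$ plane then has a positive equilibrium whose
linearisation gives a dispersion relation $\mathrm{Re}\,\lambda(k)$ and
the four Turing inequalities. The package provides:

* `ai_equilibrium()`, `ai_jacobian()`, `turing_conditions()` — the
  decoupled subsystem and its linear stability analysis;
* `dispersion()`, `scan_turing_region()`, `wavelength_series()` — the
  dispersion relation, critical wavenumber/wavelength, and the
  crescent-shaped Turing region in the $(S, Y)$ plane;
* `simulate_branching()`, `simulate_ai()` — compiled explicit
  finite-difference simulators for the full model and the decoupled one;
* `extract_trajectory()`, `select_turing_state()` — the differentiation
  trajectory of a cell through the $(S, Y)$ plane and the in-region state
  underlying a branching run;
* `pattern_summary()`, `count_spots()`, `classify_pattern()`,
  `radial_spectrum_peak()`, `classify_branch_events()` — pattern and
  branching-morphology quantification;
* `run_workflow()` — the end-to-end pipeline over an $\varepsilon$ or
  $\rho_H$ sweep.

The numbered scripts under `analysis/` run the full study and write
tables/figures to `results/`.

## Worked example

```r
library(turingbranch)

p   <- model_params()                      # reference parameter set
ctx <- ai_context(p, S = 0.352, Y = 0.248) # a state on the tip-bifurcation
                                           # trajectory, inside the region
ai_equilibrium(ctx)
#> Positive equilibrium: A* = 0.11307626, H* = 0.00084503783
#>   residuals |f| = 8.67e-19, |g| = 3.39e-21

dispersion(ctx)
#> Dispersion relation at S = 0.352, Y = 0.248
#>   Re lambda(0) = -0.0057963, max Re lambda = 0.0085071
#>   k_critical = 0.64549, wavelength = 9.7339
```

The homogeneous state is stable (`Re lambda(0) < 0`) but a band of finite
wavenumbers grows — a Turing instability with pattern spacing ≈ 9.7 length
units. Simulating the decoupled model there yields a stationary spot
pattern whose spectral peak matches that prediction:

```r
sim <- simulate_ai(ctx, grid_spec(64, 64), rng_seed = 7)
pattern_summary(sim$final$A, grid_spec(64, 64))
#> Pattern: spots, 28 spot(s)
#>   dominant wavenumber: 0.6872 (confident: TRUE)
#>   gradient max/mean: 1.316 / 0.04972
```

Across the six reference states (three per branching mode) the wavelength
falls monotonically — 11.17, 9.73, 8.80 for the tip-bifurcation trio
against 7.35, 7.19, 7.12 for the side-branching trio — while spot counts
of the stationary patterns rise (at 128×128, seed 1: 73, 103, 128 against
205, 213, 222). Shorter wavelength, denser spots, side branching:

```r
g <- grid_spec(128, 128, dx = 0.5, boundary = "zero-flux")
tip <- simulate_branching(model_params(epsilon = 1.0), g,
                          run_length = 2400, n_snapshots = 100)
classify_branch_events(tip)$overall_mode
#> [1] "tip"
side <- simulate_branching(model_params(epsilon = 0.06), g,
                           run_length = 8000, n_snapshots = 100)
classify_branch_events(side)$overall_mode
#> [1] "side"
```

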