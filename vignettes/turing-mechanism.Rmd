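---
title: "The Turing mechanism behind tip bifurcation and side branching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Turing mechanism behind tip bifurcation and side branching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`turingbranch` studies a four-variable reaction–diffusion model of lung
branching morphogenesis. An activator $A$ amplifies itself
autocatalytically, fed by a substrate $S$ and antagonised by an inhibitor
$H$; sufficiently high activator levels flip cells into an irreversibly
differentiated state $Y$, which in turn secretes both morphogens and
consumes the substrate:

$$
\begin{aligned}
\partial_t A &= \frac{cA^2S}{H} - \mu A + \rho_A Y + D_A \nabla^2 A\\
\partial_t H &= cA^2S - vH + \rho_H Y + D_H \nabla^2 H\\
\partial_t S &= c_0 - \gamma S - \varepsilon Y S + D_S \nabla^2 S\\
\partial_t Y &= dA - eY + \frac{Y^2}{1+fY^2}
\end{aligned}
$$

$Y$ does not diffuse; its kinetics are bistable (the saturating
self-activation $Y^2/(1+fY^2)$ against the linear decay $eY$), which is
what makes differentiation irreversible: once a cell is pushed over the
saddle by $dA$, it settles on the high-$Y$ branch ($Y \approx 0.89$ at the
defaults) and stays there. The default parameter set is the package's
reference condition (`model_params()`); the single interesting dial is
$\varepsilon$, the substrate consumption rate of differentiated tissue,
which switches the growth morphology from tip bifurcation (large
$\varepsilon$) to side branching (small $\varepsilon$).

An optional saturation constant $\kappa$ replaces $A^2$ by
$A^2/(1+\kappa A^2)$ in the two morphogen equations. It defaults to 0 so
that the shipped kinetics are exactly the model above; $\kappa > 0$ is an
opt-in used to generate stripe- and hole-type patterns for gradient
comparisons. Mild saturation ($\kappa \lesssim 1$) still yields spots at
the reference states; the saturated system keeps a Turing region of its
own whose patterns are stripes around $\kappa = 5$, $(S, Y) =
(0.61, 0.29)$ and holes at higher substrate levels, and those are the
contexts the examples use.

## Decoupling and linear stability

Branching is driven by the two-variable activator–inhibitor core. Freezing
$S$ and $Y$ at fixed levels (`ai_context()`) decouples that core; each
point of the $(S, Y)$ plane then owns a two-species reaction–diffusion
system. `ai_equilibrium()` finds its positive homogeneous steady state by
eliminating $H^* = (cA^{*2}S + \rho_H Y)/v$ and solving the resulting
cubic in $A^*$ (polynomial roots, Newton-polished to residuals below
$10^{-10}$). A unique positive root is returned as-is; with several
positive roots the one whose homogeneous linearisation is stable is
selected, and genuine ambiguity raises an error rather than guessing.
Note that at $Y = 0$ the unique positive equilibrium is homogeneously
*unstable* ($r_{11} = \mu > v = -r_{22}$): the Turing region necessarily
lives at $Y > 0$, where the secretion terms shift the balance.

Linearising at the equilibrium gives the Jacobian entries
$r_{11} = 2cA^*S/H^* - \mu$, $r_{12} = -cA^{*2}S/H^{*2}$,
$r_{21} = 2cA^*S$, $r_{22} = -v$, and the growth rate of a perturbation
with wavenumber $k$ is the dominant root of
$\lambda^2 - \mathrm{tr}_k \lambda + \Delta_k = 0$ with
$\mathrm{tr}_k = r_{11}+r_{22}-k^2(D_A+D_H)$ and
$\Delta_k = r_{11}r_{22}-r_{12}r_{21} - k^2(r_{11}D_H + r_{22}D_A) +
k^4 D_A D_H$. When $\mathrm{tr}_k^2 < 4\Delta_k$ the pair is complex and
$\mathrm{Re}\,\lambda = \mathrm{tr}_k/2$. Diffusion-driven instability
requires the four familiar inequalities (negative trace, positive
determinant, positive cross-diffusion combination, and a real unstable
band); `turing_conditions()` evaluates them and `scan_turing_region()`
maps the crescent-shaped region where all four hold. The scan is total:
points without a positive equilibrium are simply outside.

`dispersion()` samples $\mathrm{Re}\,\lambda(k)$ on $[0, \pi/\mathrm{d}x]$
(2000 points by default — the largest wavenumber representable on the
simulation grid) and polishes the critical wavenumber by golden-section
search around the grid argmax; the pattern wavelength is
$2\pi/k_\mathrm{crit}$. At the six reference states the wavelength falls
strictly from 11.2 to 7.1 length units, with the side-branching trio
wholly below the tip-bifurcation trio.

## Simulators and numerical choices

Both models are integrated by explicit forward Euler with a five-point
Laplacian (compiled code; an independent plain-R step serves as the test
oracle). The time step is $0.2\,\mathrm{d}x^2/(4\max D)$ — the explicit
diffusion bound with a 5× safety margin. Negative values within
$10^{-12}$ of zero are clamped (round-off of the explicit step); anything
more negative, or non-finite, aborts with a diagnostic naming the field
and step, so blow-up is never silently truncated.

The **activator–inhibitor simulator** follows the stated study design: a
200×200 periodic grid at $\mathrm{d}x = 1$, started from the equilibrium
with ±1% uniform multiplicative noise, run until stationary (maximum
kinetic rate below $10^{-6}$ for 100 consecutive steps, capped at
$5\times10^5$ steps; non-convergence is reported via a flag, never an
exception). All randomness is confined to the initial condition, so a
seed fixes the entire run bit-for-bit.

The **branching simulator**'s grid, boundary, seeding and initial state
are not part of the stated design, so they are package choices:

* **Boundary** is zero-flux (mirrored ghost cells): a stalk growing from a
  seeded edge is ill-posed under periodic wrap.
* **Seeding**: substrate starts at its undisturbed level $c_0/\gamma$,
  $Y = 0.5$ and $A{+}{=}0.5$ in a 3×3 patch at the bottom-edge midpoint,
  ±1% multiplicative noise on $A$.
* **Spatial step** $\mathrm{d}x = 0.5$ (not 1). The activator interface
  width $\sqrt{D_A/\mu} \approx 0.35$ length units is subgrid at
  $\mathrm{d}x = 1$, and discrete fronts with subgrid interfaces pin on
  the lattice: at $\varepsilon = 0.06$ the differentiation front stalls
  completely (a three-cell stalk after $t = 1.2\times10^5$), so the
  side-branching morphology can never form. At $\mathrm{d}x = 0.5$ both
  morphologies develop. The stationary patterns of the decoupled model are
  insensitive to this (no moving fronts), so it keeps $\mathrm{d}x = 1$.
* **Baseline levels** $A = 0.001$, $H = 0.01$. With equal baselines the
  background self-ignites — activator peaks nucleate everywhere,
  independently of the seed — because local fluctuations drain inhibitor
  faster than activator at these diffusivities. A quiescent background
  needs baseline $A/H \ll 1$; growth then emanates from the seed alone.

With these choices, $\varepsilon = 1.0$ grows a tree by repeated tip
splitting while $\varepsilon = 0.06$ grows stalks that sprout laterals
behind the advancing front, on a 128×128 grid within a few minutes of CPU
time.

## Trajectories and state selection

`extract_trajectory()` tracks "a cell differentiating at a growing tip":
by default, the cell whose $Y$ first crosses half the final maximum during
the second half of the run (ties broken by largest $Y$, then lowest
index). The choice is deliberately deterministic and overridable — any
cell can be tracked, and the selected $(S, Y)$ state can be injected
explicitly, which is how the package reproduces analyses anchored at
printed states rather than re-derived ones.

Two numerical realities shape the crossing computation. First, the
differentiation transient is fast: a cell's $(S, Y)$ point traverses the
thin crescent in a few time units, while field snapshots are tens of time
units apart, so membership is evaluated on a piecewise-linear refinement
of the sampled path (10 interpolation points per interval), each refined
point validated by exact re-evaluation of the Turing conditions — the
scanned mask is only advisory, since the crescent is thin relative to any
practical scan step. Second, cells at different positions in the growing
tree clip the crescent or miss it narrowly (measured on the reference
tip-bifurcation run, about a third of differentiating cells' paths cross),
so when a region is supplied the default rule prefers the first candidate
cell whose refined path crosses it. `select_turing_state()` then takes the
representative interior state of the longest in-region stretch.

## Pattern metrics

Spot counting thresholds at the midpoint of the field range, labels
8-connected components, and discards components smaller than 4 pixels.
One wrinkle is intrinsic to this model: because the activator interface is
sub-cell, stationary spots are near-grid-scale spikes, and only one or two
pixels per spot clear the midpoint threshold. `pattern_summary()`
therefore applies one pass of a 3×3 box filter before thresholding
(`presmooth = 1`), which spreads each spike over its neighbourhood without
merging neighbouring spots (spacing ≥ 7 cells); the raw algorithm remains
available in `count_spots()` for fields whose features are resolved.
Pattern classification inspects phase fractions and component elongation:
elongated components are stripes, a minority-phase of compact blobs is
spots, the mirror case holes. Gradient statistics use central differences
(one-sided at non-periodic edges); the dominant wavenumber comes from the
azimuthally averaged 2-D power spectrum, with a peak flagged low-confidence
when it fails to stand 5× above the median bin power (white noise fails
this).

`classify_branch_events()` skeletonizes the differentiated mask
(Zhang–Suen thinning) per snapshot, prunes short spurs, and takes skeleton
endpoints as branch tips. Tips are matched greedily between snapshots;
when the tip count rises, each unmatched new tip fires an event, provided
a tip persists near the same spot in the next snapshot (skeletons of thick
branches flicker, and unconfirmed endpoints are artifacts). The event
*kind* is decided by the age of the tissue the new branch grows from: tip
splitting happens at the advancing front, on tissue the front just laid
down, while side branches sprout from stalk that differentiated long
before. We first tried the more obvious rule — distance of the new tip to
the nearest pre-existing tip — and found it non-discriminating: both
morphologies are dense trees in which every new tip lies within a couple
of wavelengths of some other tip. Attachment age separates the two regimes
cleanly (front-adjacent tissue is under ~200 time units old at the default
growth speeds; the mother stalks of laterals are over ~450 old), and the
default threshold of 300 sits in the gap; it is the classifier's main
calibrated constant, alongside the tip-tracking radius `r_tip` (5 length
units). The overall mode is decided by dominance with a 10% tolerance:
a run whose events are ≥90% bifurcations is a tip-bifurcation pattern,
≥90% laterals a side-branching pattern, and anything in between hybrid —
an all-or-nothing rule would let a single late-stage artifact relabel an
entire run. The hybrid rule is a proxy: the source material gives no
operational definition.

## What the generator does and does not emulate

The synthetic branching runs emulate stalk elongation from a seeded edge,
substrate-coupled growth, and the morphology switch under $\varepsilon$ —
the features the analyses need. They do not emulate three-dimensional
airway geometry, mechanical interaction with surrounding tissue, or gene
regulation; passing tests say the *model* behaves as analysed, not that
real lungs do. Spot counts and branching-event counts are grid- and
domain-size dependent, so only their orderings across conditions are
meaningful, and those orderings are what the test suite asserts (over
three seeds for the stochastic ones).

## Problem sizes

The shipped analyses use a 200×200 scan for Turing regions, 128×128
activator–inhibitor grids (the full 200×200 behaves identically; spot
counts scale with domain area), and 128×128 branching grids at
$\mathrm{d}x = 0.5$ with run lengths 2400–4000 ($\varepsilon = 1.0$) and
8000 ($\varepsilon = 0.06$; slower growth needs longer to develop
laterals). Mode classification uses runs stopped before the tree fills
the domain — once structures merge, skeleton endpoints stop being tips.
These sizes were chosen so each analysis completes in minutes while
leaving the qualitative labels (mode, pattern class) unchanged with
respect to larger runs.

## Known limitations

* The explicit integrator is first-order in time; wavelengths and spot
  counts are insensitive to dt at the default safety factor, but precise
  transient timings are not.
* `run_workflow()` records per-stage failures and continues, but does not
  resume from persisted artifacts; its runs are minutes-scale and results
  live in memory.
* The branching-event classifier works on skeleton topology alone; highly
  saturated domains (structures that have filled most of the grid) make
  endpoints ambiguous, so classification should use runs stopped before
  saturation.
* Equilibrium handling of the saturated ($\kappa > 0$) kinetics uses a
  scan-and-bracket root finder rather than the cubic reduction; it is
  slower and, like any scan, could miss pathologically close root pairs.
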