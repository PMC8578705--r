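---
title: "Modelling and analysing quantal Ca2+ release by IP3 receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing quantal Ca2+ release by IP3 receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalCa)
```

## The model

Quantal Ca²⁺ release is the observation that a submaximal IP₃
concentration rapidly releases only part of the ER Ca²⁺ store, release
then terminates, and a further IP₃ increment promptly releases more.
`quantalCa` implements a deliberately minimal model of this behaviour in
four coupled layers.

### Tetrameric occupancy

IP₃ binding and unbinding (on-rate ~3.5 s⁻¹ at 100 nM, off-rate ~28 s⁻¹)
are far faster than the gating transitions below, so ligand binding is
treated as instantaneously equilibrated. With four independent, identical
sites per tetramer of dissociation constant $K_D$,

$$\alpha(L) = \frac{L}{L + K_D}, \qquad
  N_4(L) = N\,\alpha(L)^4,$$

where $N$ is the number of receptors per cell (or per well) and $N_4$ the
expected number of tetra-liganded — i.e. gating-competent — receptors.
`fractional_occupancy()`, `tetra_fraction()`, `tetra_count()` and
`concentration_for_count()` implement this arithmetic and its inverse
($\alpha = (N_4/N)^{1/4}$, $L = K_D\,\alpha/(1-\alpha)$). Working values:
$K_D$ = 794 nM, $N$ = 49,146 for the over-expressing line and 9,101 for a
wild-type HEK cell. The steep fourth power is the heart of the model: at
186 nM only ~0.13% of receptors (about 60 per over-expressing cell) can
open at all, and a 60→90 nM step multiplies that number 4.41-fold.

### Stochastic gating

A tetra-liganded receptor occupies closed (C₄), open (O₄) or inactivated
(I₄) states on a triangular scheme:

| transition | rate (s⁻¹) |
|---|---|
| C₄ → O₄ | $k_1 = 0.4$ |
| O₄ → C₄ | $k_1/100$ |
| O₄ → I₄ | $k_2 = 0.2$ |
| I₄ → O₄ | $k_2/100$ |
| I₄ → C₄ | $k_3 = 0.004$ |
| C₄ → I₄ | forbidden |

Reverse rates are 100-fold slower than forward rates; the forbidden edge
makes the cycle effectively irreversible and gives the scheme its
adaptation-like character: a receptor opens quickly (mean closed dwell
1/k₁ = 2.5 s), inactivates (mean open dwell 1/(k₂+k₋₁) ≈ 4.9 s), and
recovers only slowly (I₄ exits on the 100-s scale). Each ligand addition
injects newly tetra-liganded receptors into C₄; the ensuing surge of
openings decays within ~10 s, which is exactly the quantal termination.

`simulate_protocol()` advances every receptor independently in fixed steps
of $\Delta t$ = 12.5 ms: a receptor in a state with allowed exits $i$
takes exit $i$ with probability $k_i\Delta t$ (one uniform draw per
receptor per step, the unit interval partitioned into disjoint exit
sub-intervals). Because receptors are exchangeable, the default engine
draws per-state multinomial counts instead of looping over receptors —
distributionally identical and fast enough for well-scale populations
(2×10¹⁰ receptors); the literal per-receptor engine is retained for
validation (`engine = "per_receptor"`). Construction rejects
$\max(k)\,\Delta t \ge 0.1$ so per-step probabilities stay small; the
residual discretisation bias is $O(k\Delta t)$, about 0.25% at the default
rates.

Two deterministic oracles accompany the simulator.
`meanfield_occupancies()` solves the master equation $p(t) = p(0)e^{Qt}$
exactly (Matrix::expm; a fine-step ODE integration cross-checks it in the
tests to 1e−6), and `method = "discrete"` iterates the one-step matrix
$I + Q\Delta t$, the exact mean of the simulated chain. At ensembles of
10⁴–10⁵ receptors the stochastic mean tracks the continuous-time solution
within 3 binomial standard errors; at well-scale counts the $O(k\Delta t)$
bias exceeds shot noise and the discrete oracle is the sharper reference.
`stationary_distribution()` (null space of $Q^\top$) gives the long-run
distribution; note that because I₄ also exits to C₄ at $k_3$, the
stationary open/inactivated ratio is $(k_{-2}+k_3)/k_2 = 0.03$, and about
2.9% of injected receptors remain open in quasi-steady state — a slow
release trickle that matters for protocol-order comparisons (see
Limitations).

### ER store dynamics

Luminal free Ca²⁺ (µM) driven by $O_4(t)$ open receptors:

$$\frac{dC_{ER}}{dt} = -(k_{leak} + k_{rel}O_4)(C_{ER} - C)
  \;\left[+\; \frac{500 - C_{ER}}{\tau_{SERCA}}\right]$$

with defaults $k_{leak}$ = 1.8×10⁻⁴ s⁻¹ (measured from post-inhibition
decays, see below), $k_{rel}$ = 8×10⁻⁴ s⁻¹ per open receptor, cytosolic
Ca²⁺ clamped at $C$ = 0.22 µM by the buffered medium, $C_{ER}(0)$ =
500 µM, and, when SERCA pumps are active, refill toward the 500 µM
loading plateau with $\tau$ = 100 s. The refill target is a fixed constant
of the equation, not a parameter. `estimate_k_rel()` reproduces the
order of $k_{rel}$ from first principles (5×10⁵ ions s⁻¹ per channel, a
500 µM free / 5× buffered pool in ~3.5×10⁻¹³ L of ER), giving
~9.6×10⁻⁴ s⁻¹; the exact normalisation behind the working value 8×10⁻⁴ is
not recoverable, so the working value stays the default and the derivation
is exposed separately.

**Releasable pool.** 80% of the store is releasable through IP₃Rs. The
store is partitioned at the start of each integration: the
$k_{rel}O_4$ term drains only the releasable pool, the leak acts on the
total (pro rata across pools), SERCA refill enters the releasable pool,
and the reported $C_{ER}$ is the sum. This choice reproduces both the
early kinetics of the release equation and the observation that maximal
IP₃ plateaus below complete store emptying; whether the leak should also
be restricted to the releasable pool is not determined by the data, and
the total-pool reading is our documented choice. A corollary: with the
leak off, sustained maximal opening can deplete at most the releasable
fraction.

**Integrator.** Explicit Euler locked to the gating step (12.5 ms). All
rates are ≪ 1/Δt, so the scheme is stable; halving the step changes a
1,000-s trajectory by <0.01% (property-tested), and the O₄ ≡ 0 limit
matches the closed-form exponential to <0.1% over 1,000 s. Antagonist
addition (`simulate_antagonist()`) sets $k_{rel}$ = 0 from the given time,
after which an active SERCA refills the store toward its analytic steady
state $(500/\tau + k_{leak}C)/(1/\tau + k_{leak}) \approx 491$ µM.

Population wells divide the well's open-receptor count by the number of
cells before entering the store equation, keeping $k_{rel}$ a per-cell,
per-channel constant.

### Inverse analysis

`analyze_trace()` inverts a luminal fluorescence trace (assumed linear in
ER free Ca²⁺, sampled at 1.44 s) in four steps:

1. **Leak fit** (`fit_leak()`): mono-exponential least squares on the
   window from SERCA inhibition to the stimulus. The asymptote is fixed at
   the clamped cytosolic level by default: over a few hundred seconds
   $k_{leak}t \ll 1$, so a free offset is barely identifiable, while the
   physical asymptote of a pure leak is known. The analytic derivative of
   the fit defines $J_{leak}(t)$, which is paired with the time-matched
   content and refitted as $J_{leak}$(content) — second-degree polynomial
   by default, exponential as an option.
2. **Leak subtraction** (`subtract_leak()`): evoked flux =
   $-dF/dt - J_{leak}(F)$. Inside the leak window the derivative is the
   analytic one (a leak-only trace subtracts to ~0 exactly); elsewhere it
   is a central difference after Savitzky–Golay smoothing (default window
   7 samples, order 2 — raw finite differences on noisy 1.44-s data are
   unusable; pass `smooth_window = 1` for noiseless data).
3. **Reconstruction**: the evoked-flux integral is telescoped exactly —
   the reconstruction is the (smoothed) measured content with the
   integrated leak restored — rather than re-integrating the
   finite-difference derivative, which loses mass at the stimulus-onset
   kink. The generic `reconstruct_caer()` (cumulative trapezoid of any
   flux series) is exported for flux inputs that do not come from a
   derivative.
4. **Open receptors** (`open_receptors()`): evoked flux divided by the
   instantaneous gradient $C_{ER} - C$, proportional to the true open
   count with unknown factor $k_{rel}$. Noise-induced negative fluxes are
   kept in the flux output but clipped to zero only at this final step;
   samples whose gradient falls below a floor (default 2% of initial
   content) are masked rather than divided, preventing blow-up as stores
   empty.

`estimate_k_leak()` evaluates $J_{leak}$ at a reference content (500 µM
for calibrated traces) and divides by the gradient there, recovering the
rate constant used by the forward model.

## The synthetic-data generator

`generate_trace()` composes the forward model into a plate-reader-style
record: loading from a 250 µM store via SERCA refill (ATP at 50 s),
SERCA inhibition at 450 s, a 500-s leak-only window, ligand additions from
950 s spaced 150 s apart, fluorescence = a·C_ER + b sampled at 1.44 s,
plus additive white noise (default SD 1% of the dynamic range — the
magnitude is a modelling choice, not a measurement). Every trace carries
its ground truth (true O₄ and C_ER trajectories, all parameters, the
seed), and regeneration with the same seed is bitwise identical.
`template_library()` holds the standard conditions: the 96-well population
(4×10⁵ cells, ~2×10¹⁰ receptors, 60/90/120 nM), the single wild-type cell
(9,101 receptors, 143/177/219 nM ⇒ 5/10/20 tetra-liganded receptors), a
direct single addition, a strong 300 nM release, an antagonist run with
SERCA kept active, and a leak-only control.

By construction the generator satisfies the analysis model exactly:
mono-exponential leak, evoked flux $k_{rel}O_4(C_{ER}-C)$, additive white
noise, linear calibration. Passing recovery tests therefore demonstrates
the *correctness* of the inverse pipeline, not its robustness to the ways
real recordings violate these assumptions (bleaching, indicator
saturation and kinetics, baseline drift, correlated noise, well-to-well
variability) — none of which are modelled.

## Numerical and design choices

- Concentrations are nM in the pharmacology layer and µM in the store
  layer; log-molar quantities (pEC₅₀, pK_D) are derived after conversion.
- Hill fitting (`fit_hill()`) uses Levenberg–Marquardt least squares with
  data-driven initialisation (bottom = min, top = max, midpoint = the
  concentration nearest half-range, h = 1), fits log(midpoint) so the
  optimiser cannot wander non-positive, and reports failure on degenerate
  data instead of clamping. Noiseless recovery is exact to ≤1e−4
  relative; at 5% noise the median midpoint over 100 replicates stays
  within 10%.
- Competition binding uses the Cheng–Prusoff correction
  $K_D = IC_{50}/(1 + [L^*]/K_D^*)$; antagonist affinity uses the Schild
  relation $K_D = [\text{antagonist}]/(DR - 1)$; partial-agonist
  energetics use $\Delta G = -RT\ln K_D$ (molar) and
  $\Delta\Delta G = \Delta G^{IBC} - \Delta G^{NT}$.
- Tetra-liganded counts are rounded to the nearest integer at injection
  (stochastic simulation needs integers; the single-cell protocols use
  exact counts 5/10/20 by design).
- The RNG is R's Mersenne–Twister with a single integer seed recorded in
  every output.
- Cell-geometry arithmetic computes the ER volume from its factors
  (1.1×10⁻¹² L × 0.9 non-nuclear × 0.35 ER ⇒ 3.465×10⁻¹³ L), giving a
  single-cell ER Ca²⁺ content of 8.7×10⁻¹⁶ ≈ 9×10⁻¹⁶ mol.

### Problem sizes

The test suite and acceptance script run at desk scale: master-equation
comparisons use 10⁴–10⁵ receptors (where binomial standard errors are the
meaningful yardstick), dwell-time and Monte-Carlo recovery checks use
10⁴ dwells and 100 replicates, and protocol-level checks use the
single-cell (9,101-receptor) and population templates directly — the
multinomial engine makes well-scale counts cheap.

## Known limitations

- **Protocol-order effects.** The stationary 2.9% open fraction produces
  a slow release trickle, so incremental and direct additions to the same
  final concentration accumulate slightly different open-receptor
  exposure (~3–5% of store content for 150-s-spaced additions). Strict
  equality of final content is therefore approximate; at physiological
  single-cell receptor counts the discrepancy is smaller than the
  realization-to-realization Monte-Carlo spread, which is how the
  equivalence test is framed.
- No cytosolic Ca²⁺ feedback on gating, no ligand depletion, no spatial
  clustering, no partially liganded intermediates: each addition simply
  jumps the tetra-liganded count.
- The store model clamps cytosolic Ca²⁺ and ignores mitochondria and
  counter-ion fluxes.
- The inverse pipeline's derivative estimator, smoothing defaults,
  J_leak-vs-content family and negative-flux handling are our choices —
  principled but not unique; all are configurable and recorded in the
  outputs.
- Fluorescence is treated as exactly linear in luminal Ca²⁺; indicator
  photophysics are out of scope.
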