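# quantalCa

Quantal Ca²⁺ release from ER stores by IP₃ receptors: forward simulation
and inverse trace analysis.

## The problem

Submaximal concentrations of inositol 1,4,5-trisphosphate (IP₃) rapidly
release only a fraction of the Ca²⁺ stored in the endoplasmic reticulum,
and release then stops — yet the stores respond fully to a further
increment in IP₃. `quantalCa` implements a minimal quantitative account of
this *quantal* behaviour for researchers modelling ER Ca²⁺ signalling or
analysing low-affinity luminal indicator recordings:

- **Tetrameric occupancy.** An IP₃R opens only when all four subunits bind
  IP₃. With independent, identical sites of affinity K_D, the per-site
  occupancy is α = [IP₃]/([IP₃] + K_D) and the fraction of receptors
  eligible to gate is α⁴. Because α⁴ is tiny at submaximal [IP₃], only a
  handful of a cell's receptors mediate each response.
- **Three-state gating.** Tetra-liganded receptors move between closed
  (C₄), open (O₄) and inactivated (I₄) states on a triangular scheme with
  forward rates k₁ = 0.4 s⁻¹ (C₄→O₄), k₂ = 0.2 s⁻¹ (O₄→I₄),
  k₃ = 0.004 s⁻¹ (I₄→C₄), reverse rates 100-fold slower, and the direct
  C₄→I₄ transition forbidden. Each IP₃ addition therefore evokes a brief
  surge of openings that inactivates within seconds — the quantal
  signature. The simulator advances every receptor independently at
  Δt = 12.5 ms and is checked against the matrix-exponential solution of
  the master equation.
- **ER store dynamics.** Luminal free Ca²⁺ obeys
  dC_ER/dt = −(k_leak + k_rel·O₄)(C_ER − C) [+ (500 − C_ER)/τ_SERCA],
  with k_leak = 1.8×10⁻⁴ s⁻¹, k_rel = 8×10⁻⁴ s⁻¹ per open receptor,
  cytosolic Ca²⁺ clamped at C = 0.22 µM, and optional SERCA refill
  (τ = 100 s). 80% of the store is releasable through IP₃Rs.
- **Inverse analysis.** From a luminal fluorescence trace the package fits
  the IP₃-independent leak after SERCA inhibition (mono-exponential),
  subtracts the leak flux J_leak at the time-matched content, reconstructs
  the stimulus-evoked store depletion by integration, and divides the
  evoked flux by the luminal–cytosolic gradient to recover the time course
  of open receptors in arbitrary units.
- **Synthetic data.** A generator composes the forward model into
  plate-reader-style traces (1.44 s sampling, load–inhibit–stimulate
  timeline, additive noise) with full ground truth, so the inverse pipeline
  can be validated by parameter recovery.

## Worked example

```r
library(quantalCa)

# How many receptors mediate a half-maximal response?
m <- occupancy_model(794, receptors_per_cell = 49146)  # K_D = 794 nM
100 * tetra_fraction(fractional_occupancy(186, 794))
#> [1] 0.129762            # ~0.13% of receptors are tetra-liganded
tetra_count(186, m)
#> [1] 63.77282            # about 60 receptors per cell
tetra_fold_change(60, 90, 794)
#> [1] 4.409481            # a 60 -> 90 nM step multiplies that number 4.41x

# What concentrations put 5, 10, 20 tetra-liganded receptors in one cell?
concentration_for_count(c(5, 10, 20), occupancy_model(794, 9101))
#> [1] 143.5350 176.7379 219.4190   # nM

# Simulate a single cell stimulated with 143 nM IP3
pr <- addition_protocol(0, 143, kd = 794, receptors_total = 9101)
tr <- simulate_protocol(pr, gating_rates(), seed = 1, duration = 60)
max(tr$O4)
#> [1] 3                   # at most 3 of the 5 tetra-liganded receptors open
er <- integrate_er(tr, er_params())
range(er$C_ER_uM)
#> [1] 487.5677 500.0000   # a ~2.5% quantal dip in store content

# Generate a noisy synthetic plate-reader trace and invert it
trace <- generate_trace(template_library()$leak_only, noise_model(0.01, seed = 5))
analyze_trace(trace)
#> Trace reconstruction
#>   leak rate (mono-exp fit): 0.0001798 /s
#>   k_leak at reference     : 0.0001798 /s
#>   analysis span           : 450.72 to 1399.68 s (660 samples)
```

The recovered leak rate sits within 0.2% of the generating
1.8×10⁻⁴ s⁻¹.

A command-line entry point wrapping the same functions is installed at
`inst/cli/quantalca` (subcommands `occupancy`, `simulate`, `analyze`,
`generate`).

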