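---
title: "Ionization detail: from cluster-size spectra to cell survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionization detail: from cluster-size spectra to cell survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iondetail)
library(dplyr)
```

## The model

A charged particle crossing a cylinder of nanometre dimensions (a stand-in
for a short DNA segment, roughly one helical turn at 2.3 × 3.4 nm) leaves a
random number ν of ionizations. The distribution `P_ν` over ν — the ionization
cluster size distribution, ICSD — is the package's central object, stored
dense from ν = 0 (traversals with no ionization count as events) to an
explicit ν_max with no extrapolated tail.

Three statistics summarize an ICSD:

* the mean cluster size `M1 = Σ ν P_ν`;
* the cumulative probability `Fk = Σ_{ν≥k} P_ν`, which weights the spectrum by
  a hard step: 0 below k, 1 at or above. F2 expresses the minimal condition
  for a double-strand break (two ionizations), but any fixed k treats a
  2-ionization cluster and a 50-ionization cluster alike, and stepping from
  Fk to Fk+1 is discontinuous;
* `R2(p) = Σ_ν P_ν w(ν, p)` with
  `w(ν, p) = 1 − (1−p)^ν − ν p (1−p)^{ν−1}`, the probability of at least two
  lesions when each ionization independently becomes a sub-lethal lesion with
  probability `p`. The weight rises smoothly from ν = 2, saturates at 1 for
  large clusters, and is continuous in `p`; `R2(1) = F2` exactly.

Two exact identities anchor the implementation and are enforced in the test
suite at tight tolerances:

1. **Thinning equivalence.** Binomially thinning the spectrum with
   per-ionization registration efficiency η (`thin_icsd()`) and then taking F2
   equals R2(η) on the original spectrum. This is why R2 is measurable by a
   real nanodosimeter whose counting efficiency is tuned to η = p. Thinning
   also scales the mean exactly: `M1(thin(P, η)) = η M1(P)`.
2. **Slope form of the cross section.** With linear-quadratic survival
   `−ln S = αD + βD²`, the inactivation cross section at survival level S,
   `σ_S = (k/ρ)·LET·sqrt(α² − 4β ln S)` (k = 0.1602 for LET in keV/µm, σ in
   µm²), equals `(k/ρ)·LET·(α + 2βD_S)` — the local slope of `−ln S` at the
   iso-survival dose. At β = 0 it reduces to the pure linear form
   `(k/ρ)·LET·α`.

The link between the two worlds is the proportional model `σ_S ≈ K · R2(p; d)`
fitted by `grid_fit()`: for every target diameter `d` present in the quantity
grid and every `p` on a grid (default 0.2–1.0, step 0.01), records' cross
sections are paired with `R2(p)` interpolated to each record's energy, the
scale `K` minimizing the unweighted χ² (plain sum of squared differences) is
solved in closed form (`K = Σσr / Σr²`; a K-grid scan mode exists and agrees
within one step), and the χ² surface — normalized to its maximum — is scanned
for its minimum.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p` | scanned 0.2–1.0, step 0.01 | probability an ionization yields a sub-lethal lesion; both ends configurable, validated to [0, 1] |
| `d`, `h` | 1–2.3 nm, h = 1.48 d | cylinder diameter and height; `d` enters only by selecting which grid is used — no geometric interpolation |
| `K` | free (closed form) | saturation scale of the proportional model, µm² |
| survival level `S` | 0.05 | iso-effect level for dose, RBE and σ; at 5% the σ(LET) relationship is particle-independent for V79 cells |
| `k`, ρ | 0.1602, 1 g/cm³ | dose–fluence conversion constant and medium density |
| mean energy per ionization | 30 eV | toy convention converting LET (1 keV/µm = 1 eV/nm) to the primary-ionization rate of the synthetic track model |
| cluster multiplicity | 0.6 | mean geometric number of extra ionizations per primary; sets overdispersion (variance/mean = 1 + 2m) |
| radial σ | 1.0 nm | lateral displacement of ionizations; sets the in-cylinder retention 1 − exp(−(d/2)²/2σ²) and hence the d-dependence |

The energy grid (40 points, log-spaced over 0.2–1000 MeV/u) and the
ion set (¹H … ²⁸Si) mirror the breadth of typical simulated datasets while
keeping grid construction fast (a full grid builds in ~10 s).

## Interpolation choices

Quantities are tabulated on the energy ladder and interpolated to experiment
energies with a *local* three-point Lagrange quadratic in log10(E), using the
nearest bracketing triple. This reproduces grid values exactly at grid points
and avoids the oscillation a single global polynomial would show over nearly
four decades of energy; extrapolation beyond the grid span is refused rather
than guessed. Ions missing from a grid are estimated by a least-squares
quadratic in atomic number Z across donor ions at fixed energy per nucleon
(at least three donors spanning the target Z); a leave-one-out check on the
synthetic grids keeps this honest.

## What the synthetic generator emulates — and what it does not

`simulate_icsd()` implements a deliberately minimal track segment: primaries
along the cylinder axis as a 1-D Poisson process (rate = LET / 30 eV), each
spawning 1 + Geometric(m) ionizations, each ionization displaced laterally by
an isotropic 2-D Gaussian and kept only inside the cylinder. The analytic
counterpart (`synthetic_icsd_table(method = "analytic")`) evaluates the same
model exactly: the per-primary cluster-size pmf is binomially thinned by the
in-cylinder probability and compounded over Poisson primaries. The compound
pmf is computed via the FFT of its probability generating function,
`exp(µ(C(z) − 1))`, which stays numerically stable at the large means
(µ of several hundred) where a recursion starting from `exp(−µ)` underflows;
truncation points are chosen so the discarded tail is below 1e−12.

This reproduces the *statistical* anatomy of nanodosimetric spectra — Poisson
primaries, clustered secondaries with overdispersion, geometric escape that
makes small targets see smaller clusters — but none of the physics of real
track structure: no energy-dependent ionization cross sections, no electron
transport, no wall effects, no gas-to-liquid scaling. The toy LET model
(`toy_let()`: a Z²/E^0.78 power law capped harmonically at a Z-dependent
saturation) exists only to give internally consistent radiation qualities.
Passing tests therefore demonstrate that the *estimators and the fitting
machinery* are correct and identifiable, not that any particular (p, d, K)
value describes real cells.

`generate_survival_dataset()` closes the loop: records are constructed so the
cross section equals `K·R2(p)` exactly before multiplicative lognormal noise,
then inverted through the σ formula to (α, β) at a fixed α/β = 5 Gy (typical
of V79 fibroblasts; a fixed-β policy exists and floors β to 0 when
infeasible, with a logged flag). Reference-photon parameters (α = 0.184 Gy⁻¹,
β = 0.02 Gy⁻²) are attached so RBE is computable. Every stochastic operation
takes one explicit integer seed.

## Numerical and design decisions

* `w(ν, p)` is evaluated in log space (`exp(ν log1p(−p))`), accurate deep into
  the p → 1 regime; ν ∈ {0, 1} and p ∈ {0, 1} are handled as exact limits.
* ICSD construction renormalizes silently only within 1e−6 of closure
  (counts-to-probability rounding) and errors beyond; constructed spectra sum
  to 1 within 1e−9.
* The negative-β correction maps (α, β<0) to the purely linear
  (α + βD_S, 0), the unique linear curve preserving the iso-survival dose at
  the working level; it always lowers α, and pairs whose curve never reaches
  the level are flagged invalid and excluded with reason codes rather than
  silently patched.
* χ² is unweighted because survival databases generally lack usable
  uncertainties; `K` is optimized per (p, d) cell.
* Surface ties (the fit's known shallow valley) are broken toward larger `d`
  then smaller `p`, and the tie count is reported rather than hidden.
* Noise-free recovery studies scan all geometries and must select the true
  one; noisy recovery is assessed with the geometry fixed at 2.3 × 3.4 nm —
  the same convention under which a single best `p` is quoted — because the
  valley makes (p, d) jointly only weakly identifiable at realistic noise.

## Problem sizes used in the checks

The packaged test-suite and the acceptance script use: 100 random ICSDs for
the R2(1) = F2 identity (1e−12), brute-force binomial sums up to ν = 60 × 21
p-values (1e−10), 10⁶-sample Monte-Carlo thinning (3 binomial standard
errors), 150-record survival studies, 20 seeded noisy replicates for recovery
(p within ±0.05, K within ±15%) and for the model comparison (R2-based model
≥ every single-Fk model in at least 18 of 20), and 10⁵-history simulator
calibration against the exact Poisson and compound-Poisson moments.

## Known limitations

* The ICSD model has no spatial correlation along the track beyond the
  per-primary cluster; real δ-ray structure is richer.
* The single-target R2 ignores that a true DSB needs one break on *each*
  strand; modelling that would require two neighbouring targets and would no
  longer be measurable with a single-volume nanodosimeter.
* No uncertainty quantification beyond seeded-replicate spread; the χ² is not
  a calibrated goodness-of-fit statistic.
* `interpolate_missing_ion()` assumes smooth Z-dependence at fixed energy per
  nucleon; it is a fallback, not a substitute for direct tabulation.
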