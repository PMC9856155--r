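---
title: "Methods: combined PCA of homologous trajectories and global CSP titration fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined PCA and CSP titration fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsel)
```

## Scope and rationale

`dynsel` implements a comparative analysis of molecular-dynamics
trajectories from several homologous protein systems, asking two distinct
questions per collective coordinate: do the systems differ in *average
structure*, and do they differ in *dynamics*? The motivating application
is ligand selectivity between thermophilic and mesophilic homologues of an
enzyme domain, where a residual "breathing" motion of the fold in one
complex — quenched in the others — destabilises binding. The package also
implements the NMR titration side of such a study: weighted combined
chemical-shift perturbations and a global one-site dissociation-constant
fit.

Running the MD simulations themselves is out of scope; the package starts
from trajectories (multi-model PDB) and from per-residue titration tables,
and ships a synthetic generator that emulates both so the full pipeline is
testable against planted ground truth.

## Preprocessing and superposition

Trajectories are reduced to Cα atoms, split into single-subunit
trajectories, and concatenated in configuration order (subunits in
chain-id order) with per-frame provenance tags. Residues are matched
across equal-length homologous constructs by the identity map by default;
any other correspondence must be supplied explicitly as a two-column map,
because sequence alignment is out of scope.

Superposition uses the Kabsch algorithm with uniform weights on all Cα
atoms (no mass weighting, no core-selection heuristics; a selection mask
can be emulated by subsetting atoms upstream). The SVD reflection branch
is always corrected to det(R) = +1, so a mirror image can never be "fit"
by an improper rotation. The alignment reference is the iteratively
refined ensemble mean — not the first frame and not a crystal structure —
which is standard essential-dynamics practice and keeps the reference free
of single-frame noise: frames are superposed onto the running mean, the
mean is recomputed, and the cycle repeats until the mean moves by less
than 1e-4 Å RMSD (default) or 20 iterations. Non-convergence produces a
warning, not an error, because a slightly drifting mean biases eigenvalues
far less than discarding the run would.

## Combined PCA

The covariance of the concatenated, aligned Cα coordinates about the
combined mean is diagonalised (via SVD of the centred frame matrix, which
is numerically equivalent to the dense eigensolve and cheaper when frames
outnumber coordinates — the package's tests compare the two routes
explicitly). Population (1/F) normalisation is used so that the eigenvalue
λ_i exactly equals the variance of the projections on v_i; the same
convention is used for every r.m.s.f., which makes the identities in the
test suite exact rather than approximate.

Two choices here were genuinely open:

- **r.m.s.f. in projection** is the standard deviation about the *system's
  own mean*, not the RMS about the global zero. The two diagnostics are
  meant to be independent — average projection reports on structure,
  r.m.s.f. on dynamics — and RMS about zero would mix a mean offset into
  the fluctuation measure.
- **Eigenvector sign** is fixed by orienting each eigenvector so its
  largest-magnitude component is positive. Signs are mathematically
  arbitrary; this rule makes reports reproducible. It does *not* guarantee
  correspondence with any external reference direction, so comparisons
  against planted modes align signs via the dot product first.

Degenerate eigenvalues are ordered by the SVD's descending singular
values; exact ties are vanishingly rare for floating-point data and are
left to the LAPACK ordering, which is deterministic for identical input.

Pseudo-trajectories interpolate `mean + s·v` with `s` equally spaced over
the observed projection range of the fitted trajectory (default), showing
the motion actually sampled; a symmetric ±k·√λ span is available when a
variance-calibrated sweep is preferred. A zero-variance PC has no
meaningful span and is an error. Per-residue r.m.s.f. within a mode,
√λ·‖v_residue‖, is written into the B-factor column of the
pseudo-trajectory PDB so standard viewers can colour the motion.

## Titration analysis

The combined CSP is √((Δδ_H W_H)² + (Δδ_N W_N)²) with W_H = 1 and
W_N = 0.154, the conventional weighting for backbone amides. Binder
selection applies a *strict* threshold (default CSP > 0.05 ppm at 2 mM
ligand): a residue sitting exactly at the threshold is excluded.

The fit uses the exact one-site isotherm with ligand depletion, which is
required because protein (~0.5 mM) and dissociation constants (0.3–14 mM)
are comparable; the hyperbolic approximation L/(L+K_D) is accurate to
about 1% of saturation only once K_D ≥ 20·P (a property the test suite
checks numerically). All selected residues are fitted simultaneously —
raw, unnormalised CSPs, one shared K_D, one Δ₀ per residue — by
Levenberg–Marquardt with bound constraints (K_D > 0, Δ₀ ≥ 0) and a
multi-start over a log-spaced K_D grid (10^-1.5 to 10^1.8 mM, 7 starts),
which removes any sensitivity to the initial guess across the supported
affinity range. Protein concentration is a fixed input, never a fitted
parameter. Saturation-normalised, residue-averaged curves with
one-standard-deviation error bars are produced for display only; fitting
on normalised data would propagate Δ₀ errors into the dependent variable.

Uncertainty is reported two ways, because reported "± values" in the
literature rarely state their provenance: asymptotic standard errors from
the Jacobian covariance at the optimum, and an optional seeded residual
bootstrap (199 resamples by default when enabled). On the synthetic
conditions the two agree to well within an order of magnitude.

## The synthetic-data generator

The generator defines the study conditions; it is first-class, tested
code, not a fixture.

- **Scaffold**: a self-avoiding random walk with 3.8 Å Cα–Cα steps,
  compacted by a radius cap (≈15 Å for 100 residues), with identical
  chains related by a rigid translation — protein-like dimensions without
  depending on any real structure.
- **Modes**: random displacement fields built from the first four chain
  harmonics (so they are spatially smooth, like real collective motions,
  not white noise), with the six rigid-body degrees of freedom projected
  out *before* orthonormalisation. Internal modes are essential: any
  rigid-body content in a planted mode would be absorbed by the
  superposition step and distort recovery for reasons unrelated to the
  PCA itself.
- **Trajectories**: frame t is x_ref + Σ_k (μ_k + a_k z_tk)·v_k + ε, with
  z i.i.d. standard normal and ε isotropic Gaussian coordinate noise.
  For a multi-chain structure with a subunit-level mode set the modes are
  applied chain-locally with independent coefficients per chain —
  equivalently, a block-diagonal orthonormal mode set over the full
  structure sharing μ/a across chain copies — so each split subunit
  trajectory independently carries the planted statistics (projection
  mean μ_k, sd a_k).
- **Titrations**: per-residue combined CSPs follow the depletion isotherm
  exactly; a per-residue angle θ ~ U[0, π/2] splits each combined value
  into ¹H and ¹⁵N components (component-wise shifts are never reported in
  this kind of study, only combined CSPs, so any split consistent with
  the combination identity is admissible). Shifts at L = 0 are exactly
  zero by definition; Gaussian noise is added at L > 0 only.

Default study conditions: 4 systems × 2 subunits × 1000 frames × 100
residues; mode amplitudes (3, 2, 1) Å with coordinate noise 0.2 Å; mean
shifts ±2 Å on mode 1 splitting the systems into two structural pairs; one
system with a doubled mode-2 amplitude (the "present in one, quenched in
the others" pattern); titration with K_D = 0.6 mM, P = 0.5 mM, ligand grid
0–8 mM, ten 0.3 ppm binding residues, ten spectators, 0.002 ppm noise.
Where no empirical effect sizes exist for the collective modes, these
values were chosen once for clear separability at desk scale — amplitudes
well above the noise floor, mean shifts resolvable at ~10³ frames — and
are not tuned thereafter.

What the generator does **not** emulate: anharmonic or multi-well
free-energy surfaces, time correlation (frames are i.i.d., so no
autocorrelation-aware error analysis is exercised), solvent or ligand
atoms, heavy-tailed noise, and exchange-regime NMR effects. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to every pathology of real MD or NMR
data.

## Numerical choices and degenerate inputs

- Covariance eigensolve via `svd()` of the centred frame matrix;
  brute-force covariance assembly + `eigen()` is the independent oracle in
  tests (agreement to 1e-8 relative).
- Kabsch degeneracy (collinear point sets) is detected from the 3×3 Gram
  matrices and raised as a rank error rather than returning an arbitrary
  rotation.
- The global fit runs with tight Levenberg–Marquardt tolerances
  (ftol = ptol = 1e-14, ≤500 iterations per start); noiseless round-trips
  recover planted K_D to better than 1e-4 relative across 0.1–20 mM.
- Histograms use left-closed right-open bins (default 0.25 Å over
  [0, 20) Å); means are always computed on the raw series, never from bin
  centres.
- All randomness flows through per-stage substreams derived from one root
  seed; generated data are bitwise reproducible per seed on a given
  platform.

## Problem sizes

The packaged analyses and tests run at desk scale, chosen to exercise
every pipeline branch with comfortable statistical margins: the full
synthetic study (8 subunit trajectories, 8000 combined frames, 300
coordinates) completes in well under a minute, and the noisy
dissociation-constant recovery uses 100 independent titration replicates.
The estimators themselves are dimension-agnostic; nothing in the
implementation assumes these sizes.

## Known limitations

- Multi-model PDB is the only trajectory interchange format; binary
  formats (DCD/XTC) would slot in behind `read_trajectory()` but are not
  implemented.
- The identity residue map is the default; no sequence alignment is
  performed.
- No time-lagged (tICA) or nonlinear dimensionality reduction; no frame
  clustering or free-energy surfaces.
- One-site binding only; no multi-site models or exchange line-shape
  analysis.
- PCA assumes the superposition has removed all rigid-body motion; for
  highly flexible systems where superposition is ill-defined, combined
  PCA diagnostics conflate alignment artefacts with internal motion.
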