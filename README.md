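# dynsel

Comparative conformational-dynamics analysis for homologous protein–ligand
systems, combining:

1. **Combined principal component analysis (PCA)** of concatenated,
   superposed Cα trajectories from several related systems, with the
   per-system diagnostics that make cross-system comparison possible, and
2. **NMR chemical-shift-perturbation (CSP) titration analysis** with a
   global one-site dissociation-constant fit using the exact
   ligand-depletion isotherm.

The package is aimed at structural biologists asking *why a ligand
recognises one homologue over another*: differences in average structure
show up as shifted average projections on a shared eigenbasis, while
residual collective motions that destabilise a complex (e.g. a breathing
motion of a β-barrel that is quenched in a rigid thermophilic scaffold but
not in its mesophilic homologue) show up as excess r.m.s.f. in projection.
A synthetic-data generator plants known collective modes and binding
parameters so every stage has a ground-truth recovery test.

## The model

**Combined PCA.** Trajectories of all systems are reduced to Cα atoms,
split into single-subunit trajectories, concatenated, and iteratively
superposed onto the ensemble mean (Kabsch rigid-body least squares,
uniform weights, proper rotations only). With frame coordinates
x_t ∈ R^(3N) and combined mean x̄, the covariance C = (1/F) Σ_t
(x_t − x̄)(x_t − x̄)^T is diagonalised into eigenpairs (λ_i, v_i). For
each system S and PC i the two observables are

- average projection ⟨p⟩_S = mean over t∈S of (x_t − x̄)·v_i — differences
  mean different *average structures* along that collective coordinate;
- r.m.s.f. in projection = sd of (x_t − x̄)·v_i about the system's own
  mean — differences mean different *dynamics* in that collective motion.

Pseudo-trajectories x̄ + s·v_i over the observed projection range
visualise each motion; per-residue r.m.s.f. in a mode is
√λ_i · ‖(v_x, v_y, v_z)‖ per residue.

**Titration.** Amide shifts are combined as
CSP = √((Δδ_H·W_H)² + (Δδ_N·W_N)²) with W_H = 1, W_N = 0.154. Residues
with CSP > 0.05 ppm at 2 mM ligand are fitted simultaneously (one shared
K_D, one saturation amplitude Δ₀ per residue) with the exact depletion
isotherm

    CSP(L) = Δ₀ · [P + L + K_D − √((P + L + K_D)² − 4PL)] / (2P)

by Levenberg–Marquardt least squares with a multi-start over a log-spaced
K_D grid; uncertainties come from the Jacobian covariance, optionally from
a seeded residual bootstrap.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic conditions (4 systems × 2 subunits × 1000 frames × 100 residues;
planted mode amplitudes 3/2/1 Å, coordinate noise 0.2 Å; mean shifts ±2 Å
on mode 1; one system with a doubled mode-2 amplitude):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_combined_pca.R
Rscript analysis/04_contacts.R
Rscript analysis/05_titration.R
```

Stage 3 prints the per-system diagnostics on the shared eigenbasis:

```
 system pc avg_proj_A rmsf_A
   sysA  1   1.938801  3.044
   sysB  1   1.981919  3.060
   sysC  1  -2.003426  3.057
   sysD  1  -1.917294  2.991
   sysA  2   0.055374  3.971
   sysB  2  -0.012742  1.963
   ...
principal angles to the planted mode subspace: 0.65, 0.82, 2.21 deg
```

PC 1 separates the two pairs of systems by average structure (±2 Å planted,
recovered within 0.1 Å); PC 2 exposes the system whose collective motion is
*not* quenched (r.m.s.f. 3.97 Å vs ≈ 1.97 Å, the planted 2× amplitude).
Stage 5 fits the synthetic titration:

```
10 of 20 residues exceed 0.05 ppm at 2 mM ligand: r1 r10 r2 ... r9
global fit: KD = 0.600 +/- 0.006 mM (bootstrap +/- 0.005); planted 0.600 mM
```

The same operations are available directly (`make_toy_structure`,
`make_mode_set`, `simulate_system_trajectory`, `select_calpha`,
`split_chains`, `concatenate_trajectories`, `align_to_mean`, `fit_pca`,
`project_trajectory`, `system_stats`, `pseudo_trajectory`,
`distance_series`, `distance_histogram`, `combined_csp`, `select_binders`,
`fit_global`, ...), or end-to-end via `run_pipeline(default_run_config())`.

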