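---
title: "Multi-state multi-condition refinement: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state multi-condition refinement: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msxtal)
```

# The model

`msxtal` treats a crystal as a mixture of N discrete conformational states.
A model is the pair (states, weights): N complete atomic conformations of
identical composition, and an N×J weight matrix whose column j holds the
normalized populations of the states under experimental condition j. The
posterior density of a model given J amplitude datasets factorizes into a
product of per-dataset likelihoods and a per-state prior; the package works
throughout with the score `S = Σ_j (-log L_j) + Σ_i E_prior(M_i)`, dropping
normalization constants and the partition function (their gradients vanish
and rankings are unaffected; any overall scale mismatch between the two
terms is absorbed by the automatic gradient balance described below).

## Forward model

Structure factors are computed by direct summation over atoms and symmetry
operators, `F(h) = Σ_ops Σ_a occ_a f_a(stol) exp(-B_a stol²)
exp(2πi h·(Rx+t))`, with `stol = 1/(2d)` and the `exp(+2πi h·x)` phase
convention. The multi-state amplitude is the exact complex weighted sum
`F_C = Σ_i w_ij F_i`: a crystal whose cells are randomly assigned to
states, partially occupied by both, or segregated into blocks produces the
same Bragg amplitudes in the large-crystal limit, so the weighted sum is
the correct (and cheapest) forward model. The degeneracy experiment
(`degeneracy_experiment()`) demonstrates this numerically with finite
crystals; the partial-occupancy configuration is exact at every crystal
size by linearity of the Fourier transform, and the implementation
exploits that the crystal transform restricted to the single-cell
reciprocal lattice equals the transform of the cell-summed density (cells
enter only through their counts), so one single-cell FFT suffices.

One reading choice: the "labels swapped" configuration is implemented as a
statistically identical relabeled realization of the per-cell-random
configuration (state 2 drawn with probability w2). Reading it instead as
swapping the probabilities themselves would converge to `w2 T1 + w1 T2`,
which contradicts the convergence the experiment is meant to show. The
"two separate crystals" configuration defaults to two blocks in one
coherent volume, which converges exactly; the optional incoherent variant
(intensities add) retains the interference cross-term
`2 w1 w2 Re(F1 F̄2)` and is documented as *not* converging to the coherent
reference — it is provided for comparison, not as an equivalent reading.

Bulk solvent is a flat binary mask (probe 1.1 Å, shrink 0.9 Å, grid
d_min/4) around the weighted-average structure, Fourier transformed and
scaled by `k_mask`; it is off by default for toy work and differentiable
quantities treat `F_B` as fixed between refreshes.

## Likelihood and nuisance parameters

Each amplitude follows the Rice density (acentric) or the folded-normal
density (centric) around `α|F_M|` with variance `εβ`. Both branches are
evaluated in log space; `log I0` switches to the asymptotic expansion above
argument 700, so arguments up to 1e6 and beyond are safe. The per-shell
nuisance parameters are deliberately simple and fully deterministic:
`k_total` and `k_mask ≥ 0` minimize the work-set least-squares amplitude
residual (the `k_mask` profile need not be unimodal on toy cells, so a
coarse grid scan brackets the optimum before 1-D refinement); `α` is
initialized at 1; `β` per shell is the moment estimate
`mean((F_obs-|F_M|)²/ε)`, floored at `1e-3·⟨F_obs²⟩` so a perfect fit
cannot produce a degenerate zero-variance likelihood. Shells hold at least
20 work reflections (10 shells by default, merged when data are scarce).
Full joint maximum-likelihood estimation of (α, β) is not implemented; the
moment estimate refreshes every macro-cycle and is adequate for the
synthetic studies this package targets. Free reflections are excluded from
the likelihood and from every nuisance fit — they exist only for Rfree.

During dynamics the per-reflection derivative `d(-log p)/d|F_M|` is frozen
as a local quadratic (value, first and second derivative at the refresh
point) and refreshed every macro-cycle; the exact derivative is available
behind `exact_gradient = TRUE` and the two agree at the refresh point by
construction.

## Prior

The per-state prior is a simplified CHARMM-style force field: harmonic
bonds and angles, periodic dihedrals, harmonic impropers, and
Lennard-Jones `ε[(Rmin/r)¹² - 2(Rmin/r)⁶]` with 1-2/1-3 exclusions, a
configurable 1-4 scale (default 1), and a switched cutoff (7.5–9 Å).
Electrostatics are deliberately absent. States are isolated molecules — no
periodic images, so crystal packing contacts are not modeled. A minimal
embedded parameter set (`toy_forcefield()`, alanine-like types) ships for
the synthetic systems; external files in the sectioned text dialect can be
loaded, with completeness the user's responsibility.

# Sampling

Sampling draws models from the posterior with biased Langevin dynamics
(BAOAB splitting; velocity Verlet is the zero-friction limit, which the
tests use to check energy conservation). Defaults, all exposed in
`sampler_config()`:

| parameter | default | why |
|---|---|---|
| temperature | 5000 K | rugged multi-state landscape needs aggressive exploration; the thermostat absorbs the non-conservative X-ray force |
| w_xray sweep | 1.0, 0.5, 0.25 | mild under-weighting of the likelihood gradient improves exploration |
| timestep | 1 fs | hydrogens present, no constraints; blow-ups are caught, flagged, and truncate the trajectory without failing the batch |
| friction | 1 ps⁻¹ | light coupling; enough to thermostat the non-conservative force |
| macro-cycle | 100 steps | nuisance refit, quadratic-target refresh, w_auto update and snapshot cadence |
| cg polish | ≤500 iters, grad RMS 1e-3 | Polak-Ribière with Armijo backtracking; the best point seen is returned, so the polished score never exceeds the input score |

`w_auto` is recomputed at every macro-cycle as mean(|prior gradient|) /
mean(|likelihood gradient|) over all atoms of all states (clamped at 1e6
when the likelihood gradient vanishes), so after scaling the two average
per-atom magnitudes are equal. Weights are drawn once per trajectory from
the flat Dirichlet (the uniform density on the simplex — the natural
uninformative choice when no sampling distribution is prescribed);
mid-trajectory resampling is available behind
`resample_weights_every` for experimentation. Velocities and thermostat
noise are pre-generated per state from per-state seeds, which makes
trajectories bit-reproducible and makes the state-relabeling symmetry
exact: permuting states, weight rows and per-state seeds permutes the
trajectory.

# Synthetic data

`build_toy_native()` emulates the heterogeneity of a real two-state
crystal: a peptide-like helical chain (backbone N-CA-C=O plus a CB-HB side
group per residue) whose second state differs by a smooth 0.3 Å-RMS
backbone displacement and per-residue rigid side-group rotations scaled to
1.5 Å RMS — small backbone, large side-chain deviations. Rotation axes are
chosen from a candidate pool by steric clearance, so state 2 is a
plausible strained alternate conformation rather than a clash pile-up. All
B-factors are 15 Å², all occupancies 1. The default weight matrix
`[0.8 0.3; 0.2 0.7]` makes state 1 dominant under condition 1 and state 2
under condition 2, mimicking a low/high temperature pair.

`simulate_datasets()` enumerates the complete unique reflection list to
d_min (default 2.0 Å), computes noiseless amplitudes per condition with
the native's weight column, and adds relative Gaussian noise with
`sd = σ·amplitude` (default σ = 5%; relative rather than absolute noise,
because the noise level is naturally quoted as a percentage), clamping at
zero and recording the sigma column. One shared free set (default 5%, 10
resolution bins — values the package chooses, both configurable and
logged) is assigned across all conditions, because the simulated datasets
are perfectly correlated and per-dataset free sets would leak information.

What the generator does **not** emulate: experimental artifacts (radiation
damage, absorption, partiality), solvent scattering, anisotropy,
measurement-error heteroscedasticity beyond the relative model, and real
rotamer libraries. Passing tests on these toys show the machinery is
correct and self-consistent, not that the method's accuracy transfers
quantitatively to experimental data.

# Problem sizes used by the tests and the acceptance script

The shipped studies are deliberately desk-scale: 8–16 residues per state
(48–96 atoms), 2.5–3 Å synthetic data (≈800–1800 unique reflections in a
P1 box), 8 trajectories × 3 w_xray values of 200 steps with 40-step
macro-cycles, 60 polish iterations, 200-decoy landscapes, and degeneracy
crystals up to 8³ cells on a 32³-per-cell grid. These sizes make the full
benchmark reproducible in minutes on one CPU while keeping every
qualitative feature of the method exercised.

# Design choices that were genuinely open

* **Dynamics flavor.** Langevin (BAOAB) rather than a deterministic
  thermostat: the X-ray force is non-conservative, and stochastic
  thermostatting is robust to it. Friction, not velocity rescaling,
  maintains T.
* **Decoy generation.** Conformation decoys come from short prior-only
  dynamics bursts started at the native, binned by RMSD* and re-sampled to
  near-uniform coverage of the accuracy range; weight decoys redraw the
  weight matrix at native conformations. The landscape score is the joint
  negative log-likelihood (nuisance refit per decoy), the quantity the
  benchmark design varies.
* **RMSD\*.** Computed on raw coordinates in the crystal frame, no
  superposition (the metric compares models of the same crystal); a
  superposed variant exists but is not the default. Ties in best-model
  selection break by lower total score, then earlier trajectory.
* **Reflection bookkeeping.** One asymmetric-unit representative per
  reflection, chosen as the lexicographically largest symmetry/Friedel
  equivalent — deterministic and testable. Systematic absences are
  rejected on input. Epsilon is the magnitude of the phase-consistent
  count of operators fixing h, which reproduces the standard
  intensity-enhancement factors and flags absences as zero.

# Known limitations

* Direct summation only — fine at toy scale, O(atoms × reflections) per
  evaluation; no FFT-based structure factors, no anomalous scattering, no
  anisotropic scaling, no intensity-based likelihood.
* The prior is minimal: no electrostatics, no CMAP/Urey-Bradley, no
  periodic images. It regularizes geometry; it is not a production force
  field.
* Occupancies and B-factors are fixed by the discrete-state
  representation; the sampler refines coordinates and weights only.
* At desk scale the 2-condition vs 1-condition comparison for a single
  dataset can be a statistical tie: with a 0.4 Å start and conjugate
  gradient polishing, both runs reach the 5% noise floor, and with ~90
  free reflections the Rfree difference between them (≲0.005) is within
  free-set sampling noise. The 2-state vs 1-state ordering and weight
  recovery are robust; the condition-count ordering becomes informative
  only on harder problems (larger systems, farther starts, or less data),
  which is consistent with the advantage being a sampling effect.
* MTZ files are not read or written; the CSV reflection dialect is
  canonical. PDB/mmCIF model output carries state weights in a JSON
  sidecar, since neither format has a weight field.
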