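---
title: "Pressure-perturbation analysis of protein ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-perturbation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presstraj)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter and
why they have the defaults they do, and what the synthetic-data tests do
and do not establish about real trajectories.

## The scientific setting

Actins of deep-sea grenadiers differ from shallow-water and terrestrial
actins by only two or three residues (Q137K near the ATP/Mg²⁺ site plus
V54A or L67P on the subdomain-2 surface), yet their polymerisation and
nucleotide binding tolerate pressures around 60 MPa that strongly
perturb the other variants. Explaining that tolerance requires comparing
ensembles of the protein at low (0.1 MPa) and high (60 MPa) pressure
through several lenses at once: packing (excluded volume, SASA,
compressibility), energetics (a thermodynamic cycle for the
pressure-induced free-energy shift), electrostatic architecture (salt
bridges by structural context), and active-site geometry (the water
poised to attack the ATP γ-phosphate). The package implements each lens
as a module over a common structure/trajectory model, plus generators
that produce inputs with analytic ground truth so every estimator is
testable without any simulation engine.

The default study conditions — 277 K, pressure labels 0.1 and 60 MPa,
3.2 Å salt-bridge cutoff, 1.4 Å probe, five entropy blocks — are the
conditions of the deep-sea actin comparison and are collected in
`run_config()`.

## Volume, surface, compressibility

`excluded_volume()` integrates the union of probe-inflated spheres by
counting grid cells whose centroid falls inside any sphere; 0.25 Å cells
keep the error on analytic fixtures below 1% and the function refuses
grids coarser than 0.5 Å. `sasa()` places a deterministic generalized
spiral lattice (default 960 points, < 1% error on spheres) on each
inflated atom and counts points outside all other inflated spheres;
hydrogens carry no sphere because the radius classes are united-atom
style: 2.0 Å for sp³ C, sp³ N and S–H; 1.85 Å for sp² C with hydrogens
and bare S; 1.8 Å for sp² N with several hydrogens; 1.7 Å for bare sp²
C and single-H sp² N; 1.4 Å for O. Class assignment is template-based
over the 20 amino acids plus ATP, and unknown atoms are an error rather
than a silent default, because a wrong radius corrupts both V_ex and
the nonpolar solvation term downstream.

`isothermal_compressibility()` implements the fluctuation estimator
κ_T = Var(V)/(k_B T ⟨V⟩). The operation accepts any positive volume
series. Which volume to feed it is a genuine ambiguity: for a simulation
box the estimator returns the solution's compressibility; protein-sized
values (0.13–0.15 GPa⁻¹, an order below water's 0.49 GPa⁻¹) arise when
the per-frame series is the protein's own excluded volume, so the
pipeline documents per-frame V_ex as its default input and leaves box
series supported. `gen_volume_series()` inverts the estimator
(Var = κ k_B T ⟨V⟩) so recovery tests have closed-form truth; it refuses
parameter combinations that would produce negative volumes with
probability above 10⁻⁶.

## The free-energy cycle

The pressure-induced shift is assembled by `free_energy_shift()` as
ΔG = ΔE_conf + ΔΔμ − TΔS, the cycle in which the solute is desolvated at
low pressure, changed in vacuum from the low- to the high-pressure
conformational state, and resolvated at high pressure; the cycle assumes
solvation itself does not relax the endpoint structures.

- **ΔE_conf** is the change in mean solute conformational energy,
  consumed from per-frame energy tables (`mean_conformational_energy()`).
  The package deliberately does not re-implement a force field; its
  `nonbonded_energy()` (vacuum Coulomb + 12-6 LJ) exists so synthetic
  fixtures can carry self-consistent energies.
- **Δμ_polar** comes from a finite-difference two-dielectric Poisson
  solve (`polar_solvation()`): trilinear charge spreading, harmonic-mean
  edge dielectrics sampled at five points per edge (the series-flux
  average that keeps the normal displacement continuous across the
  cavity boundary), red-black SOR in compiled code to a 10⁻⁷ relative
  update tolerance, analytic screened-Coulomb boundary values, and a
  reference solve with exterior permittivity 1 on the identical grid so
  the grid self-energy cancels exactly. Against the Born closed form the
  solver stays within ~1% at a 0.4 Å grid over radii 1.5–4 Å and
  charges up to ±2 e (the validation sweep allows 5%). The interior
  permittivity defaults to 2, the common continuum compromise for
  electronic polarisation; the exterior comes from `water_dielectric()`.
- **Δμ_nonpolar** is γ(T)·A with γ(277 K) = 0.1091 kcal/mol/Å², scaled
  to other temperatures by the air–water surface-tension ratio; the van
  der Waals attraction term is pinned at zero because its contribution
  is below 0.1%.
- **Water permittivity** uses the Kirkwood dielectric equation with an
  effective orientational correlation (g) factor. The parameterisation
  is calibrated so ε(298.15 K, 0.1 MPa) = 78.4 exactly; temperature and
  pressure then enter through the molecular density (a small built-in
  saturation-density table with a Tait-like compressibility correction,
  replaceable via `density_fun`) and the 1/T Boltzmann factor. The
  calibrated g absorbs the cavity-field corrections a full
  Kirkwood–Fröhlich treatment would carry; what the cycle actually needs
  is the correct ambient anchor and the correct signs of ∂ε/∂p > 0 and
  ∂ε/∂T < 0, both of which the model guarantees by construction.

**Entropy.** S = S_trans + S_rot + S_int. The translational and
rotational terms use the standard closed forms (Sackur–Tetrode at a
1 L/mol standard state, classical rigid rotor with symmetry number 1 by
default); these are the textbook expressions consistent with the symbol
lists (h, M, V, ω_i; I_x, I_y, I_z) the source material prints, adopted
because the equations themselves are only available as images there.
S_int is quasi-harmonic: frames are superposed to remove external
motion, the mass-weighted coordinate covariance is diagonalised, each
eigenvalue λ_i becomes an effective frequency ω_i = sqrt(k_B T/λ_i), and
the quantum harmonic-oscillator entropy (kinetic term included) is
summed over modes. The six smallest eigenvalues are discarded as
residual external motion, plus anything below 10⁻⁸ amu Å² (numerical
null space); both cutoffs are arguments, and the recovery tests disable
them when the generated ensemble contains no external motion at all so
the closed-form truth covers exactly the generated modes.
`block_entropy()` averages S over five contiguous blocks and reports the
across-block mean and population SD, which estimates the sampling spread
rather than propagating per-term errors. For pressure differences the
package propagates SDs in quadrature; the printed spreads in the
literature tables this mirrors are evidently not quadrature (the Arm row
would give 73 rather than 69), so the regression tests assert the means,
not the SDs.

## Interactions

A salt bridge is any (charged N, charged O) pair at ≤ 3.2 Å — boundary
inclusive, matching the "less than or equal to" rule — with all atom
pairs counted, so one Arg–Asp contact can contribute up to six bridges.
The charged set covers Asp/Glu carboxylates, Lys N^ζ, Arg N^η/N^ε,
explicitly flagged protonated histidines (3-methylhistidine is always
protonated), chain termini (the N-terminal amine can be disabled for
acetylated constructs), and ATP phosphate oxygens tagged α/β/γ by
walking the P–O connectivity from the ribose-linked phosphorus.

Classification needs per-residue secondary structure. The assigner
(`assign_secondary_structure()`) is a deliberately simple φ/ψ-window
method — helix: φ ∈ [−100°, −30°] ∧ ψ ∈ [−80°, −5°], minimum run 4;
strand: φ ∈ [−180°, −40°] ∧ ψ ∈ [90°, 180°] ∪ [−180°, −170°], minimum
run 3 — because the classification only consumes H/E/C labels and run
identities, and an externally supplied annotation always takes
precedence. Bridges between two H/E residues of the same run are
intra-helix/strand, of different runs inter-helix/strand; one
H/E + one coil is helix/strand–loop; two coils loop–loop. ATP-involved
bridges bypass these categories and are counted once in the ATP column,
which is what makes both reported identities exact:
Total = (four secondary-structure categories) + ATP
      = inter-subdomain + intra-subdomain + ATP.
The four-lobe subdomain map defaults to SD1 = 1–32 ∪ 70–141 ∪ 338–375,
SD2 = 33–69, SD3 = 142–180 ∪ 270–337, SD4 = 181–269 — a convention
consistent with the hinge residues 141–142/336–337, not a published
boundary list, and fully overridable.

Hydrogen bonds use invented-but-conventional geometric defaults (D–A ≤
3.0 Å, D–H⋯A ≥ 160°), configurable, since the comparison they feed is
qualitative.

## Active site

The nucleophilic-water rule is geometric: θ is the O^β–P^γ–O^w angle
taken from the β–γ *bridging* oxygen — the in-line attack axis opposite
the leaving group, the natural reading where the reference oxygen is
ambiguous, and configurable to any tagged β oxygen — and d_Nu is
P^γ–O^w. Per frame, among waters with θ strictly greater than 109.3°
(the tetrahedral eligibility threshold; "greater than", so the boundary
is excluded), the water with minimum d_Nu is selected, ties broken by
lowest water id. No spatial pre-filter is applied to the water list by
default. The (θ, d_Nu) records accumulate into a 2° × 0.1 Å histogram
converted to free energy as F = ln(max count) − ln(count), which is
exactly zero at the mode and invariant under uniform rescaling of
counts. Mg²⁺ coordination counts oxygens within 2.6 Å (a typical Mg–O
bond is ≈ 2.1 Å) and labels the W-type and Q-type shells that
distinguish the two actin-1 models.

## Rotamers and domain geometry

Side-chain rotamers are the Cartesian product of
gauche−/gauche+/trans = {−60°, 60°, 180°} over the rotatable χ angles
(81 states for lysine's four); the canonical state set is an argument.
`select_rotamer_max_distance()` implements the modelling rule used for
the Q137K substitution: build every rotamer and keep the one whose
probe atom (N^ζ) lies farthest from the bound cation, ties resolved by
lexicographic χ order so the choice is deterministic. Superposition is
Kabsch least squares over base-R SVD, validated against an independent
quaternion (Horn) oracle; RMSD/RMSF selections default to backbone heavy
atoms (N, Cα, C, O). The average structure is the fixed point of
fit-all-frames-then-re-mean, iterated to a 10⁻⁶ Å mean shift with a
100-iteration cap. The propeller angle is the torsion of the four
subdomain centroids in the order (2, 1, 3, 4) — the order and the
all-atom centroid choice are conventions recorded in the output
metadata, since neither is fixed by the published definition — under the
IUPAC sign convention (verified against `bio3d::torsion.xyz`).

## What the synthetic data does and does not show

The generators emulate exactly the statistical features the estimators
consume: Gaussian coordinate fluctuations with prescribed covariance
(optionally rigid-rotated per frame to exercise external-motion
removal), Gaussian volume series with prescribed mean and variance,
charged groups and ATP/Mg/water geometries placed at exact separations
with truth blocks derived from the construction rules rather than from
the code under test, and Born ions with closed-form solvation energies.
Passing these tests establishes correctness of the estimators as
mathematical procedures — unbiased recovery, exact identities, oracle
agreement — under Gaussian, clash-free, single-conformer conditions.
They do not establish robustness to what real trajectories add:
anharmonic and multimodal fluctuations (quasi-harmonic entropy is then
an upper-bound-flavoured approximation), force-field and sampling error
in the energy tables, protonation ambiguity, or correlated volume noise.
Scale is also deliberately modest: validation ensembles are 10–50 atoms
by up to 5 × 10⁴ frames and Poisson grids are ion-sized, sizes chosen so
the whole suite settles in minutes at desk cost while leaving the
algorithms identical at protein scale.

## Numerical choices and degenerate inputs

Distance cutoffs compare with ≤ (the 3.2 Å rule is inclusive); the θ
threshold is strict. Zero-variance volume series return κ_T = 0 rather
than erroring; zero-variance coordinates contribute no entropy modes;
single-occupied-bin histograms are valid and give a single zero-valued
free-energy bin. Collinear or undersized superposition selections,
empty subdomains, missing backbone atoms, unknown residue names and
unparameterised atoms raise informative errors (or a warning plus
exclusion where the contract says so). The Poisson solver reports
non-convergence with its iteration count instead of returning a stale
field. All randomness is seeded; reruns of the pipeline with one config
are byte-identical.

## Known limitations

Union-of-spheres volume is grid-based, not analytic, and the surface is
the probe-center (accessible) surface, not the Connolly re-entrant
surface. The Poisson model is linear, salt-free and two-dielectric. The
secondary-structure assigner is a fallback, not a DSSP replacement. The
g-factor dielectric is a calibrated effective model, not a
first-principles parameterisation. ΔE_conf is only as good as the energy
table supplied. The quasi-harmonic entropy inherits the usual caveats of
treating sampled fluctuations as one harmonic basin.
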