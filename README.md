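# presstraj

Analysis toolkit for asking how hydrostatic pressure perturbs a protein's
conformational ensemble, developed around monomeric (G-)actin and the
deep-sea fish actin variants whose few substitutions (Q137K plus V54A or
L67P) confer tolerance to pressures around 60 MPa. It is aimed at
molecular-simulation practitioners who have per-frame coordinate,
volume and energy data for a protein at two pressures and want the full
battery of published-style observables without the MD engine in the loop.

## What it computes

**Volume, surface and compressibility.** Excluded volume V_ex (union of
probe-inflated van der Waals spheres, grid occupancy) and
solvent-accessible surface area (deterministic spiral-lattice rolling
probe), with the hybridization-class radius table (2.0 / 1.85 / 1.8 /
1.7 / 1.4 Å, probe 1.4 Å). Isothermal compressibility from equilibrium
volume fluctuations:

    kappa_T = ( <V²> − <V>² ) / ( k_B · T · <V> )

**Thermodynamic-cycle free energy.** The pressure-induced stability shift
is decomposed as

    ΔG = ΔE_conf + ΔΔμ − TΔS

with ΔE_conf from per-frame solute energies, Δμ = Δμ_polar + γ·A
(finite-difference two-dielectric Poisson solve for the polar part,
γ(277 K) = 0.1091 kcal/mol/Å² for the nonpolar part, water permittivity
from a Kirkwood g-factor model), and S = S_trans + S_rot + S_int
(Sackur–Tetrode, classical rigid rotor, and quasi-harmonic
quantum-oscillator entropy from the mass-weighted coordinate covariance,
averaged over five trajectory blocks).

**Interactions.** Salt bridges as charged N–O pairs at ≤ 3.2 Å (multiple
bridges per residue pair counted), classified by secondary-structure
element (inter-helix/strand, helix/strand–loop, loop–loop,
intra-helix/strand), by subdomain (inter/intra with the four-lobe actin
map), and by ATP contact (K18–O_α, K18–O_β, K137–O_γ); hydrogen bonds at
≤ 3.0 Å / ≥ 160°; per-pair formation rates across frames.

**Active site.** Mg²⁺ coordination patterns (W-type: 4 waters + 2
γ-oxygens; Q-type: 3 waters + 2 γ-oxygens + side-chain O), per-frame
nucleophilic-water assignment (minimum P^γ–O^w distance among waters with
attack angle θ > 109.3°), and binned (θ, d_Nu) free-energy surfaces in
k_BT. Rotamer enumeration (3 states per χ; 81 for lysine) and
farthest-from-cation rotamer selection support the Q137K modelling step.

**Synthetic data.** Every estimator ships with a generator producing
inputs with analytic ground truth: Gaussian harmonic ensembles with
prescribed mode eigenvalues, volume series built by inverting the
fluctuation formula, charged-group and ATP/Mg fixtures at exact
geometries, and Born ions for the Poisson solver.

## Worked example

```r
library(presstraj)

# recover a target compressibility from synthetic volume fluctuations
g <- gen_volume_series(mean = 7.4e4, target_kappa = 0.14,
                       temperature = 277, n = 1e5, seed = 1)
isothermal_compressibility(g$series)
#> kappa_T = 0.141 GPa^-1 (target 0.14)

# detect and classify salt bridges on a constructed fixture
residues <- data.frame(resname = c("LYS", "ASP", "LYS"),
                       resid = c(10, 40, 137), ss = c("H", "H", "C"),
                       element_id = c(1, 1, NA), subdomain = 1)
fx <- gen_interaction_fixture(residues,
        pairs = data.frame(pos_resid = 10, neg_resid = 40, distance = 3.0),
        atp = list(pos_resid = 137, tag = "gamma", distance = 3.0))
anno <- annotate_topology(fx$trajectory$topology, fx$config)
classify_salt_bridges(
  detect_salt_bridges(frame_structure(fx$trajectory, 1), anno, cutoff = 3.2),
  fx$ss_profile, fx$subdomains)[, c("pos_resid", "neg_resid", "distance",
                                    "ss_category", "atp_tag")]
#>   pos_resid neg_resid distance        ss_category      atp_tag
#> 1        10        40        3 intra_helix_strand         none
#> 2       137       400        3               <NA> K137-O_gamma

# assemble the cycle for one system's 0.1 -> 60 MPa shift
fe <- free_energy_shift(c(-147, 67), c(510, 22), c(29, 20))
fe$delta_G
#> delta_G = 334 +/- 73 kcal/mol
```

The first block shows the fluctuation estimator landing within 1% of the
0.14 GPa⁻¹ it was asked to encode; the second shows one intra-helix
Lys–Asp bridge at exactly 3.0 Å plus the K137–γ-oxygen ATP contact; the
third reproduces a deep-sea actin free-energy row (−147 + 510 − 29 =
334 kcal/mol, destabilised at pressure but less so than non-deep-sea
variants; the quadrature SD is reported alongside).

`run_pipeline(run_config(seed = 1), "out/")` runs every stage over a
self-contained synthetic two-pressure study and writes
publication-table-shaped TSVs (`table2.tsv` … `table5.tsv`, `rmsf.tsv`,
`propeller.tsv`, `fes.tsv`); the bundle is byte-identical under a fixed
config and seed.

## Layout

- `R/` — modules: `model_io`, `geometry`, `surface_volume`,
  `interactions`, `thermo`, `active_site`, `synthetic_data`,
  `cli_report`
- `src/` — Rcpp red-black SOR kernel for the Poisson solver
- `inst/extdata/` — plain-text reference tables used by the regression
  checks
- `vignettes/pressure-analysis.Rmd` — the methods account: models,
  assumptions, parameter choices, numerical details, limitations
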