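# mdscape

Post-processing toolkit for molecular dynamics (MD) trajectories of proteins
and protein–ligand complexes, written for the analysis chain used in
computational studies of polyester-degrading cutinases: structural-stability
observables, conformational free-energy landscapes, binding-site geometry,
and end-point binding free energies by the solvated interaction energy (SIE)
method.

MD studies of enzymes such as cutinases (serine hydrolases with a
Ser–His–Asp catalytic triad that hydrolyse synthetic polyesters like PES,
PCL and PET) typically answer three questions with the same pipeline: *is
the fold stable* (RMSD/RMSF, disulfide distances), *which conformational
states does the enzyme visit and do they open a usable active-site cavity*
(Cartesian PCA → free-energy landscape → minima → pocket volumes), and *how
strongly and through which residues does the substrate bind* (clustering and
stable-window selection, hydrogen-bond and interaction-fingerprint
occupancies, SIE scoring). `mdscape` implements that chain as tested,
reusable R functions, plus synthetic-trajectory generators with known ground
truth so every stage can be validated without microsecond trajectories.

## The models at the core

**Free-energy landscape (FEL).** Frames are superposed (Kabsch) onto their
mean structure, the 3N Cartesian covariance is eigendecomposed, and the
first two principal components span a plane on which the sampled density is
binned:

    ΔG(b) = −kT · ln( P(b) / P_max ),   kT = k_B·T,  k_B = 0.0019872041 kcal·mol⁻¹·K⁻¹

At the default simulation temperature of 313.15 K, kT ≈ 0.6223 kcal/mol.
Minima are detected on a smoothed surface, merged per connected occupied
region, and reported with both the bin-level depth `dG` and the
occupancy-based basin free energy `dG_basin = −kT·ln(P_basin/P_deepest)`.

**Solvated interaction energy (SIE).** An end-point score over a stable
trajectory window:

    ΔG_bind = α · (E_vdW + E_Coul + ΔG_RF + γ·ΔSASA) + C

with intermolecular Lennard-Jones and Coulomb terms, a generalized-Born
reaction-field change on binding (f_GB = √(r² + aᵢaⱼ·exp(−r²/4aᵢaⱼ))), and a
cavity term from the buried solvent-accessible surface area (Shrake–Rupley).
Defaults: α = 0.1048, C = −2.89 kcal/mol, γ = 0.0129 kcal·mol⁻¹·Å⁻²,
ε_in = 2.25, ε_out = 78.5. `sie_calibrate()` refits (α, C) to any
component table with reference affinities and flags rows inconsistent with
the linear model.

## Worked example

Two-state conformational ensemble with 80/20 occupancies, landscape and
basin depths:

```r
library(mdscape)

g     <- gen_multibasin_trajectory(occupancies = c(0.8, 0.2),
                                   n_frames = 2000, seed = 11)
bb    <- select_atoms(g$topology, preset = "backbone")
model <- pca_fit(g$trajectory, bb)
proj  <- pca_project(model, g$trajectory, 2)
surf  <- fel_build(proj)                     # 60x60 bins, T = 313.15 K
find_minima(surf)
#>   rank   pc1     pc2   dG occupancy dG_basin
#> 1    1 -12.2  0.0397 0.00     0.811     0.00
#> 2    2  53.8 -0.5266 1.06     0.179     0.94
```

The two planted states are recovered with their occupancies; the basin
free-energy gap 0.94 kcal/mol estimates the ideal kT·ln(0.8/0.2) =
0.863 kcal/mol from one finite sample.

Scoring a published SIE component table and screening it for internal
consistency:

```r
tab <- read_energy_table(system.file("extdata", "sie_table2_components.csv",
                                     package = "mdscape"))
cal <- sie_calibrate(tab)
cal
#> <sie_calibration> alpha = 0.1049, C = -2.88 kcal/mol; max |residual| 4.069; 1 outlier(s)
data.frame(tab[, c("system", "polymer")],
           dG_model   = round(sie_score(tab, cal$coefficients), 2),
           dG_printed = tab$dG)
#>   system polymer dG_model dG_printed
#> 1 MrCut1     PES    -9.17      -9.17
#> 2 MrCut1     PCL    -9.00      -9.00
#> 3 MrCut1     PET    -8.40      -8.40
#> 4 MrCut3     PES   -12.06      -7.99
#> 5 MrCut3     PCL    -7.30      -7.30
#> 6 MrCut3     PET    -7.95      -7.95
```

Five of the six columns recombine to their printed affinity at two decimal
places; the MrCut3/PES column is flagged as inconsistent with the linear
model the other rows satisfy (residual ≈ 4 kcal/mol) — it is reported, not
corrected.

`run_pipeline(config)` chains every stage (geometry → PCA/FEL → minima →
pockets → clustering/window → fingerprints/H-bonds → SIE) into one
reproducible report directory with a JSON manifest; `inst/cli/mdscape` is a
thin command-line dispatcher over the same functions.

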