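---
title: "Methods: conformational landscapes and SIE scoring in mdscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational landscapes and SIE scoring in mdscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscape)
```

`mdscape` post-processes molecular-dynamics trajectories of proteins and
protein–ligand complexes. This vignette documents the models the package
implements, the assumptions behind them, the tunable parameters and their
defaults, the numerical decisions taken where the methodology is genuinely
open, and what the synthetic generators do and do not emulate.

## Units and conventions

Coordinates and distances are in ångström, times in nanoseconds, energies
in kcal/mol, temperatures in kelvin. The Boltzmann constant is
k~B~ = 0.0019872041 kcal·mol^−1^·K^−1^ and the Coulomb conversion constant
k~e~ = 332.0636 kcal·Å·mol^−1^·e^−2^. Atom order is the identity mapping
across trajectory frames; readers never re-match atoms by name, so a
mismatch surfaces as an error rather than a silent misalignment.

## Superposition and stability observables

All deviation measures rest on mass-unweighted Kabsch superposition over a
selection (default: the backbone preset N, CA, C, O). The rotation comes
from the SVD of the 3×3 covariance of the centred coordinate sets; the
reflection case is handled by flipping the smallest singular direction, so
the returned rotation always has determinant +1. Selections with fewer than
three atoms or collinear geometry are rejected.

* `rmsd_series()` superposes every frame independently onto the reference
  frame, so the series is exactly zero for rigid motion and at the
  reference frame.
* `rmsf_profile()` uses the iterated mean structure as its reference
  (align to frame 1, average, re-align to the mean). The mean is the
  standard fluctuation baseline; a single pass is already close, the second
  pass makes the reference self-consistent. A separate `fit_selection`
  allows aligning on a stable scaffold while profiling mobile parts —
  without it, a strongly fluctuating region drags the fit and deflates its
  own apparent fluctuation.
* Pair-distance series (e.g. disulfide S–S monitoring) are plain Euclidean
  distances per frame; stability thresholds (such as a 3 Å RMSD guideline)
  are reporting conventions for the user, not hard-coded logic.

## Cartesian PCA and the free-energy landscape

`pca_fit()` eigendecomposes the 3N×3N covariance of superposed selected
coordinates. Variance fractions are eigenvalues over the trace; component
signs are fixed by making each component's largest-magnitude element
positive, so orientations are reproducible across platforms. Replicate
trajectories are concatenated before fitting (consistent with clustering
all replicates jointly); per-replicate analysis remains possible by calling
the functions per replicate.

`fel_build()` bins the first two projections on a regular grid and converts
probabilities to free energies, ΔG(b) = −kT·ln(P(b)/P~max~), so the most
occupied bin is exactly zero. Defaults and their rationale:

* **Bins: 60×60** over the data range padded by 2% per side. This resolves
  up to four basins on fixtures of 1000–5000 frames; for much smaller frame
  counts the caller should reduce the bin count, since a sparse histogram
  on a fine grid fragments into single-frame bins.
* **Temperature: 313.15 K** (a typical production-simulation temperature),
  giving kT ≈ 0.6223 kcal/mol.
* **Empty-bin cap: max occupied ΔG + 1 kT** — finite, plot-friendly, and
  clearly above every minimum.

### Minima as basins

Whether published landscapes use raw or smoothed histograms, and at what
bin counts, is generally unstated; the following is this package's own,
fully documented procedure. Candidate bins are local minima (8-neighbour)
of the box-smoothed surface (one 3×3 pass by default). Finite sampling
always fragments a broad basin into several shallow local minima, so
candidates lying in the same 8-connected region of *occupied* bins are
merged into one basin; genuinely separated wells stay apart because the
bins between them are empty. Each basin reports

* `dG` — the raw surface value at its deepest bin (the conventional
  landscape depth). Ties are broken by row-major bin order, which also
  makes a perfectly flat occupied surface yield a single minimum at the
  first bin.
* `dG_basin` — the basin free energy −kT·ln(P~basin~/P~deepest~) from the
  total occupancy of the basin's bins.

The distinction matters statistically: a single bin count carries Poisson
noise and, when the deepest bin is selected, a maximum-over-bins bias,
whereas basin occupancies are binomial totals with negligible bias. Depth
*differences* between states should therefore be read from `dG_basin`;
`dG` remains the value plotted on the surface. Basins whose centre lies
more than `depth_window` (default 2 kcal/mol) above the global minimum are
dropped, and at most `max_minima` (default 4) are reported, deepest first.

Representative structures are the frames nearest (Euclidean, in the PC
plane) to a minimum's bin centre, ties to the lowest frame index.

## Clustering and the stable window

`cluster_frames()` builds the full pairwise superposed-RMSD matrix and
applies average-linkage agglomerative clustering, cut at a height of
2 Å by default (the scale at which backbone conformers are conventionally
considered distinct). Each cluster's representative is its medoid (minimal
mean RMSD to members). Merge heights are rounded to 10^−8^ Å before
cutting: identical frames produce zero distances whose averaged heights can
drift below machine epsilon out of order. The O(n²) matrix makes this
appropriate up to a few hundred frames; the pipeline subsamples longer
trajectories (default cap 400 frames) before clustering.

`select_stable_window()` scans every contiguous window of the requested
length (default 300 ns) starting at a frame time and returns the one
maximising the fraction of frames in the largest cluster, earliest window
on ties, with a flag for whether the fraction reaches `min_fraction`
(default 0.5 — the window should represent at least half the sampled
conformations).

## Binding-site geometry

**Pocket volume** uses a seeded grid flood fill: a cubic grid (default
0.5 Å pitch) spans a search sphere around the seed point; a grid point is
open if it clears every atom's radius plus the probe radius (default
1.4 Å, a water-sized probe); the pocket is the 6-connected open region
containing the seed, excluding the search-sphere boundary layer. A fill
that reaches the boundary sets a `leak` flag; a blocked seed returns zero
volume with a diagnostic. The method is deterministic and analytically
testable (a hollow shell of known interior radius has a closed-form
volume). Per-element fallback radii are C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å when the topology carries none.

**Hydrogen bonds** use the standard geometric definition: donor–acceptor
heavy-atom distance ≤ 3.5 Å and, when a hydrogen position exists, a
D–H···A angle ≥ 130°. On heavy-atom-only topologies the convention is
element-based and unambiguous: nitrogens donate, oxygens accept. This
deliberately ignores hydroxyl donors (indistinguishable without
hydrogens) but guarantees the two directional detector calls partition
donor/acceptor classes without double counting. Occupancies are averaged
per replicate first; the reported spread is the standard deviation across
replicate means, which is the reproducibility-between-replicates quantity,
not the frame-to-frame fluctuation.

**Fingerprints** flag four classes per residue and frame — hydrophobic
(carbon/sulfur pair ≤ 4.5 Å), hbond_donor / hbond_acceptor (from the
residue's perspective), and van der Waals contact (heavy-atom pair
≤ 4.0 Å) — and report the fraction of frames flagged. The distance
thresholds are conventional mid-range values for contact analysis;
published fingerprint tools rarely state theirs, so they are exposed in
`interaction_criteria()`. All-zero residues are omitted from reports.

## SIE scoring

The solvated interaction energy is the affine end-point model
ΔG = α·(E~vdW~ + E~Coul~ + E~RF~ + E~cav~) + C with:

* **E~vdW~, E~Coul~** — intermolecular 12-6 Lennard-Jones
  (Lorentz–Berthelot combination) and Coulomb sums over all protein–ligand
  pairs, no cutoff (end-point systems are desk-scale).
* **E~RF~** — generalized-Born reaction field with the standard pairwise
  f~GB~ = √(r² + aᵢaⱼ·exp(−r²/4aᵢaⱼ)), self terms included, computed as
  G(complex) − G(protein) − G(ligand) at fixed coordinates (rigid,
  single-trajectory decomposition — the standard end-point convention).
  Born radii are *inputs* (topology or configuration); the package
  deliberately does not implement a descreening model, which bounds scope
  and keeps every term closed-form testable.
* **E~cav~** — γ·ΔSASA from a deterministic golden-spiral Shrake–Rupley
  surface (default 960 points per atom for standalone calls; 240 in the
  per-frame trajectory loop, where the area enters only through a small
  γ-scaled term).

Defaults α = 0.1048, C = −2.89 kcal/mol, γ = 0.0129 kcal·mol^−1^·Å^−2^,
ε~in~ = 2.25, ε~out~ = 78.5. The constant C is taken from the published
table shipped in `inst/extdata/`; α is not printed there, so the package
default is the value recovered by least squares over the internally
consistent rows of that table — making the table self-verifying without
external references.

`sie_calibrate()` fits (α, C) to any component table with reference
affinities. Because a single grossly inconsistent row can have high
leverage (its component sum is extreme) and drag an ordinary least-squares
line far enough to hide itself, rows are first screened against a
Theil–Sen line (median of pairwise slopes — exact for two rows, robust to
a minority of outliers); rows whose screen residual exceeds 1 kcal/mol are
flagged and the final coefficients are ordinary least squares on the
remainder. Flagged rows are reported, never corrected or dropped from the
output. In the shipped table this isolates exactly one column whose
printed components cannot reproduce its printed affinity under the model
the other five columns satisfy (residual ≈ 4 kcal/mol); the package takes
no position on which of its entries is mistyped.

## What the synthetic generators emulate

The generators exist so that each analysis stage can be scored against a
planted truth at desk scale; each is a pure function of its arguments and
seed (the caller's RNG state is restored).

* `gen_multibasin_trajectory()` — a 30-residue × 4-backbone-atom scaffold
  whose basin reference conformations are displaced along mutually
  orthogonal 3N directions, orthogonalised against the six rigid-body
  modes so the planted separation (default 6 Å backbone RMSD) survives
  superposition. Frames sample basins independently per occupancy and add
  isotropic Gaussian jitter (default 0.5 Å). There are **no kinetics**:
  the landscape depends only on occupancies and no kinetic claim is
  tested. An `assign = "exact"` mode realises occupancies deterministically
  for tests that need exact fractions.
* `gen_toy_complex()` — a rigid, widely spaced scaffold with active-site
  residue labels (Thr43/45, Ser120, Gln121, His185) and one dedicated
  ligand atom per planted contact, placed at its contact distance in
  exactly the requested fraction of frames (interleaved on/off pattern).
  Element choices make each contact trigger exactly the intended detector
  class; geometric unsatisfiability (a contact colliding with another
  residue) is an error.
* `gen_pocket_structure()` — concentric golden-spiral shells enclosing a
  cavity of analytic volume (4/3)πr³; atom spacing is validated against
  the probe so the shell cannot leak.
* `gen_energy_table()` — component tables from a known (α, C) linear model
  with optional Gaussian noise, for calibration-recovery tests.

What they do **not** emulate: force-field physics, solvent, kinetics,
side-chain packing, flexible ligands, or the heterogeneous noise of real
trajectories. Passing tests therefore demonstrate the correctness of the
estimators on data satisfying their assumptions, not the accuracy of any
published simulation result; trajectory-dependent published statistics
(mean RMSDs, variance fractions, pocket volumes in ų, per-residue
hydrogen-bond counts) are not reproducible without the original
trajectories and are not asserted anywhere.

## Problem sizes and numerical tolerances

The test suite works at deliberately small scales chosen to keep the full
run in minutes while leaving clear statistical margins: 2000-frame
landscape recoveries (20 seeds for the occupancy-ratio check), ≤ 150-frame
pipeline runs, ≤ 60-frame clustering fixtures, 10-atom superposition pairs
against a 48-start Nelder–Mead brute-force oracle (10^−4^ Å agreement),
0.5 Å pocket grids (5% of the analytic cavity volume), 960-point SASA
spheres (0.5% of the analytic area), and closed-form generalized-Born
checks at 10^−6^ kcal/mol. Degenerate inputs — single frames, collinear
selections, zero variance, empty selections, all-empty surfaces, blocked
pocket seeds — either raise descriptive errors or return explicitly
flagged results, as documented on each function.

## Known limitations

* Cartesian PCA on a degenerate (noise-only) axis spreads over many tiny
  bins; with few frames and fine grids, fringe bins can appear as spurious
  shallow basins. They are filtered by the depth window in practice, but
  bin counts should be matched to frame counts.
* The pairwise RMSD matrix makes clustering quadratic in frames.
* No periodic-boundary unwrapping: inputs are assumed whole molecules.
* Binary MD formats (DCD/XTC/NetCDF) and mmCIF are out of scope; inputs
  are multi-model PDB or XYZ.
* The hydrogen-bond convention on heavy-atom topologies cannot see
  hydroxyl donors; supply hydrogens for full donor coverage.
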