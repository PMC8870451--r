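---
title: "ionpocket: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ionpocket: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpocket)
```

ionpocket packages the analysis stack used to characterize the conserved
allosteric sodium site of class A GPCRs: ion coordination statistics and
side-chain rotamer/H-bond analysis from MD trajectories, accelerated-MD
boost parameterization, Gaussian-dielectric Poisson–Boltzmann energetics,
and a sequence clustering/phylogeny pipeline. This vignette documents the
models, every tunable parameter that matters, what the synthetic
generators do and do not emulate, and the design decisions taken where
the protocol left room.

## 1. Coordination-shell model

The ion's environment is classified per frame from plain Euclidean
distances (inputs are assumed imaged/whole; there is no periodic-boundary
handling, and broken geometries are the caller's responsibility):

| parameter | default | unit | meaning |
|---|---|---|---|
| `first_shell_protein` | 2.8 | Å | protein ligand in the first shell |
| `first_shell_water` | 3.0 | Å | water oxygen in the first shell |
| `second_shell` | 6.0 | Å | outer limit of the second shell |
| `bridge_water` | 3.0 | Å | water–ligand distance for bridging |

A protein atom between 2.8 and 6 Å belongs to the second shell **only if**
some first-shell water lies within `bridge_water` of it. The protocol's
wording leaves open whether the bridging water must merely exist in the
ion's first shell or must also be near the candidate atom; we require
both (water ≤ 3 Å from the ion *and* ≤ 3 Å from the protein atom), which
is the reading under which the water actually "bridges" the two. The
cutoff is exposed for sensitivity analysis.

Occupancies are percentages of frames per ligand, for the first shell and
for the "total" (first ∪ second) shell; counts and occupancies are first
averaged within a replica, then summarized across replicas as mean ± SEM
with the sample standard deviation (n − 1). A single replica reports SEM
as `NA` — dispersion is undefined, not zero.

## 2. Ion RMSD

Each frame is rigid-body superposed (Kabsch) on a selection — by default
the protein ligand atoms — onto a reference (by default frame 1), and the
ion's displacement from its reference position is recorded. This measures
how far the ion wanders from its initial, modeled position within the
aligned binding site. Fewer than three alignment atoms make the
superposition underdetermined and are rejected.

## 3. Rotamers and hydrogen bonds

Chi dihedrals follow the IUPAC sign convention, wrapped to (−180°, 180°].
The classification bins are the standard chi1 wells:

* trans: |chi1| > 120°
* g+: chi1 ∈ (0°, 120°]
* g−: chi1 ∈ [−120°, 0°]

The source protocol does not state bin edges; these midpoints between the
180°/+60°/−60° wells are consistent with a chi1 of 87° being labelled g+.
The boundary at exactly −120° is assigned to g− so the bins partition the
circle. Colinear frames yield an undefined angle and are flagged, never
silently dropped; histogram fractions are taken over defined frames.

H-bonds require donor–acceptor ≤ 3.5 Å and a D–H···A deviation from
linearity ≤ 30° (the convention of the common trajectory-analysis tools).
The replica filter reflects the inward/outward N3.35 protocol: "outward"
is identified with the g− chi1 label (configurable), a replica whose
filtered side chain goes outward within the first 50 ns
(`rotamer_filter_window`) is excluded entirely, and in retained replicas
only inward-labelled frames enter the denominator.

## 4. Accelerated-MD boost

From a classical-MD energy series, the thresholds are the arithmetic
means over the 20–120 ns window (the "soft" protocol — thresholds equal
the averages exactly, no offset), and

* α_dihed = λ·E_dihed_avg / 5
* α_pot = λ·N (kcal/mol by the convention of the method)

with λ = 0.3 and N the system's atom count. The boost applied below a
threshold E is ΔV = (E−V)²/(α+E−V); this functional form comes from the
dual-boost literature the protocol cites, not from the protocol itself,
and is documented here as an imported formula. It satisfies ΔV ≥ 0,
continuity at V = E, monotonicity of V + ΔV, and V + ΔV < E below
threshold. Reweighting of accelerated trajectories is deliberately out of
scope: the boost is used to observe rare ingress events, not to compute
reweighted statistics.

## 5. Poisson–Boltzmann electrostatics

**Dielectric model.** Each atom contributes a Gaussian density
g_i(r) = exp(−|r−r_i|²/(σ²R_i²)); the solute density is
ρ = 1 − Π(1 − g_i) and ε(r) = ρ·ε_in + (1−ρ)·ε_out — a smooth
interpolation with no molecular surface. Defaults are the
surface-ionizable-group parameterization ε_in = 8, σ = 0.7 (the
hydrophobic-interior alternative ε_in = 4, σ = 0.9 is a parameter choice
away), ε_out = 80, 0.15 M 1:1 salt, 1.8 grid points per Å, and a solute
extent of 70 % of the box edge (Lp = 0.7·L). A `"sharp"` two-dielectric
model (union of atomic spheres) is also provided because the analytic
Born oracle is only meaningful there: the Gaussian model has no exact
Born radius, so closed-form validation uses the sharp model while
production runs use the Gaussian one.

**Discretization.** Node-centered cubic grid, 7-point stencil. The face
dielectrics are harmonic averages of ε sampled at 8 points along each
edge — the flux-continuity rule, exact for a one-dimensional interface —
which removes most of the sharp-interface alignment artifacts (Born error
at 1.8 pts/Å drops from ≈ 6 % with node-averaged faces to ≈ 0.3 %).
Charges are spread trilinearly (total charge conserved to < 1e−10 e).
The screening term ε_out·κ² is zeroed where ρ > 0.1 (`rho_cut`,
configurable; no Stern layer). Boundary conditions are the sum of
Debye–Hückel-screened monopole potentials of all charges. The linear
system is symmetric positive definite and solved by Jacobi-preconditioned
conjugate gradient (compiled code) to a 1e−6 relative residual. The
*linear* PB equation is used throughout: the binding energies of interest
are a few kT and the cited tooling defaults to linear PB for this use.

**Box placement.** The box is axis-aligned and centered on the solute
(or on an explicit center). The upstream protocol orients the cube along
the solute's principal axes; we do not rotate the solute — the synthetic
systems are nearly isotropic and a fixed lab frame keeps the
"identical grid" contract of the binding-energy protocol trivial to
enforce. Energies are reported in kT at 298.15 K (the protocol reports kT
without stating T; 25 °C is assumed, making the Coulomb constant
≈ 560.5 kT·Å/e²).

**Binding free energy.** ΔG_bind = E_grid(complex) − E_grid(receptor) −
E_grid(ion), each E_grid = ½Σ q_node φ_node, computed in three runs on the
node-for-node identical grid that the complex defines; the receptor/ion
systems must partition the complex atom-for-atom at identical coordinates
(enforced, not re-derived). Aggregation extracts 35 snapshots every 8 ns
per trajectory by default, reports boxplot statistics and per-trajectory
means, computes the least-squares R² of mean ΔG against mean first-shell
protein coordination (omitted, never fabricated, with fewer than two
trajectories), and warns when the solute reaches 70 % of the box edge.

**pKa.** Single-site approximation:
pKa = pKa_model + ΔΔG_elec/(2.303·kT) for an acid, where ΔΔG_elec is the
charging-work difference between the protein environment and the model
compound; each state's work is its grid energy minus the energy of the
same charges on the same grid in uniform solvent, so lattice
self-energies cancel within each state. Signs are such that stabilization
of the charged form lowers an acid's pKa (and raises a base's). The
model-compound table (Asp 4.0, Glu 4.4, His 6.3, …) is configuration.
Site–site titration coupling is out of scope. The default protocol
evaluates seven equally spaced frames and reports mean ± sd.

## 6. Sequence pipeline

Pairwise identity counts matches over columns where neither sequence is
gapped (the NRDB/BLAST-style convention; the upstream protocol does not
state one, so the convention is recorded in the output metadata).
Clustering is a deterministic greedy pass at 90 % identity: sequences are
visited by decreasing ungapped length (ties by id) and join the first
cluster whose *representative* they match at threshold; the founder is
the representative, making the manual "longest termini privileged" choice
reproducible. NJ is implemented from scratch (Saitou–Nei, ties broken by
the lowest index pair) and is exact on additive matrices; `ape` is used
only for tree containers, Newick I/O and as an independent oracle in the
tests. The NJ distance is d = 1 − identity by default; a 20-state
Jukes–Cantor correction is available behind a flag (the protocol states
no distance model). Bootstrap resamples columns with replacement, 500
replicates by default; replicate r uses the r-th substream of the seed,
which makes supports reproducible and invariant to taxon input order.
Two-taxon inputs yield a degenerate single-edge tree with a warning.

Database mining (keyword filters, the 550 → 318 → 75-cluster funnel) is
database-release-dependent and out of scope; `filter_report()` provides
the equivalent configurable filter stage over user-supplied FASTA.

## 7. The synthetic world

The generators plant ground truth by construction and are themselves
tested code:

* **Trajectories** (`gen_site_trajectory`): ligand shell membership is a
  per-frame schedule; first-shell frames place the ligand at its nominal
  distance (which must clear the 2.8 Å cutoff by the noise margin —
  violations are rejected naming the frame and ligand), second-shell
  frames place it at 4.5 Å (or its nominal distance when compatible) with
  a bridging water at the midpoint of the ion–ligand axis — inside the
  water first shell and within 3 Å of the ligand by construction — and
  "none" frames use 7.5 Å. Ligands sit on well-separated fixed directions
  (octahedron + cube-diagonal set) so cross-talk cannot flip memberships.
  Rotamer schedules place a 4-atom side chain at the 180°/+60°/−60° well
  centers; H-bond schedules place donor–H–acceptor triples at 2.9 Å
  (linear) or 4.5 Å. Noise is isotropic Gaussian per coordinate,
  truncated at 1.5·`noise_sd` per atom so pairwise distances move by at
  most 3·`noise_sd`, which is exactly the margin the planted geometry
  reserves — ground truth remains exact at any permitted noise level
  (`noise_sd` ≤ 0.1 Å). Coordinates are rounded to the PDB's 3-decimal
  precision so serialization round trips are lossless.
* **Energy series**: Gaussian white noise around a stated mean — enough
  for windowed-mean parameter checks, with no autocorrelation.
* **Charge systems**: point/Born/dipole/two-body systems carry their
  closed-form reference energies (Coulomb constant evaluated at the
  requested temperature).
* **Sequence families**: a root sequence evolves along a guide tree under
  a 20-state Jukes–Cantor model (keep probability
  1/20 + (19/20)e^(−20b/19) per site per branch), no indels, so the
  leaves are aligned and the guide tree is the true tree. Marked-column
  clade overrides plant diagnostic splits verbatim.

What a green test does **not** establish: the generators emulate none of
the physics — no force field, no water dynamics, no membrane, no realistic
protein geometry, no sequence-database biases. Green means the *analysis
machinery* is correct (oracle-equivalent, planted-truth-recovering,
within closed-form bounds), not that the scientific conclusions of any
particular study are reproduced. The headline numbers of the motivating
study (first-shell coordination 2.8 ± 0.2, ion RMSD 3.2 ± 0.9 Å, median
ΔG −3.0 vs −2.2 kT, R² = 0.90, D2.50 pKa 4.1) require sub-microsecond MD
of modeled receptors and a dated sequence database and are therefore not
desk-scale reproducible; the acceptance suite is property-based instead,
with simulation sizes scaled within the stated caps to fit the runtime
budget (100 trajectories of ≤ 120 frames; PB grids ≤ 97³).

## 8. Numerical choices and degenerate inputs

* PB solver tolerance 1e−6 (relative residual), CG with Jacobi
  preconditioning; non-convergence is an error reporting the residual,
  never a silent result.
* Zero-charge systems short-circuit to an identically zero potential via
  a zero right-hand side and zero boundary values.
* NJ ties are broken deterministically (lowest row-major pair); negative
  branch lengths are left as computed, as in the classical algorithm.
* Identity of an all-gap pair is `NA` and flagged, never 0.
* `sem()` of one observation is `NA`.
* Rotamer bins must partition: overlapping or non-covering custom bins
  are rejected at classification time.
* All generator APIs require an explicit seed; the pipeline derives
  per-stage seeds from the config seed, and reruns are byte-identical on
  every numeric report (the run log carries the only timestamp).

## 9. Known limitations

* No PBC unwrapping or mass-weighted whole-protein RMSF; the trajectory
  side handles the binding-site analyses only.
* Linear PB only; no Stern layer; no principal-axes box orientation; no
  membrane slab dielectric.
* pKa is single-site — titratable sites do not interact.
* The PQR reader accepts the common whitespace dialect only.
* Multiple sequence alignment construction is out of scope; inputs must
  be pre-aligned.
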