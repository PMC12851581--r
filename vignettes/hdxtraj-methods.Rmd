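---
title: "Methods: differential HDX-MS statistics and trajectory dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential HDX-MS statistics and trajectory dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxtraj)
```

# Scope

`hdxtraj` analyzes the structural dynamics of ligand-coupled membrane
transporters from two complementary data streams: peptide-level differential
hydrogen–deuterium exchange mass spectrometry (HDX-MS), and molecular-dynamics
trajectories. The package covers the statistics and the mapping — not raw
mass-spectral processing (peptide identification, isotope deconvolution) and
not the simulations themselves (force fields, integrators). A synthetic-data
module generates both data types with known ground truth so that every
pipeline stage has a testable end-to-end path.

# The differential HDX-MS model

## Data unit and bookkeeping

The atomic observation is one deuterium uptake value (in deuterons, i.e.
Da-equivalent mass shift) for one peptic peptide, in one protein state, at
one labeling timepoint, in one replicate. Residue numbering is 1-based and
peptide intervals are inclusive on both ends. The default labeling design is
three timepoints (30 s, 300 s, 3000 s) in triplicate; the replicate count is
always taken from the data, never assumed, since exported tables frequently
mix duplicate and triplicate cells.

A peptide of length $L$ has at most $L - 1 - n_P$ exchangeable backbone
amides, where $n_P$ counts prolines beyond the first residue: the N-terminal
amide back-exchanges too rapidly to retain label, and proline has no backbone
amide hydrogen. No back-exchange correction is applied; the pipeline operates
on relative uptake throughout (a multiplicative correction can be folded into
the uptake column upstream if desired).

Coverage percentages are reported with a configurable denominator (the
analyzed residue range by default, or the full protein length), because
vendor software is not consistent about which it uses and published coverage
figures are often not exactly reproducible from the non-covered-residue
counts alone.

## The hybrid significance test

For a state pair (holo vs apo), the differential uptake of each peptide
$\times$ timepoint cell is

$$\Delta D = \bar D_{\mathrm{holo}} - \bar D_{\mathrm{apo}},$$

and a cell is significant only if **both** arms of the hybrid criteria hold:

1. **Magnitude arm.** $|\Delta D|$ exceeds a dataset-wide *global threshold*
   derived from the pooled replicate standard deviation. Pooling runs over
   every peptide–timepoint cell of both states of the pair:
   $s_p^2 = \sum_c (n_c - 1)\, s_c^2 \,/\, \sum_c (n_c - 1)$, with
   $\mathrm{dof} = \sum_c (n_c - 1)$. The threshold is the two-sided
   Student-$t$ confidence bound on a difference of means,
   $$\mathrm{thr} = t_{1-\alpha/2,\,\mathrm{dof}} \; s_p
     \sqrt{1/n_{\mathrm{holo}} + 1/n_{\mathrm{apo}}},$$
   using the modal per-cell replicate counts. The "hybrid criteria" label in
   the HDX literature names the combination but not one canonical formula;
   this confidence-bound form is the common choice and is emitted with all
   of its ingredients (pooled SD, dof, $n$'s) so any printed threshold can be
   compared against it rather than assumed.
2. **Test arm.** Welch's unequal-variance two-sample $t$-test on the raw
   replicate uptake values of the cell gives $p < \alpha$ (default
   $\alpha = 0.05$), with Welch–Satterthwaite degrees of freedom. Degenerate
   cells follow explicit conventions instead of NaNs: both variances zero
   with equal means $\Rightarrow p = 1$; zero variances with different means
   $\Rightarrow$ the smallest representable $p$, flagged degenerate. Cells
   with fewer than two replicates in either state are emitted with the test
   marked unavailable and are never significant.

Significant cells are direction-labeled: *protected* ($\Delta D < 0$, less
uptake when ligand-bound, i.e. rigidified backbone) or *deprotected*
($\Delta D > 0$). No multiple-testing correction is applied beyond the global
threshold — that matches standard practice for this test; a
Benjamini–Hochberg layer can be added downstream on the emitted $p$ values if
wanted. An optional log-transform of relative uptake before testing is
available but off by default: log scaling is conventional for uptake
time-course comparisons, not for $\Delta D$ testing.

## Per-residue consensus mapping

For display on structures, peptide-level values collapse to residues:

* **Mean deuteration** per peptide averages first across timepoints, then
  across replicates; per residue, the mean over covering peptides is
  unweighted (peptide length does not weight the average).
* **Consensus effects**: a peptide is effect-bearing if *any* timepoint is
  significant. A residue is `protected`/`deprotected` when all effect-bearing
  covering peptides agree, `mixed` when they disagree (conflicts stay
  visible rather than being vote-resolved — real datasets contain peptides
  deprotected at short and protected at long labeling times),
  `not_significant` when covered without any effect, `uncovered` otherwise.
* The first residue of a peptide retains no label kinetically but is counted
  as spatially covered by default (coverage is spatial, not kinetic); this
  is configurable.

`export_structure_map()` writes either channel into the per-atom temperature
factor (B-factor) column of a PDB or mmCIF file; unannotated residues get a
sentinel (-1, outside both channels' ranges). Structure numbering must agree
with sequence numbering up to a constant offset; no automatic alignment is
attempted.

# Structure-derived annotations

* `pocket_residues()`: residues with any non-hydrogen atom within a cutoff
  (default 5 Å) of any non-hydrogen ligand atom; waters and the ligand
  itself excluded. Deposited crystal structures lack hydrogens, so the
  heavy-atom criterion keeps the definition consistent across inputs.
* `polar_contacts()`: N/O–N/O atom pairs across two selections within
  3.5 Å — candidate hydrogen bonds and salt bridges.
* `superpose()`: atoms paired by identical (chain, residue number, atom
  name) within a selection (Cα by default; altloc 'A' kept on read), then a
  Kabsch least-squares rigid fit. RMSD is reported in Å with the selection
  recorded in the output, since published RMSD figures frequently omit both.

# Trajectory analyses

## Water-site occupancy

The binding-site water criterion is geometric. Four heavy-atom pairs tie the
sugar to its coordinating residues — by default (galactosyl O5, Gln372 NE2),
(O5, Thr373 OG1), (O6, Gln372 NE2), (O6, Thr373 OG1). A water oxygen
occupies the site in a frame iff for at least one pair its distances to both
members are within the outer cutoff *and* at least one is below the inner
cutoff. Boundary conventions are explicit because prose definitions mix
"within" and "below": outer is inclusive ($\le 4.0$ Å), inner strict
($< 3.5$ Å). Occupancy is the fraction of frames with at least one occupying
water, pooled over all frames of all replicas (per-replica fractions are
reported for dispersion; per-water counts are auxiliary only — the frame
flag, not the water count, defines occupancy). Frames are assumed imaged and
whole; no periodic reconstruction is performed internally.

## Side-chain RMSF and replica comparison

Frames are rigid-fitted to the time-averaged structure over protein Cα atoms
(one fit-to-frame-1 pass followed by one fit-to-mean refinement; the
reference choice is configurable since published methods rarely state it).
Per residue,

$$\mathrm{RMSF} = \sqrt{\left\langle \lVert x - \bar x \rVert^2
  \right\rangle_{\mathrm{frames,\ side\text{-}chain\ heavy\ atoms}}},$$

with glycine flagged absent. State comparison runs per residue as an
unpaired two-sided Welch test on the replica RMSF values (five replicas per
state in the default design), so the replica — not the frame — is the unit
of independence.

# The synthetic-data generators

The generators exist to give the statistics a ground truth, not to imitate
physics.

**HDX**: per-residue first-order exchange
$u(t) = f\,(1 - e^{-k_{\mathrm{int}} t / P})$ with labeling fraction
$f = 0.9$ (a 10-fold dilution into deuterated buffer), a single configurable
intrinsic rate $k_{\mathrm{int}}$ (sequence-dependent rate tables are out of
scope — the downstream statistics see only uptake values), and per-state,
per-residue protection factors $P \ge 1$. Peptide uptake sums the
exchangeable residues; replicate noise is Gaussian on the peptide value,
truncated at 0 and at saturation. Digestion maps draw peptide lengths around
a mean (default 12) and advance starts by a Poisson step
(mean length / target overlap depth), emulating overlapping peptic maps. No
EX1/EX2 distinction, no sequence-dependent rates, no spectral effects —
passing tests therefore demonstrate the statistics and bookkeeping, not
robustness to correlated or heteroscedastic real-world noise.

**Reference recovery scenario** (used by the acceptance checks and the
`analysis/` drivers): a 200-residue protein, ~50–100 peptides at overlap
depth 3, baseline $P = 1000$ with $k_{\mathrm{int}} = 1\,/\mathrm{s}$, and a
bound state with $P \times 10$ over residues 40–60. At 300 s this gives a
per-residue $|\Delta D| \approx 0.21$ deuterons, about $4\times$ the
0.05-deuteron replicate noise — a strong but not caricatured effect whose
per-peptide magnitude then scales with how many block residues the peptide
covers. Timepoints 30/300/3000 s span the pre-exchange, mid-exchange and
near-saturation regimes of the baseline.

**Trajectories**: residues fluctuate isotropically about fixed anchors with
per-axis amplitude $\sigma$ (expected RMSF $\sqrt{3}\,\sigma$ for Gaussian
displacements); the four site atoms are static at a geometry where the site
midpoint satisfies the pair rule; per frame, with probability equal to the
target occupancy, one water is placed at the site midpoint, all others in a
far shell (>15 Å). The per-frame Bernoulli draws are stored on the returned
object, so measured occupancy can be compared with the generator's realized
fraction *exactly*, separating algorithmic error from sampling noise. All
generators are bit-reproducible under a fixed seed.

# Numerical and design choices

* **False-positive accounting.** Sensitivity is reported at the peptide
  level (a peptide counts as detected if any timepoint passes, matching the
  mapping rule), but false positives are reported at the peptide–timepoint
  cell level — the unit the hybrid test operates on. The any-timepoint union
  over three timepoints inflates the family-wise null rate to roughly three
  times the per-cell rate, so a peptide-level union cannot sit under the
  per-cell $\alpha$; the cell-level rate is the test's actual operating
  characteristic and is what the null-calibration check bounds.
* **Threshold degrees of freedom** come from pooling all cells, so the
  $t$ quantile is effectively Gaussian for realistic dataset sizes; with
  triplicates and $\sigma = 0.05$ D this lands the threshold near 0.08 D.
* **Ties and zero variance** never produce NaN; see the conventions above.
* **Kabsch sign correction** uses the determinant of $VU^\top$ to exclude
  reflections; self-superposition RMSD is 0 to machine precision and rigid
  invariance holds to $10^{-8}$ Å on in-memory coordinates (file round-trips
  are limited by PDB's $10^{-3}$ Å field precision).
* **Problem sizes** in the shipped tests and drivers (e.g. 1000 null cells,
  150–1000 frames, 5 replicas) were chosen as the smallest sizes at which
  the binomial/replica standard errors make the checks meaningful.

# Worked example

```{r example}
prot <- random_protein(200, seed = 2001)
map <- make_digestion_map(prot, mean_length = 12, overlap_depth = 3,
                          seed = 2002)
apo <- exchange_model(prot, k_int = 1, protection = 1000)
pvec <- rep(1000, 200); pvec[40:60] <- 10000
holo <- exchange_model(prot, k_int = 1, protection = pvec)
ds <- simulate_uptake(list(apo = apo, mel = holo), map, replicates = 3,
                      noise_sd = 0.05, seed = 2003)

thr <- global_threshold(ds, "mel", "apo")
thr
diffs <- hybrid_classify(delta_uptake(ds, "mel", "apo"), thr)
table(diffs$direction)

cc <- consensus_effects(diffs, ds)
table(cc$effect)
```

# Known limitations

* Real HDX noise is neither homoscedastic nor purely Gaussian, and back
  exchange varies by residue; the generator models none of this.
* Consensus mapping treats peptides as rectangles of uniform information;
  sub-peptide localization beyond overlap resolution is not attempted.
* Occupancy analysis assumes pre-imaged trajectories; only an orthorhombic
  minimum-image option is provided.
* `read.cif` support inherits the limitations of bio3d's reader; the mmCIF
  writer emits the atom_site loop only.
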