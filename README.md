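# hdxtraj

Structural-dynamics analysis for ligand-coupled membrane transporters (the
motivating system is MelB, a Na⁺-coupled melibiose symporter whose sugar- and
cation-binding sites communicate allosterically). The package integrates two
data streams:

1. **Differential HDX-MS.** Peptide-level deuterium-uptake tables
   (state × timepoint × replicate) are tested with the *hybrid significance
   criteria*: a cell (peptide × timepoint) is significant only if
   |ΔD| = |D̄_holo − D̄_apo| exceeds a dataset-wide global threshold

   > thr = t₍₁₋α/2, dof₎ · s_p · √(1/n_holo + 1/n_apo),

   where s_p pools the replicate SD over every cell of the state pair, **and**
   Welch's unequal-variance t-test gives p < α (default 0.05). Peptide calls
   collapse to per-residue consensus classes (protected / deprotected / mixed /
   not significant / uncovered) via overlapping-peptide agreement and can be
   written into the B-factor channel of a PDB/mmCIF model.
2. **MD trajectory statistics.** Binding-site water occupancy by a four
   heavy-atom-pair geometric rule (both pair distances ≤ 4.0 Å and at least
   one < 3.5 Å; occupancy = fraction of frames with ≥ 1 occupying water,
   pooled over replicas), and per-residue side-chain heavy-atom RMSF with an
   unpaired Welch test on replica values between states.

Structure utilities (ligand-pocket residues within a cutoff, polar contacts,
Kabsch Cα superposition RMSD) support the mapping, and a synthetic-data
module simulates first-order hydrogen-exchange kinetics with per-residue
protection factors plus toy trajectories with known occupancy and RMSF, so
the whole pipeline is testable with ground truth and no external downloads.

Intended users: HDX-MS and MD practitioners who want the differential
statistics, consensus mapping and trajectory criteria in one scriptable,
tested toolbox.

## Worked example

```r
library(hdxtraj)

# a 200-residue synthetic transporter, ~50 overlapping peptic peptides
prot <- random_protein(200, seed = 2001)
map  <- make_digestion_map(prot, mean_length = 12, overlap_depth = 3, seed = 2002)

# bound state: 10x protection over residues 40-60; 30/300/3000 s, triplicate
apo  <- exchange_model(prot, k_int = 1, protection = 1000)
pv   <- rep(1000, 200); pv[40:60] <- 10000
holo <- exchange_model(prot, k_int = 1, protection = pv)
ds   <- simulate_uptake(list(apo = apo, mel = holo), map,
                        replicates = 3, noise_sd = 0.05, seed = 2003)

thr <- global_threshold(ds, "mel", "apo")
thr
#> <hdx_threshold> mel-apo: pooled SD 0.05085 (dof 612), alpha 0.05 -> |dD| > 0.08153

diffs <- hybrid_classify(delta_uptake(ds, "mel", "apo"), thr)
sum(diffs$significant)
#> [1] 24
```

The threshold line says the replicate noise pools to ≈0.051 deuterons across
all 612 residual degrees of freedom, so a |ΔD| above ≈0.082 deuterons clears
the magnitude arm; 24 peptide–timepoint cells also pass Welch's test, all of
them protections inside or overlapping the seeded 40–60 block.

The same workflow, end to end with structure and trajectory steps, is in the
numbered drivers:

```sh
Rscript analysis/01_simulate_hdx.R        # uptake tables + ground truth
Rscript analysis/02_differential_hdx.R    # threshold, Welch tests, hybrid calls
Rscript analysis/03_residue_consensus.R   # per-residue classes + B-factor maps
Rscript analysis/04_structure_annotations.R  # pocket, contacts, superposition
Rscript analysis/05_trajectory_dynamics.R    # water occupancy + RMSF comparison
```

Each driver prints what it found and writes its tables under `results/`.
Step 5, for example, reports for the simulated two-state system (five
replicas, twofold side-chain damping on binding, 60% target water occupancy):

```
water-1 site occupancy: apo 0.047, bound 0.597 (pooled over 750 frames each)
residues with significantly damped side chains: 20/20 (p < 0.05)
mean RMSF apo 1.381 A vs bound 0.691 A (expected sqrt(3)*sigma: 1.386 vs 0.693)
```

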