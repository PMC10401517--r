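# sascliffs

Structure–activity landscape analysis for chemical bioactivity datasets:
activity-cliff detection on a structure–activity similarity (SAS) map,
matched-molecular-pair (MMP) cliff calling, seven-type structural cliff
classification, and mechanism-of-action (MOA) cliff classification for
chemicals screened in paired agonist/antagonist assays.

## Who this is for

Computational toxicologists and cheminformaticians working with screening
tables of the ToxCast/Tox21 shape — a chemical identifier, a SMILES, a
reported `modl_ga` (log10 AC50 in µM), a binary hit call and an assay
endpoint — who need to know where in their dataset the
similar-structure/similar-activity assumption breaks, which chemicals break
it most (activity cliff generators), and whether close analogs flip between
activating and blocking a receptor.

## The statistics at the core

* **Activity scale.** `pAC50 = −log10(AC50 in M) = 6 − modl_ga`; pair
  activity difference `Δ = |pAC50_i − pAC50_j|`. The cliff threshold Δ ≥ 2
  corresponds to a 100-fold potency change.
* **SAS map.** Every unordered pair is a point (Tanimoto similarity of
  2048-bit ECFP4 fingerprints, Δ). Thresholds `sim > 0.35` (strict) and
  `Δ ≥ 2` partition pairs into scaffold hops (I), smooth SAR (II),
  **activity cliffs (III)** and uncertain (IV). A chemical in ≥ 5 cliff
  pairs is an activity cliff generator (ACG).
* **MMPs.** Molecules are fragmented on 1–3 acyclic single bonds
  (carbon-anchored cut rule, hydrogen substitution included) and indexed by
  their shared constant part; size restrictions (fragment difference ≤ 8
  heavy atoms, fragment size ≤ 13, constant ≥ 2× each fragment, minimal
  transformation per pair) yield size-restricted MMPs, and Δ ≥ 2 flags
  MMP-cliffs.
* **Cliff types.** Scaffold / cyclic-skeleton / R-group / attachment-
  topology comparisons classify each cliff as one of: chirality, topology,
  R-group, scaffold, scaffold/topology, scaffold/R-group, unclassified.
* **MOA classes.** For structurally similar dual-endpoint chemicals
  (excluding inactive-in-both): opposite (agonist, antagonist) hit tuples →
  strong MOA-cliff; identical → same MOA; otherwise → weak MOA-cliff.

Molecular primitives (canonicalization, fingerprints, scaffolds, fragment
enumeration) are computed through a bundled Python RDKit helper
(`inst/python/chem_bridge.py`); the analysis itself is R.

## Worked example

The package ships a seeded synthetic-data generator that plants cliffs with
known ground truth (see the vignette for what it does and does not
emulate):

```r
library(sascliffs)

cfg <- synthetic_config(n_scaffold_families = 4, family_size = 6,
                        noise_sd = 0.1, seed = 7, check_margin = TRUE)
gen <- generate_series(cfg)

cur <- curate(gen$records)
#> Curated chemical dataset: 24 of 24 records retained
#>   dropped: missing activity 0 | invalid 0 | mixture 0 | duplicate 0 | linear 0

pairs  <- pairwise_table(cur$records)
cliffs <- find_activity_cliffs(pairs)
#> SAS-map activity cliffs: 10 pairs formed by 12 unique chemicals
#>   region counts: I=182 II=50 III=10 IV=34
#>   thresholds: similarity > 0.35 ; activity difference >= 2

head(cliffs$cliffs[, 1:4], 3)
#>        id_i      id_j  tanimoto activity_diff
#> 1 SYN-02-01 SYN-02-03 0.6842105      2.718624
#> 2 SYN-02-02 SYN-02-03 0.7368421      2.888667
#> 3 SYN-02-03 SYN-02-04 0.6923077      3.218281

find_acgs(cliffs)[, 1:2]
#>     chem_id cliff_pair_count
#> 1 SYN-02-03                5
#> 2 SYN-03-02                5

mm <- find_mmp_cliffs(
  apply_size_restrictions(index_mmps(fragment_molecules(cur$records))),
  cur$records)
#> Size-restricted MMPs: 60 pairs; 10 MMP-cliffs (activity difference >= 2)

attr(classify_cliffs(cliffs, cur$records), "histogram")
#>         chirality          topology           r_group          scaffold
#>                 0                 0                10                 0
#> scaffold_topology  scaffold_r_group      unclassified
#>                 0                 0                 0
```

Reading the output: the 276 pairs among 24 chemicals split into the four
SAS regions; the 10 region-III pairs are exactly the planted
jumped-vs-unjumped analog pairs (two jumped families of six members →
2 × 5 cliffs); the two jumped chemicals each sit in 5 cliff pairs and are
the ACGs; every cliff is an analog pair differing in one substituent on a
shared scaffold, so all 10 classify as R-group cliffs and are also
MMP-cliffs. `run_pipeline()` chains all stages (plus the MOA stage when
both endpoints are given) and writes CSV artifacts and a manifest;
`inst/cli/sascliffs` exposes the same stages as subcommands
(`curate`, `pairs`, `sasmap`, `mmp`, `classify`, `moa`, `synth`,
`run-all`).

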