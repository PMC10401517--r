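---
title: "Structure-activity landscapes, activity cliffs and MOA-cliffs with sascliffs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-activity landscapes, activity cliffs and MOA-cliffs with sascliffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative structure-activity relationship (QSAR) modelling assumes that
similar structures have similar activities. Real screening datasets violate
this assumption locally: a pair of nearly identical chemicals can differ a
hundred-fold or more in potency. Such pairs are *activity cliffs*, and their
presence bounds the accuracy any similarity-based predictor can reach on that
dataset. When the same chemicals are screened in two complementary assays
(for a receptor, typically an agonist and an antagonist mode), structurally
similar pairs can additionally differ in their *mechanism of action* (MOA) -
one analog activates the receptor while the other blocks it. `sascliffs`
detects and characterizes both phenomena from a plain activity table:
chemical identifiers, SMILES, a log-AC50 activity (`modl_ga`, log10 of the
AC50 in micromolar, as reported by high-throughput screening pipelines such
as ToxCast/Tox21), a binary hit call, and an assay-endpoint label.

## Activity scale

All thresholding is done on the pAC50 scale. With `modl_ga` the log10 AC50
in micromolar units,

    AC50(M) = 10^modl_ga * 1e-6,      pAC50 = -log10(AC50(M)) = 6 - modl_ga

and the activity difference of a pair is `|pAC50_i - pAC50_j|`. Two log
units equal a 100-fold potency change; differences are never computed on raw
AC50 ratios.

## Curation

`curate()` applies, in order: drop records with no reported activity;
standardize structures; compute pAC50; deduplicate; remove ring-free
("linear") chemicals. Standardization strips recognized counter-ion and
solvent fragments (a packaged, deliberately inorganic-only list - organic
acids such as acetate are treated as the parent structure, so sodium acetate
curates to acetic acid), collapses repeated identical fragments, rejects
true multi-component mixtures, neutralizes the survivor and canonicalizes
it. The stereochemistry-stripped canonical SMILES is the package-wide
structure key - for deduplication, scaffold comparison and matched-pair
constants alike - because the whole workflow (ECFP4 without chiral bits) is
stereo-insensitive; the stereo-bearing form is kept as a provenance column.
Two records differing only in stereo flags are therefore duplicates, and the
first occurrence in file order wins (the upstream tools this emulates do not
document a tie-break; first-wins is reproducible and the log records every
loser).

## The SAS map

Every unordered pair of curated chemicals is placed on a structure-activity
similarity (SAS) map: x = Tanimoto coefficient between 2048-bit ECFP4
(Morgan radius 2) fingerprints, y = activity difference. Two thresholds
partition the map:

* similarity: a pair is "similar" when Tanimoto is **strictly greater
  than** 0.35;
* activity: a pair is "activity-different" when the difference is **at
  least** 2 log units.

The two boundary operators intentionally differ; `assign_region()` encodes
them exactly. Region I (dissimilar/similar activity) holds scaffold hops,
region II (similar/similar) the smooth SAR, region III (similar/different)
the activity cliffs, region IV (dissimilar/different) the uncertain
remainder. The 0.35 default is not sacred: on typical environmental-chemical
collections it sits near `median + 3*SD` of the pairwise Tanimoto
distribution, and `suggest_similarity_threshold()` reports that diagnostic
for your dataset (note it mixes a robust location estimate with the sample
standard deviation about the mean; we compute and document exactly
`median + 3*sd`). The pipeline default stays 0.35 unless overridden.
Fingerprint length (2048) is the community default and configurable; pair
counts near the threshold can be sensitive to it.

A chemical participating in at least 5 cliff pairs is an *activity cliff
generator* (ACG) - a chemical whose presence degrades local QSAR reliability
most. Ties in the ACG ranking are broken by identifier for reproducible
output.

## Matched molecular pairs

The second, substructure-based cliff detector generates matched molecular
pairs (MMPs) by fragment-and-index: every molecule is cut on 1-3 acyclic
single bonds (the standard carbon-anchored matched-pair cut rule,
`[#6+0;!$(*=,#[!#6])]!@!=!#[*]`; ring bonds are never cut), the single
fragment holding all attachment points is the *variable* part and the rest
the *constant* part, attachment labels are canonicalized by permutation so
identical constants hash equal, and hydrogen substitutions are included as
single-cut fragmentations with a zero-heavy-atom variable part. Chemicals
sharing a constant with differing variable parts form an MMP. We adopted the
carbon-anchored cut rule (rather than "every acyclic single bond") so that
the enumeration is checkable pair-for-pair against an independent
implementation of the same scheme (RDKit's `rdMMPA`); the tests do exactly
that on a fixture panel.

Four size-restriction criteria then make transformations chemically
meaningful: (i) exchanged fragments differ by at most 8 heavy atoms;
(ii) the constant part is at least twice the size of each fragment
(vacuously true for hydrogen fragments); (iii) each fragment has at most 13
heavy atoms; (iv) per chemical pair, only the transformation with the least
heavy-atom difference survives (ties: smaller total fragment size, then the
lexicographically smallest transformation - the selection must be
deterministic, and the literature is silent on ties). A size-restricted MMP
with activity difference >= 2 is an *MMP-cliff*. Because the MMP route is
far more restrictive than fingerprint similarity, MMP-cliffs are expected to
be (and on our synthetic worlds are) a subset of the SAS-map cliffs;
`compare_with_sas()` reports the overlap rather than assuming it.

## Seven-type cliff classification

Each cliff pair is explained structurally from four comparisons: Bemis-
Murcko scaffold equality; cyclic-skeleton equality (the scaffold with every
heavy atom carbon and every bond single - pure ring topology); R-group
multiset equality; and R-group topology (attachment-pattern) equality. The
decision tree: with equal scaffolds, equal R-groups and equal topology give
*chirality* (only stereochemistry can differ), equal R-groups with moved
attachment sites give *topology*, and differing R-groups give *r_group*;
with different scaffolds, differing skeletons give *unclassified*, while a
shared skeleton gives *scaffold_r_group* (R-groups differ), *scaffold*
(everything else equal) or *scaffold_topology* (sites moved).

Topology comparison is the one genuinely open design point: the original
scheme was applied manually. We compare canonical SMILES of the scaffold
decorated with one labelled attachment dummy per R-group (labels encode
which R-group sits where, so swapping two different groups between sites
counts as a topology change); across different scaffolds with a shared
skeleton the decorated *skeleton* is compared instead, which makes the
comparison exact up to graph automorphism without any explicit embedding
search. Hypervalent scaffolds that cannot be sanitized after
carbon-genericization fall back to an explicit-valence serialization - still
a deterministic topology key. The chirality label is retained for
completeness although the stereo-insensitive fingerprints upstream make it
practically unreachable for real cliff pairs (a known limitation of the
workflow, inherited deliberately).

## MOA classification

For chemicals present in both an agonist and an antagonist dataset (matched
by canonical structure; identifier matching is unreliable when registry
coverage is incomplete), pairs with Tanimoto > 0.35 - the same threshold
and operator as the SAS map, read from one shared configuration value - are
labelled from their (agonist, antagonist) hit tuples after removing
chemicals inactive in both assays: element-wise opposite tuples form a
*strong MOA-cliff*, identical tuples *same MOA*, anything else a *weak
MOA-cliff*. The three labels partition the similar pairs by construction.

## The synthetic world

`generate_series()` builds analog series the way a medicinal-chemistry
dataset is structured: up to 10 scaffold families (steroid-like, glucoside,
spiro-amine, pyrazole-biaryl, flavone, sulfolane, pyridyl-piperazine,
binaphthyl, tetralone, indole cores), each decorated at one aromatic
position with small substituents (H, methyl, ethyl, halogens, hydroxyl,
methoxy, amino, nitrile). pAC50 values are `family base (uniform on [4, 7])
+ substituent effect (uniform on +-0.15) + Gaussian noise (sd 0.2,
truncated at 3 sigma)`; a configurable fraction of families has one member
jumped by 3 log units. The core panel was fixed once, before any test was
written, so that at 2048-bit ECFP4 every within-family pair exceeds 0.35
similarity (minimum 0.47) and every cross-family pair stays below it
(maximum 0.30): planted-cliff ground truth is then pure combinatorics -
every jumped/unjumped pair within a jumped family, nothing else.

Exact-recovery assertions additionally require the separation condition
`cliff_jump - effect_range - 6*noise_sd >= 2` and `effect_range + 6*noise_sd
< 2`; note the general-use defaults (jump 3, noise 0.2) do *not* satisfy it
- recovery tests run at noise 0.1, and `check_margin = TRUE` refuses
under-separated configurations rather than producing flaky truth. Noise
truncation at 3 sigma is what turns the margin from a probabilistic
statement into a hard guarantee.

What the generator does **not** emulate: the long-tailed structural
diversity of real environmental-chemical libraries (median pairwise Tanimoto
around 0.1, thousands of singleton scaffolds), activity-measurement
artifacts, stereoisomer pairs, and mixtures arriving as multi-component
records. A green recovery test therefore establishes the correctness of the
detection and classification machinery under the stated model - not that
any particular real dataset yields any particular cliff count.

## Numerical and degenerate-input choices

* Boundary semantics: similarity strict `>`, activity `>=`, everywhere.
* An empty fingerprint union (two zero-bit vectors) has Tanimoto 1 by
  convention; it cannot occur for molecules with a heavy atom.
* Identical duplicated fragments in one SMILES collapse to one before the
  mixture test; a structure that is nothing but salt components is invalid.
* Pairwise tables are computed by bit-matrix cross-products; at n = 1000
  chemicals this is a 1000 x 2048 dense matrix, well within memory.
* All generator randomness is seeded and restored (`.Random.seed` is left
  untouched); reruns are byte-identical.
* Zero-row inputs flow through every stage (empty cliff sets, empty MMP
  tables) and produce empty, correctly-typed outputs.

## Known limitations

* Stereochemistry is ignored throughout; chirality cliffs are structurally
  unreachable on real data (see above).
* The MOA stage compares hit calls, not potencies, because the two
  annotations come from different assays; no cross-assay affinity
  quantification is attempted.
* Aggregate cliff counts on any specific external dataset depend on the
  exact fingerprint length and fragmentation rule of the tools that
  produced published numbers; this package fixes both and documents them.
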