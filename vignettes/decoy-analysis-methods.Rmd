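---
title: "Interaction-fingerprint analysis of docking decoys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-fingerprint analysis of docking decoys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockfp)
```

## The problem

Rigid-body protein–protein docking against a receptor that undergoes large
conformational changes (calmodulin being the classic case) produces large
ensembles of candidate complexes ("decoys"), most of them false positives.
Ensemble docking makes this worse: docking the same ligand against every
member of an NMR conformer ensemble multiplies the decoy count by the number
of conformers. The post-docking task is to find the near-native poses in
that pile, ideally *without* knowing the native complex.

Cartesian measures such as ligand RMSD depend on a superposition step and
degrade when receptor conformers differ by large hinge motions. `dockfp`
implements the alternative: compare decoys by *which residues touch which*,
encoded as an interaction fingerprint, and combine fingerprint clustering
with energy-score profiles to discriminate near-native decoy groups.

## Interaction fingerprints

For a receptor of N residues and a ligand of L residues, a decoy's
fingerprint is a bit vector over the fixed N×L universe of residue pairs;
bit (r−1)·L + (l−1) is set iff residues r and l are in non-bonded contact.
A contact is any receptor heavy atom within a distance cutoff of any ligand
heavy atom — hydrogens are excluded, there is no lower distance bound and no
atom-type restriction. The default cutoff for all-atom structures is
3.90 Å, the conventional maximum for non-bonded contact detection in
interface-analysis tools; it is exposed as a parameter everywhere.

Residue pairing is *positional*: residues are indexed 1..N in chain order,
independent of author numbering, insertion codes, or point substitutions
between bound and unbound forms. The universe is fixed per
receptor–ligand system, so fingerprints computed on different receptor
conformers remain directly comparable — a requirement for cross-conformer
ensemble analysis.

Fingerprints are compared with the Tversky family

$$S(A,B) = \frac{c}{\alpha(a-c) + \beta(b-c) + c}$$

where $a$, $b$ are the two popcounts and $c$ the number of shared bits.
Two members matter:

* **Tanimoto index** ($\alpha=\beta=1$): $c/(a+b-c)$, symmetric; used for
  decoy–decoy comparison and clustering (distance $1 - S$).
* **S_frac** ($\alpha=1, \beta=0$ with the native fingerprint as query
  $a$): $c/a_\text{native}$, the fraction of native residue pairs a decoy
  recovers. Because the native popcount is fixed, S_frac takes values on a
  discrete grid $\{0, 1/a, \dots, 1\}$. It is preferred over Tanimoto for
  decoy-to-native scoring because Tanimoto loses linearity when the decoy
  has many more bits than the native.

Degenerate case: two empty fingerprints get similarity 0 (with a warning)
rather than NaN, so distance matrices are always defined; an
empty-interface pair is maximally distant, which is the conservative choice
for clustering.

## RMSD convention

The package's ligand RMSD is receptor-anchored: the decoy receptor is
superposed onto the reference receptor over Cα atoms of all shared residues
(Kabsch, SVD with reflection correction), the transform is applied to the
decoy ligand, and the RMSD over ligand Cα (or heavy) atoms is reported with
no further fitting. For decoy–decoy matrices every decoy is first mapped
into a single declared reference conformer's frame, which makes the matrix
well-defined across conformers. This is a declared convention — the
standard docking ligand-RMSD — not an inference about any particular
historical pipeline; complex-wide or all-atom variants would give different
absolute values.

A simplified global-distance-test curve is provided for conformer
comparison: superpositions are seeded from every contiguous 7-residue Cα
window and iteratively extended with all residues within the cutoff until
the fitted set stops growing; the curve reports the maximum residue
fraction per cutoff (as a running maximum over ascending cutoffs, so the
reported curve is nondecreasing). This is a deterministic heuristic, not a
full LGA search: it can under-estimate the optimal fraction, and it is
intended for qualitative hinge-motion comparison only.

## Clustering and energy uniformity

Decoy distance matrices (1 − Tanimoto, or pairwise ligand RMSD) are
clustered with UPGMA: merge the closest pair; the distance from the merged
cluster to any other is the size-weighted arithmetic mean of the members'
distances; the merge height is the merged pair's distance. Heights are
nondecreasing. Ties in the minimal distance are broken by the
lexicographically lowest cluster-index pair, making results deterministic
across platforms. Trees are cut either at a height (a Tanimoto threshold
$t$ maps to height $1-t$, so the canonical Tc thresholds 0.6/0.8/0.9 are
cuts at 0.4/0.2/0.1) or into exactly $k$ groups by removing the $k-1$
highest merges.

Two workflows are exposed:

* **Pooled threshold cuts**: all decoys in one tree, cut at the canonical
  thresholds (Tc 0.6/0.8/0.9; RMSD 3/5/8/10 Å), then per-group energy
  statistics. The quality measure is the mean per-group sample SD of the
  energy score over groups of size ≥ 2 (singletons report SD 0 and are
  flagged but excluded from the summary; sample SD is a documented choice —
  population SD would shrink every group estimate slightly but change no
  comparison). A grouping method is better when its groups are more
  energy-uniform.
* **Per-conformer k-groups**: each conformer's decoys are clustered
  separately into $k = 10$ groups, giving $10 \times$ (number of
  conformers) groups with globally unique ids. This is the workflow for
  near-native group discrimination.

Pooled matrices are $O(n^2)$; the functions refuse more than 20 000 decoys
unless the cap is raised explicitly, and per-conformer mode is recommended
at ensemble scale.

## Near-native discrimination

Given group scorecards (size, mean energy, mean per-member S_frac, S_frac
of the union fingerprint, b-decoy fraction), two selection modes exist:

* `by_s_frac` — argmax mean S_frac; requires the native complex and serves
  as the evaluation reference.
* `by_energy` — argmin mean energy; uses *only* energies and cluster
  structure, never the native fingerprint. This is the blind prediction
  mode.

Ties break toward the larger group, then the smaller group id. Agreement
between the two modes on ensembles with a planted near-native subpopulation
is the package's central recoverable property.

Decoy populations are compared on a metric axis by range-based area
classification: area I is the value range occupied only by b-decoys
(bound-conformer decoys), area III only by a-decoys, area II the overlap.
Ranges, not histogram bins, define the areas — bin-based counting
reproduces published figures only up to bin width, whereas range-based
labels are parameter-free and deterministic. Per-residue interaction
frequencies (fraction of group members touching each receptor residue)
summarize what a group's members agree on; the profile of a native
singleton group is exactly the native contact indicator.

## The synthetic generator

Everything above is exercised end-to-end on synthetic ensembles built by
`simulate_ensemble()`. The generator emulates the *structure* of an
ensemble-docking experiment, not its physics:

* **Receptor**: a Cα+CB pseudo-atom chain (60 residues by default) folded
  as two packed idealized helical segments (rise 1.5 Å/residue, radius
  2.3 Å) joined by a short loop; the inter-segment gap is the binding
  groove. CB pseudo-atoms point radially off the local helix axis.
* **Ligand**: a 12-residue helical Cα chain seated in the groove. The
  native interface is validated to carry at least 10 residue-pair contacts.
* **Conformers** (default 5): the bound form plus unbound conformers made
  by rotating the second segment about the inter-segment loop by a random
  hinge angle (SD 20°) with 0.3 Å per-atom jitter — a coarse analogue of
  NMR ensemble variability dominated by a hinge motion.
* **Decoys** (default 100 per conformer): rigid-body ligand poses. On the
  bound conformer, 15% are *tight* poses — the native pose perturbed by
  ~1.5 Å translations and ~10° rotations (the planted near-native
  subpopulation, labeled like the decoys that only the bound receptor can
  produce); all remaining poses are *loose*. Loose poses are a mixture
  over a small set of surface funnels per conformer (10 in total;
  on the bound conformer the native groove is one of them, leaving 9
  background funnels), each funnel being a random non-interface surface
  anchor with ~2 Å / 20° within-funnel scatter. The funnel structure
  matters: docking output piles many similar poses into a limited number
  of favorable patches, and that redundancy is precisely what makes decoy
  sets clusterable. Background funnels avoid native-interface residues
  because near-native content is, by the generator's definition, carried
  only by the planted tight subpopulation.
* **Energies**: $E = -k \cdot (\text{native residue pairs recovered}) +
  \sigma \varepsilon$ with $k = 5$, $\sigma = 8$, $\varepsilon \sim
  N(0,1)$ — a declared stand-in for an external rescoring function, made
  monotone in native-contact recovery *by construction*. This is what
  turns "blind low-energy selection finds the near-native group" into a
  testable property of the pipeline rather than an empirical claim about
  any particular force field.
* **Contact cutoff**: 6.0 Å for synthetic structures (pseudo-atom packing
  is sparser than all-atom; the all-atom default remains 3.90 Å).

Everything is deterministic given the seed; the ground-truth table (pose
class, recovered native bits, true ligand RMSD, applied transform) is
emitted for test assertions only.

What the generator deliberately does **not** model: side chains and
rotamer packing, realistic energetics (electrostatics, desolvation),
docking-score biases uncorrelated with nativeness, binding-site overlap
between the native funnel and background funnels, pseudo-symmetric
inverse-binding poses, and sequence differences between bound and unbound
forms. Consequently, passing the planted-truth tests demonstrates that the
*pipeline* (fingerprints → UPGMA → energy-based selection) recovers a
planted signal under contact-driven energies; it does not demonstrate that
any real scoring function is contact-driven, nor predict performance on
shallow or small interfaces, where fingerprint discrimination is known to
weaken.

```{r example, eval = FALSE}
ens <- simulate_ensemble(synthetic_config(seed = 1))
fps <- decoy_fingerprints(ens$decoys, cutoff = 6.0,
                          receptor_length = 60, ligand_length = 12)
res <- discriminate_near_native(ens$decoys, ens$native_fp, fps = fps, k = 10)
res$agreement   # blind == native-informed selection?
```

## Numerical choices and degenerate inputs

* Contact detection is exact vectorized all-pairs distance evaluation,
  chunked to bound memory; it is verified against a scalar brute-force
  loop. No spatial-grid approximation is used, so there is no grid/exact
  discrepancy to manage.
* Kabsch uses base `svd()` with determinant sign correction; inputs with
  fewer than 3 points or (near-)collinear configurations are rejected
  (second singular value below 1e−8 of the first).
* UPGMA validates symmetry to 1e−9, non-negativity and a zero diagonal;
  heights from the incremental update match a from-scratch naive
  recomputation to 1e−9 on random matrices.
* Alternate locations resolve to the highest occupancy (ties: first
  encountered); waters are dropped; HETATM residues survive only when they
  carry a Cα (modified residues inside a polymer chain); elements are
  inferred from atom-name columns when the element field is blank.
* Group SDs use the sample (n−1) convention; singleton groups report 0 and
  are excluded from ensemble summaries.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script studies run 50 replicate ensembles of
5 conformers × 100 decoys (500 decoys each, 60×12 bit universe) — sizes at
which the pooled workflow, the per-conformer workflow and all property
checks complete quickly on a single core while leaving the clustering trees
non-trivial (≈ 50–150 groups at the canonical cuts). The discrimination
property is reported as the fraction of replicates in which the blind
low-energy group is ≥ 80% planted members; the uniformity property as the
fraction of replicates in which the fingerprint grouping's mean per-group
energy SD (averaged over its canonical thresholds) is at most the RMSD
grouping's. Accession-anchored checks against real NMR ensemble entries
(model counts, chain lengths, native contact totals and fingerprint
popcounts) are included in the acceptance tests but require the four
reference PDB files locally; the native contact totals are sensitive to
the 3.90 Å cutoff choice, and any mismatch is reported rather than
absorbed by re-tuning the cutoff.

## Known limitations

* The GDT curve is a seed-and-extend heuristic (window stride 1), not an
  exhaustive search; use it for hinge-motion comparison, not for scoring.
* Fingerprint distance is Tanimoto-only for clustering; typed fingerprints
  (H-bond/ionic/aromatic channels) are out of scope.
* No symmetry correction for pseudo-symmetric helical ligands: an
  inverse-bound pose legitimately scores high RMSD while sharing many
  contacts.
* Pooled clustering is quadratic in decoy count; cluster per conformer at
  ensemble scale.
* The energy model's monotonicity in native-contact recovery is an
  assumption about rescoring functions, encoded in the generator; blind
  selection inherits whatever violations a real scoring function commits.
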