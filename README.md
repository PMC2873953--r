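# dockfp — interaction-fingerprint analysis of protein–protein docking decoys

`dockfp` is an R toolkit for the *post-docking* stage of ensemble
protein–protein docking: given thousands of candidate receptor–ligand
complexes ("decoys") built on multiple receptor conformers, find the
near-native ones — ideally without knowing the native complex. It is aimed
at structural bioinformaticians analyzing rigid-body docking output for
receptors with large conformational changes (hinge-bending calmodulin-like
systems), where plain ligand RMSD is confounded by the superposition step.

## The method

Each decoy interface is encoded as an **interaction fingerprint (IFP)**: a
bit vector over the fixed N×L universe of receptor×ligand residue pairs,
where bit (r−1)·L+(l−1) is set iff residues r and l share a non-bonded
heavy-atom contact (distance ≤ 3.90 Å by default). Fingerprints are
compared with the Tversky similarity

S(A,B) = c / (α(a−c) + β(b−c) + c)

with popcounts a, b and shared-bit count c. α=β=1 gives the **Tanimoto
index** Tc = c/(a+b−c) (decoy–decoy comparison); α=1, β=0 with the native
fingerprint as query a gives **S_frac** = c/a_native, the fraction of
native residue pairs a decoy recovers. Decoys are clustered with **UPGMA**
on 1−Tc (or on receptor-anchored ligand-Cα RMSD after Kabsch
superposition), trees are cut at similarity thresholds or into k groups,
and near-native groups are discriminated two ways: *blind* (lowest mean
energy score, using only energies and cluster structure) and
*native-informed* (highest mean S_frac). Agreement of the two selections,
and the superior energy-uniformity of fingerprint groups over RMSD groups,
are the package's testable claims.

A self-contained synthetic generator (`simulate_ensemble()`) builds toy
receptor conformer ensembles with a planted near-native decoy
subpopulation and contact-driven pseudo-energies, so the whole pipeline is
exercisable and testable offline. See the methods vignette
(`vignettes/decoy-analysis-methods.Rmd`) for models, assumptions and
limitations.

## Worked example

```r
library(dockfp)

ens <- simulate_ensemble(synthetic_config(seed = 1))   # 5 conformers x 100 decoys
fps <- decoy_fingerprints(ens$decoys, cutoff = 6.0,
                          receptor_length = 60, ligand_length = 12)
ens$native_fp
#> <ifp> universe 60 x 12, 40 set bits

res <- discriminate_near_native(ens$decoys, ens$native_fp, fps = fps, k = 10)
res$blind_group; res$sfrac_group; res$agreement
#> [1] 1        # group with the lowest mean energy (blind mode)
#> [1] 1        # group with the highest mean S_frac (native-informed)
#> [1] TRUE     # the two selections agree

head(res$scorecards, 3)
#>  group_id n_decoys mean_energy mean_s_frac union_s_frac b_fraction
#>         1       15  -157.38167   0.7983333        1.000          1
#>        17        1   -23.65560   0.0000000        0.000          0
#>        23       10   -20.41836   0.1075000        0.225          0
```

The native interface sets 40 of the 720 residue-pair bits. After
per-conformer UPGMA clustering into 10 groups each (50 groups total), the
blind lowest-energy group (15 decoys, mean energy −157, every member a
bound-conformer decoy) is exactly the planted near-native subpopulation —
its union fingerprint recovers all native pairs (`union_s_frac = 1`), and
the native-informed selection picks the same group.

Comparing grouping quality by energy uniformity (smaller per-group energy
SD = more coherent groups):

```r
compare_group_energy_uniformity(ens$decoys, fps)
#>  method threshold n_groups n_groups_ge2 mean_group_sd sd_group_sd
#>     ifp       0.8      482           17      7.990332    3.373037
#>    rmsd       8.0       45           43      9.552359    3.841231
```

Fingerprint groups at the Tc 0.8 cut are more energy-uniform (mean SD 8.0)
than RMSD groups at the 8 Å cut (mean SD 9.6).

A command-line interface wrapping the same functions ships at
`inst/cli/dockfp` (subcommands `simulate`, `fingerprint`, `rmsd`,
`cluster`, `analyze`, `gdt`):

```sh
Rscript inst/cli/dockfp simulate --out sim --seed 1
Rscript inst/cli/dockfp fingerprint --dir sim
Rscript inst/cli/dockfp cluster --fingerprints sim/fingerprints.tsv \
    --distance ifp --per-conformer --k 10 --out sim/clus
```

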