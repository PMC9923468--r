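# mitoreef

Small-scale population structure of reef corals from whole mitochondrial
genomes.

Broadcast-spawning corals like *Acropora* are usually genetically uniform
over tens of kilometres, so ordinary F-statistics say little about how many
larvae actually stay on their natal reef — the quantity that determines
whether heat-tolerant genotypes can build up locally and whether assisted
gene flow has a chance of sticking. The whole mitogenome (~18.5 kb,
inherited as one fully linked locus) changes the picture: colonies with
*identical* mitogenomes share a recent maternal ancestor, so the spatial
arrangement of identical and near-identical genomes carries a dispersal
signal on recent time scales.

`mitoreef` takes an aligned FASTA of haploid mitogenome consensus sequences
plus a colony metadata table (reef, region, coordinates, optional heat
exposure) and provides:

* **Distances** — pairwise nucleotide differences d_ij with pairwise
  deletion of uncalled sites (`N`/`-`), variable-site counts, diversity
  summaries.
* **Haplogroups** — clusters of identical genomes (connected components of
  the d = 0 graph), with singletons one base from a group consensus folded
  in; a strict-identity mode keeps exact matches only.
* **AMOVA** — three-level analysis of molecular variance
  (regions / reefs within regions / colonies within reefs) with
  Φ_RT = σ²_a/σ²_T, Φ_PR = σ²_b/(σ²_b+σ²_c), Φ_ST = (σ²_a+σ²_b)/σ²_T and
  stratum-appropriate permutation p-values; per-haplogroup chi-square tests
  of regional homogeneity with FDR correction.
* **Co-occurrence** — the centrepiece: T = Σ_{g,r} C(k_gr, 2), the number
  of colony pairs sharing both a haplogroup and a reef, tested against a
  constrained permutation null that shuffles colonies among reef slots
  while preserving reef sizes and the group-size spectrum; plus the
  rare-group (2–10 members) variant.
* **Spatial** — haversine reef distances, isolation-by-distance and
  heat-difference regressions over reef pairs (optional Mantel
  permutation).
* **Rates** — mutation wait time 1/(L·r) and divergence time p/r under an
  explicit pairwise/per-lineage convention flag.
* **Simulator** — a reef-metapopulation generator with founder haplotypes
  on a random genealogy and a tunable local-retention probability ρ, with
  ground truth for validation.

## Worked example

A Palau-scale synthetic survey (39 reefs in 7 regions, 273 colonies,
18,482 bases) with moderate local retention, analysed end to end:

```r
library(mitoreef)

sim <- simulate_reefs(sim_config(retention = 0.25, seed = 1))
dm  <- pairwise_difference_matrix(sim$alignment)
h   <- assign_haplogroups(sim$alignment, dm)
summary(h)
#> Haplogroups (haplogroup): 30 groups, largest 46
#>   core 245, folded 25, ungrouped 3; rare (2-10) groups: 22

cooccur_test(h, sim$metadata, B = 1000, seed = 2)
#> Reef co-occurrence test (haplogroup mode; same-reef same-group pairs)
#>   observed: 111   null: 54.4 (SD 6.81)
#>   one-tailed p = 0.000999  (B = 1000, seed = 2)

amova(dm, sim$metadata, permutations = 499, seed = 3)
#> Hierarchical AMOVA (273 colonies; squared distances: site counts)
#>
#>                      Source  df       SS     MS Est. var.     %
#>               Among regions   6  129.379 21.563     0.308   4.5
#>  Among reefs within regions  32  306.500  9.578     0.499   7.2
#>                Within reefs 234 1423.714  6.084     6.084  88.3
#>                       Total 272 1859.593     NA     6.891 100.0
#>
#> Phi statistics:
#>   PhiRT = 0.045  (p = 0.008, B = 499)
#>   PhiPR = 0.076  (p = 0.002, B = 499)
#>   PhiST = 0.117  (p = 0.002, B = 499)
```

Reading the output: 111 same-reef same-haplogroup pairs were observed where
random placement of the same colonies on the same reefs yields 54.4 on
average (SD 6.81) — colonies with identical genomes are strongly
co-located, the signature of local larval retention. The AMOVA attributes
most molecular variance to colonies within reefs, with a modest regional
component driven by the divergent clade's uneven regional frequencies.
With `retention = 0` the co-occurrence test is calibrated: observed ≈ null
and p is uniform.

`run_all(alignment, metadata, out_dir, B, seed)` executes every stage and
writes TSV/JSON artifacts (AMOVA table, haplogroup assignment, the four
co-occurrence tests with their null distributions, reef-pair table,
regressions) plus a `manifest.json`; the same seed reproduces every file
exactly. Real data enter through `read_alignment()` (FASTA) and
`read_metadata()` (CSV/TSV with columns
`colony,reef,region,lat,lon,date[,heat_fraction]`).

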