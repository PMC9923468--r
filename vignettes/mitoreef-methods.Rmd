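---
title: "Reef-scale population structure from whole mitochondrial genomes: methods"
author: "mitoreef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reef-scale population structure from whole mitochondrial genomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Broadcast-spawning corals such as *Acropora* release larvae that can, in
principle, drift for weeks, and most population-genetic surveys only detect
differentiation over hundreds of kilometres. Yet adaptation to local
conditions — and interventions like assisted gene flow — depend on how many
recruits actually come from the natal reef, a quantity ordinary
equilibrium F-statistics over such distances say little about.

The whole mitochondrial genome offers a different lens. It is inherited as a
single fully linked locus of ~18.5 kb, so although the per-base mutation
rate is tiny, the locus-wide mutation rate is thousands of times that of any
single SNP. Colonies whose entire mitogenomes are identical share a recent
maternal ancestor; where those colonies sit relative to one another is a
signal about dispersal on recent, management-relevant time scales.

`mitoreef` implements that analysis chain for an aligned set of haploid
mitogenome consensus sequences plus per-colony metadata (reef, region,
coordinates, optional heat exposure):

1. pairwise nucleotide differences with pairwise deletion of uncalled sites;
2. haplogroups: clusters of identical genomes, with single-base variants
   folded in;
3. hierarchical AMOVA with Phi fixation indices and permutation p-values;
4. a reef co-occurrence statistic with a constrained permutation null —
   the centrepiece;
5. isolation-by-distance and temperature regressions over reef pairs;
6. molecular-rate arithmetic (mutation wait time, divergence time);
7. a reef-metapopulation simulator with known ground truth.

## Distances with missing data

Consensus genomes assembled from shotgun reads carry uncalled bases (`N`,
typically a few dozen per genome here) and alignments can introduce gaps;
both are treated as "not called". For colonies $i, j$:

$$d_{ij} = \#\{\text{sites where both are called and differ}\}, \qquad
  c_{ij} = \#\{\text{sites where both are called}\}.$$

Pairwise deletion (dropping sites uncalled in *either* member of the pair)
is essential: complete-case deletion would discard most of the genome, and
any scaling by $c_{ij}$ would stop two genomes that differ nowhere they are
jointly called from being "identical". Distances are therefore raw site
counts. The cost is that $d$ is not guaranteed to satisfy the triangle
inequality, and zero distance is not transitive (A may match B, B match C,
yet A and C differ at a site that B has uncalled). We document the first
and detect the second (below) rather than hide either.

A column is *variable* when at least two distinct called bases occur in it;
`N`/gap never make a column variable. Ambiguity codes other than `N` are
rejected at parse time — a haploid consensus should not contain them, and
mapping them silently would corrupt identity calls.

## Haplogroups

`build_identity_groups()` forms the graph with an edge wherever
$d_{ij} = 0$ and takes connected components. Components of size $\ge 2$ are
candidate groups; singletons are held back. Because zero distance is not
transitive under missing data, a component can contain a pair with
$d > 0$; the component is still kept whole (the alternative — splitting —
has no principled cut point) and every violating pair is logged in
`$violations`.

Each group gets a consensus: per column, the majority called base over core
members, `N` where nobody is called. Since core members agree wherever
jointly called, the majority rule only bites in violation components;
elsewhere it reduces to filling across members, which is how it is
computed.

`fold_single_base_variants()` then folds every held-back singleton whose
genome is exactly one called base from a group consensus into that group
(`kind = "folded"`). Two deliberate choices:

* **Distance one to the consensus suffices.** Whether the variant allele is
  unique in the whole dataset is computed and logged per folded colony, but
  not enforced; requiring uniqueness would make folding depend on unrelated
  colonies elsewhere in the data.
* **Ties go to the largest group**, then the lowest label, and are logged.
  Ties are rare (they require a singleton equidistant from two consensuses)
  but the resolution must be deterministic.

Remaining singletons are `ungrouped`. The three kinds partition the
colonies in every mode. *Strict-identity mode* keeps only core members of
multi-member groups — the analysis restricted to exactly identical genomes.

Group labels are made deterministic by ordering groups by (size descending,
then smallest member id), so any permutation of the input sequences yields
identical assignments — a property the test suite checks.

One subtlety worth knowing when validating against simulations: folding is
*supposed* to merge lineages one mutation apart. If two true founder
haplotypes differ by a single base, their clusters legitimately fold
together. Recovery checks against ground truth therefore use
strict-identity mode, where the identity partition equals the founder
partition exactly in noise-free data.

## Hierarchical AMOVA and Phi statistics

Colonies are nested in reefs, reefs in regions. With squared distances
$\delta^2_{ij}$, the sum of squares of a set $S$ is
$SS(S) = \frac{1}{|S|}\sum_{i<j \in S} \delta^2_{ij}$, and

$$SS_\text{within} = \sum_r SS(\text{reef } r), \quad
  SS_\text{reefs} = \sum_g SS(\text{region } g) - SS_\text{within}, \quad
  SS_\text{regions} = SS(\text{all}) - \sum_g SS(\text{region } g),$$

with $df = (R-1,\; P-R,\; N-P)$ for $R$ regions, $P$ reefs, $N$ colonies.
Variance components $(\sigma^2_a, \sigma^2_b, \sigma^2_c)$ come from the
expected mean squares with the standard unequal-sample-size coefficients

$$n_1 = \frac{N - \sum_g \frac{\sum_{i \in g} n_{ig}^2}{N_g}}{P - R},\quad
  n_2 = \frac{\sum_g \frac{\sum_{i\in g} n_{ig}^2}{N_g} - \frac{\sum n_{ig}^2}{N}}{R - 1},\quad
  n_3 = \frac{N - \frac{\sum_g N_g^2}{N}}{R - 1},$$

solved by back-substitution of
$E[MS_c] = \sigma^2_c$, $E[MS_b] = \sigma^2_c + n_1\sigma^2_b$,
$E[MS_a] = \sigma^2_c + n_2\sigma^2_b + n_3\sigma^2_a$. The test suite
confirms the solution against an independent brute-force least-squares
solve to 1e-10.

Fixation indices use the raw components
($\sigma^2_T = \sigma^2_a + \sigma^2_b + \sigma^2_c$):

$$\Phi_{RT} = \sigma^2_a / \sigma^2_T, \qquad
  \Phi_{PR} = \sigma^2_b / (\sigma^2_b + \sigma^2_c), \qquad
  \Phi_{ST} = (\sigma^2_a + \sigma^2_b) / \sigma^2_T.$$

Choices and edge cases:

* **$\delta^2 = d$, not $d^2$** (the haplotypic convention for sequence
  data, under which $\Phi_{ST}$ is the $F_{ST}$ analog). `distance =
  "squared"` switches to $d^2$ for sensitivity checks.
* **Negative component estimates are retained** in `$sigma` and in the Phi
  statistics — a slightly negative $\Phi_{PR}$ is informative — and
  truncated at zero only for the percent-of-total column, whose entries
  then sum to 100.
* **Two-level designs** (every region a single reef) have no among-reefs
  stratum: $\Phi_{PR}$ is `NA` and $\Phi_{ST} = \Phi_{RT}$.
* **No molecular variance at all** (all sequences identical) flags the
  result degenerate; components are zero and Phi is `NA`, never `NaN`.

Permutation p-values follow the scheme standard for nested sequence AMOVA:
$\Phi_{RT}$ permutes whole reefs among regions (preserving the number of
reefs per region), $\Phi_{PR}$ permutes colonies among reefs within their
region, $\Phi_{ST}$ permutes colonies among all reefs. Each p-value is
$(1 + \#\{\Phi^* \ge \Phi_\text{obs}\})/(B+1)$.

Per-haplogroup regional homogeneity uses a chi-square goodness-of-fit test
of each group's regional counts against expectation proportional to
regional sample sizes, Benjamini–Hochberg corrected across groups
(Bonferroni available); expected cells below 5 are flagged since small
groups make the asymptotic p coarse.

## The co-occurrence statistic and its constrained null

The centrepiece statistic counts, over every (group $g$, reef $r$) cell
with $k_{gr}$ members,

$$T = \sum_{g,r} \binom{k_{gr}}{2},$$

the number of unordered colony pairs that share both a haplogroup and a
reef. An alternative "instances" counting, $\sum_{g,r}\max(k_{gr}-1, 0)$,
is available behind a flag; pairs is the default. Folded members count
toward their group; ungrouped colonies contribute no pairs but *do* occupy
reef slots.

The null holds everything fixed except which colony sits on which reef:
each replicate applies a uniform random permutation of the observed
reef-label multiset to the colonies. The number of groups, the group-size
spectrum and the number of colonies per reef are thus conserved exactly;
only colony-reef pairing is randomized. One-tailed
$p = (1 + \#\{T^* \ge T_\text{obs}\})/(B+1)$, with the replicate trace,
null mean and SD, and seed stored in the result for exact
reproducibility. The same machinery drives the rare-group statistic: the
number of groups with 2–10 members (inclusive) that place at least two
members on one reef.

Because $T$ is integer-valued, the null is discrete: the permutation
p-value is conservative in the presence of ties, and extreme configurations
(e.g. perfectly separated reefs) can recur under permutation with small
probability, so "no permutation can match the observed value" holds only up
to that probability. Calibration was checked by simulation: under the
exchangeable null (retention 0, no regional weighting) the rejection rate
at $\alpha = 0.05$ over 200 datasets at the study's reef/group structure
falls inside the exact binomial band around 0.05.

`cooccurrence_report()` bundles the four tests of interest — full and
strict mode, pair count and rare-group count — with a deterministic seed
split.

## Reef-pair regressions

`reef_pair_table()` summarises every unordered reef pair: great-circle
distance (haversine, Earth radius 6371.0088 km) between mean colony
coordinates, mean cross-reef nucleotide distance, the fraction of
cross-reef colony pairs sharing a haplogroup (all cross pairs in the
denominator, including ungrouped colonies), the same fraction restricted
to rare groups, and the absolute heat-exposure difference.

`ibd_regression()` is ordinary least squares with intercept; it reports the
coefficient table, $R^2$, adjusted $R^2$ and the overall F-test p-value.
Reef-pair rows are not independent observations — each reef appears in
many pairs — so the default p-values inherit the usual caveat of
distance-matrix regressions; a Mantel-style permutation p (permuting reef
identities and rebuilding the response) is available via `mantel = TRUE`
for the overall fit. Zero-variance predictors error out; near-collinear
predictor sets trigger a condition-number warning.

## Molecular-rate arithmetic

Rates are interpreted as **pairwise** divergence accumulation by default:
a rate $r$ quoted in percent per million years converts to
$r/100/10^6$ per site per year, so over a genome of $L$ bases a mutation
is expected every $1/(L \cdot r_\text{site,year})$ years —
about 54,000 years for 18,642 bases at 0.1 %/Myr — and two clades
$p\%$ apart diverged $p/r$ million years ago (0.2 % at 0.1 %/Myr
$\to$ 2 Myr). The per-lineage convention (rate halved, wait time doubled,
divergence time halved) is available via `convention = "lineage"`; mixing
conventions is the classic error this flag exists to make explicit.

## The simulator

`simulate_reefs()` generates a reef metapopulation with known truth, so
every stage can be validated without any external download:

* **Founder haplotypes on a random genealogy.** Each new founder copies a
  random earlier one and gains $1 + \text{Poisson}(\lambda)$ mutations at
  *fresh* sites, guaranteeing pairwise-distinct founders; a divergent clade
  descends from an ancestor a configurable percentage (default 0.2 %)
  from the main stock. Founder frequencies come from a symmetric Dirichlet
  (concentration 0.4), giving a long-tailed class-size spectrum.
* **Placement with local retention.** Colonies fill reef slots in order;
  with probability $\rho$ a colony copies the haplotype of a uniformly
  chosen earlier colony on the *same* reef, otherwise it draws a founder
  from the frequency spectrum, with the divergent clade's frequency
  multiplied by a per-region weight. The copy-from-own-reef Bernoulli is
  the minimal mechanism that produces excess same-reef identity without
  creating regional haplotype clustering; an explicit larval-transport
  matrix is out of scope.
* **Noise.** Each transmitted haplotype mutates at one random site with
  probability 0.11 (producing the single-base "folded" variants), and
  uncalled bases are injected i.i.d. per site at rate 50/18,482.

Defaults emulate the study design this package targets: 7 regions, 39
patch reefs, 7 colonies per reef (273 colonies), 18,482 aligned bases, 45
founders of which 7 form the divergent clade, clade weights (1.5, 1.5,
0.15, …) concentrating it in two regions. Under these defaults the
realised datasets show a largest group around 50, roughly 20–30 groups,
about 25–30 folded and a handful of ungrouped colonies, and 110–140
variable sites — the right neighbourhood for a ~280-colony tabletop-coral
survey. The same seed and config reproduce the FASTA and metadata byte for
byte.

What the generator does **not** emulate: clustered missingness (real
uncalled bases concentrate in low-coverage tracts), recurrent mutation at
the same site, selection, within-reef spatial structure, or real
oceanography. Passing tests on synthetic data therefore demonstrate the
statistical machinery under a known-truth model, not the realism of that
model.

`truth_comparison()` scores an assignment against truth at the pair level
(precision and recall of group co-membership), invariant to any relabeling
of inferred groups.

## Problem sizes used by the checks

The packaged validation runs were sized to finish quickly on one CPU while
keeping the structure that matters at full scale: the null-calibration
study uses 200 datasets at the full reef/group structure with the genome
shortened to 4,000 bases (the pair-count statistic depends only on the
group-by-reef table, so genome length affects only runtime); the
retention-monotonicity study uses 200 datasets per retention level at a
reduced 12-reef configuration; oracle comparisons for the permutation null
enumerate all assignments for up to 8 colonies on up to 3 reefs at
B = 10,000.

## Known limitations

* The mitogenome is a single maternal marker: identical genomes bound, but
  do not prove, recent co-ancestry, and male-mediated gene flow is
  invisible. Conclusions about retention are qualitative.
* Pairwise-deletion distances can understate differences between genomes
  with heavy, overlapping missingness; the validation report surfaces
  per-genome uncalled counts so such data are visible before analysis.
* The AMOVA permutation schemes treat colonies (or reefs) as exchangeable
  units; strong within-reef family structure would violate that.
* P-values from reef-pair regressions treat pairs as independent; prefer
  the Mantel option when the decision hinges on significance.
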