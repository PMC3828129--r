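# foldage

Parsimony-based evolutionary ages of protein domain superfamilies, and the
fold-space preference analysis built on them.

## What this is for

A SCOP superfamily groups protein domains with a common evolutionary
origin. Its **occurrence profile** — a binary vector of presence/absence
across completely sequenced genomes — can be explained on a species tree by
scenarios of **gain** events (de novo emergence, lateral transfer, false
positive annotation) and **loss** events (true loss, false negative).
Maximum parsimony finds the scenario minimising

```
S = L + g · G
```

where `L` and `G` count losses and gains and `g` is the gain weight
(default 1: equal penalties). The **age** of the superfamily is the
normalized height of the oldest gain node in that scenario: 0 at the
leaves, 1 at the Archaea/Bacteria/Eukarya trifurcation (LUCA). *Ancient*
superfamilies have age exactly 1; *new-born* ones fall at or below a
cutoff. Contrasting the two populations — domain length, non-local
contacts and buried fraction normalised by the radius of gyration,
hydrophobicity, strand direction, disulphides, amino-acid propensities,
GO-term enrichment, greek key versus jelly roll sheet motifs — is the
analysis this package implements, for anyone studying how fold space has
been explored over evolutionary time.

The package provides, as tested library code:

- occurrence matrices, genome filtering, fold-level collapse, Jaccard and
  Bray–Curtis profile distances (`build_matrix`, `filter_genomes`,
  `collapse_to_fold`, `distance_matrix`);
- whole-genome trees: neighbour joining, delete-half jackknife with
  extended majority-rule consensus, Fitch–Margoliash least-squares and
  Wagner-parsimony (MPR-averaged) branch lengths, trifurcation/outgroup
  rooting, height normalization (`neighbor_joining`,
  `majority_rule_consensus`, `fit_branch_lengths_ls`,
  `parsimony_branch_lengths`, `root_tree`, `normalize_heights`);
- three age models with exact dynamic programmes and a controllable
  co-optimal tie-break (`mp_scenario`, `dollo_age`, `fusion_scenario`,
  `assign_age_groups`, `gain_weight_sweep`);
- structural descriptors and sheet-motif detection (`domain_descriptors`,
  `find_greek_keys`, `find_jelly_rolls`);
- tie-corrected Mann–Whitney (with exact permutation path),
  hypergeometric enrichment under Bonferroni, propensities, percentile
  curves, and the structure-versus-function contrast;
- a synthetic generator with known ground truth (`random_tree`,
  `simulate_profiles`, `synthetic_domain`, `synthetic_go`) and an
  end-to-end driver (`run_pipeline`).

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables under `results/`.

## Worked example

Simulate 500 superfamilies on a 12-genome tree with 10% branch loss, 1%
lateral transfer and 1% annotation noise, then date one of them:

```r
library(foldage)
tree <- random_tree(c(Archaea = 4, Bacteria = 4, Eukarya = 4), seed = 1)
sim  <- simulate_profiles(tree, n_units = 500, loss_rate = 0.1,
                          hgt_rate = 0.01, fp_rate = 0.01, fn_rate = 0.01,
                          seed = 1)
sim$matrix
#> occurrence_matrix: 500 superfamily units x 12 genomes (19.4% present)

unclass(sim$matrix)["sf0018", ]
#> arc_03 arc_01 arc_02 arc_04 bac_02 bac_01 bac_03 bac_04 euk_03 euk_02 euk_04 euk_01
#>      1      1      1      0      0      0      0      0      0      0      0      0

mp_scenario(tree, unclass(sim$matrix)["sf0018", ], g = 1)
#> mp parsimony scenario (g = 1): cost 2, age 0.7851
#>   gains at nodes {14}; losses at nodes {4}
```

The cheapest explanation is one gain at the archaeal ancestor (node 14,
normalized age 0.785) and one loss on the branch to `arc_04` — cost
`1 + 1·1 = 2`; the recorded true birth node of `sf0018` has age 0.7851,
so the estimate is exact here. Dating all 500 units and grouping them:

```r
ages <- vapply(rownames(sim$matrix), function(u)
  mp_scenario(tree, unclass(sim$matrix)[u, ])$age, 0)
table(assign_age_groups(ages, cutoff = 0.1)$group)
#> ancient  middle newborn
#>      17     222     261

cor(sim$truth$true_age, ages, method = "spearman")
#> [1] 0.8040367
```

Under these noise rates the estimated ages still rank the true birth
times with Spearman correlation 0.80. `run_pipeline(default_config(1))`
chains every stage (eight tree recipes, concordance matrix, descriptors,
enrichment) and prints a stage-by-stage report;
`analysis/01_simulate_inputs.R` through `analysis/05_statistics.R` do the
same as standalone scripts with TSV outputs.

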