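---
title: "Dating protein superfamilies by gain/loss parsimony: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating protein superfamilies by gain/loss parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldage)
```

## The problem

A protein superfamily groups domains that share a common evolutionary
origin. Whether a superfamily is present on a genome can be read off from
domain assignments to completely sequenced genomes; collapsing those
assignments over all genomes gives a binary *occurrence profile* per
superfamily. Given a species tree over the same genomes, the profile can be
explained by scenarios of **gain** events (de novo emergence, lateral
transfer, or a false-positive annotation) and **loss** events (true loss or
a false-negative annotation) on the tree's branches. The oldest gain in the
most parsimonious scenario dates the superfamily: its *age* is the
normalized height of that node, 0 at the leaves and 1 at the
Archaea/Bacteria/Eukarya trifurcation (the last universal common ancestor).
Ages then stratify superfamilies into *ancient* (age exactly 1), *new-born*
(age at or below a cutoff) and *middle* groups, whose structural,
sequence and functional properties can be contrasted.

This package implements that whole analysis at desk scale: occurrence
matrices and their dissimilarities, whole-genome tree construction, three
parsimony age models, structural descriptors of representative domains,
beta-sheet motif detection, and the statistics used for the group
contrasts. Because the real inputs are large database downloads, a
synthetic generator with known ground truth stands in for them; every
stage is exercised and tested against that truth.

## Age models

All three models are dynamic programmes over the two states
{absent, present} on a rooted, height-normalized tree. The lineage above
the root is taken to be absent, so presence at the root itself costs one
gain; this makes "age 1 = gained at the root" well defined and gives the
all-present profile the finite cost $g$.

**Maximum parsimony (MP).** Minimises $S = L + g\,G$ where $L$ and $G$
count loss and gain events and $g$ is the gain weight (default 1: equal
penalty for gain and loss). Transition costs are $g$ for
absent$\to$present, 1 for present$\to$absent, 0 otherwise; the optimum is
found by Sankoff-style dynamic programming.

**Dollo.** Exactly one gain, placed at the most recent common ancestor of
the present leaves, plus the minimal set of losses: the maximal absent
subtrees below that ancestor.

**Fusion.** MP everywhere except that at most one gain may occur inside
the Eukaryotic clade (Dollo behaviour there), reflecting the view that
eukaryotic domain repertoires grow mostly vertically. Implemented by
augmenting the DP state with the Eukaryotic gain budget (0 or 1).

**Tie-breaking.** Several scenarios can share the minimum cost, and they
need not agree on the age. The DP optimises lexicographically
(cost, then earliest-gain age) and by default returns the *oldest*
co-optimal dating; `tie_break = "youngest"` returns the youngest instead,
so the sensitivity of any downstream result to this choice is directly
measurable. Because a scenario's age is the maximum over its gain nodes,
and subtree choices are independent, per-child optimisation of the
subtree value is exact for both directions.

**Relations used as tests.** MP age never exceeds the Dollo age (a gain
above the presence-MRCA can always be moved down without raising the
cost). As $g \to \infty$ MP collapses onto Dollo; operationally the suite
uses $g$ greater than the number of tree edges, since that bounds any
possible loss count. (A weaker threshold — $g$ greater than the number of
present leaves — is *not* sufficient: with two presences whose MRCA is the
root and several absent subtrees below it, two leaf gains can stay cheaper
than one root gain plus its losses.) All scenario costs are verified
against exhaustive enumeration over all internal state assignments on
trees small enough to enumerate.

## Trees

Eight trees are built per genome set, mirroring the configuration count of
the original analysis: a backbone (taxonomy-style) topology with
Wagner-parsimony branch lengths at superfamily and fold level; NJ
jackknife-consensus trees for Jaccard and Bray-Curtis distances at both
levels; and a provided (parsimony) topology again with Wagner branch
lengths at both levels. Full parsimony topology *search* is out of scope —
any topology can be supplied as Newick.

- **Distances.** With $a$ = units on both genomes, $b$ and $c$ = units
  private to each: Jaccard $(b+c)/(a+b+c)$, Bray–Curtis $(b+c)/(2a+b+c)$.
  Units absent from both genomes are ignored. Bray–Curtis never exceeds
  Jaccard on the same counts.
- **NJ and consensus.** Standard neighbour joining (via `ape`), negative
  branch-length estimates clamped to 0. One hundred delete-half jackknife
  resamples *of the units* (not the genomes) feed an extended
  majority-rule consensus (via `phangorn::allCompat`), with per-split
  support reported.
- **Least-squares branch lengths.** Weighted least squares on the fixed
  consensus topology with Fitch–Margoliash weights $1/d_{ij}^2$ (pairs
  with $d_{ij}=0$ get the largest finite weight), solved on the unrooted
  topology (a degree-2 root would make its two edges unidentifiable) and
  clamped at 0.
- **Wagner branch lengths.** Per branch, the expected number of 0/1
  transitions averaged uniformly over *all* most-parsimonious
  reconstructions, computed exactly by inside–outside MPR counting and
  summed over units. Summed over branches this equals the total parsimony
  score — a conservation law the tests assert.
- **Rooting and ages.** Trees are rooted at the node joining the three
  superkingdom clades (error if any superkingdom is not monophyletic,
  naming the offenders) or on an outgroup's pendant edge. The published
  text normalises branch lengths root-to-leaves yet orients ages
  leaf-to-root without fixing the convention for non-ultrametric trees;
  we define a node's age as its maximum path length to a descendant leaf
  divided by the tree height. This pins every leaf to exactly 0 and the
  root to exactly 1, is invariant to uniform rescaling, and makes ages
  non-increasing along every root-to-leaf path. In the pipeline, jackknife
  noise can break superkingdom monophyly in a consensus tree; the run then
  falls back to rooting on an archaeal outgroup, as the original analysis
  did for its multicellular genome set.

## Statistics

- **Mann–Whitney with ties.** Ages are heavily tied (many units date to
  the same node), so the normal approximation uses midranks and the
  tie-corrected variance
  $\frac{n_1 n_2}{12}\bigl[(N+1) - \sum_j (t_j^3-t_j)/(N(N-1))\bigr]$,
  with a 0.5 continuity correction. For pooled sizes $N \le 12$ the exact
  permutation distribution is also enumerated, reporting both the raw
  exact p and the exact **mid-p** (half the point mass at the observed
  statistic). Under heavy ties the point mass is large, and the mid-p is
  the quantity a continuous approximation estimates; the suite asserts
  average agreement between the normal p and the exact mid-p at $N = 12$.
  Worst-case agreement at these sizes is a property of the normal
  approximation itself, not of any implementation, and is documented
  rather than asserted.
- **Enrichment.** One-sided hypergeometric upper tail $P(X \ge k)$ per
  (term, group), Bonferroni-corrected over the number of terms tested, as
  in the original analysis. The universe defaults to annotated
  superfamilies only and is an explicit argument, since the published
  text does not state the choice; terms never seen in the universe are
  skipped and logged. No ontology-graph propagation is performed —
  annotations are consumed as provided, with pre-propagated input
  accepted.
- **Propensities.** $P(a, G) = (n_{a,G}/N_G)/(n_a/N)$ with expectation 1;
  per-cell significance by a 1-df Pearson chi-square on the 2×2 table,
  Bonferroni over cells. For any partition into groups,
  $\sum_G (N_G/N) P(a,G) = 1$ per amino acid — asserted as a property.
- **Structure versus function.** Enriched-term lists are built for
  parallel and antiparallel superfamilies; ages are then compared three
  ways (by structural label; by functional annotation with overlaps
  counted; restricted to superfamilies unique to one side). On synthetic
  data where age depends only on the structural label, the structural
  Mann–Whitney deviate exceeds the functional one.

## Descriptors and motifs

Per representative domain: radius of gyration of the C$\alpha$ trace;
contacts (C$\alpha$ pairs within 8 Å) and non-local contacts
($|i-j| \ge 5$), normalised by $R_g$; buried fraction (relative exposure
below 7%, the JOY burial convention) normalised by $R_g$ (dividing the
raw count instead of the proportion is available by flag, since the
published formula is ambiguous on this point); mean hydrophobicity on the
Sweet–Eisenberg optimal matching hydrophobicity scale (any complete scale
may be substituted); strand-direction label (domains under 15% strand
content are not applicable; 70% of oriented strand residues calls a pure
direction, otherwise mixed); disulphide class per superfamily (*with* if
more than half the domains have a bond, *without* only if none do,
*ambiguous* otherwise and excluded from that contrast). Contact, burial
and direction thresholds are placeholders in the published text; the
defaults above are the conventional values from the contact-order and JOY
literature and are all configurable arguments. Superfamily summaries are
domain means, majority-vote strand labels (mixed on a tie), and the dual
disulphide criterion.

Sheet topologies (strand order along the chain, integer sheet slots,
pairing orientations) arrive as data — the PROMOTIF boundary. A **greek
key** is a window of four sequence-consecutive strands in one sheet whose
slot deltas match a signature from a configurable set, default
$\{(+3,-1,-1), (-3,+1,+1)\}$ (mirror-closed, so reversing the sheet
numbering changes nothing), with every spatially adjacent window pair
paired antiparallel. A **jelly roll** wraps a greek key with the strands
immediately preceding and following it in sequence, sitting at the two
outer slots and paired antiparallel. Superfamily sets follow the
any-domain rule for jelly rolls, and the greek key set excludes jelly-roll
members, so the two sets are disjoint by construction. The signature set
is data, not code, because the cited extraction method admits variants
(five-strand keys, mixed sheets); the defaults are deliberately
conservative.

## The synthetic generator

`random_tree()` draws three superkingdom clades under a trifurcating root
with exponential branch lengths (rate 1). `simulate_profiles()` gives each
unit a birth node (uniform over nodes by default, or branch-length
weighted with the root weighted by the mean branch length); presence
descends to all descendants; each branch below the birth loses the unit
with probability `loss_rate` (loss is absorbing — regain only by explicit
lateral transfer); branches outside the present clade acquire it with
probability `hgt_rate`; leaf states flip at `fp_rate`/`fn_rate`. Units
ending all-absent are re-drawn and counted, keeping the matrix aligned
with the truth table. Birth at a leaf is allowed (true age 0) since the
new-born class includes leaf-level origins. The default study conditions
are 12 genomes (4 per superkingdom), 200–500 units, loss 0.1, lateral
transfer and flip rates 0.01, seed 1 throughout; with all rates zero every
model recovers every true age exactly, with losses only the estimates are
never older than the truth, and under the default noise the rank
correlation between true and estimated ages is checked at the default
seed.

`synthetic_domain()` builds C$\alpha$ traces from a secondary-structure
plan: ideal helices (2.3 Å radius, 1.5 Å rise, 100° per residue),
near-extended zig-zag strands, random-walk coils; 3.8 Å virtual bonds
throughout, non-consecutive residues kept at least 3.5 Å apart, with
per-segment re-orientation and bounded whole-chain retries on a clash.
Exposures are sampled to hit a target buried fraction (default 0.3);
disulphides, when requested, mutate spatially proximal sequence-distant
residue pairs to cysteine. What the generator does *not* emulate: real
packing densities, sheet hydrogen-bond geometry, sequence–structure
correlation, or SCOP class frequencies. Passing tests therefore certify
the algebra and the algorithms, not biological realism of descriptor
distributions.

## Problem sizes and runtime choices

The test suite enumerates parsimony scenarios exhaustively on trees of 8–12
leaves (up to $2^{11}$ internal assignments), checks 240 (tree, profile,
gain-weight) instances against that oracle, 100 NJ recoveries, 500-unit
recovery simulations, 500 null replicates for the family-wise error of
Bonferroni-corrected enrichment (bounded by $0.05 + 2\sqrt{0.05\cdot
0.95/500}$), and 100 random rigid motions at $10^{-9}$ relative
tolerance. The end-to-end driver uses 200 units and 100 jackknife
replicates. These sizes keep every stage exact or well-powered while the
whole suite runs in well under a minute.

## Known limitations

- No likelihood or Bayesian gain/loss models; parsimony only, as in the
  analysis this package reproduces. Per-superfamily evolutionary models
  are out of scope.
- Parsimony *topology* search is not implemented; topologies come from NJ
  consensus or are supplied.
- Ages on a 12-leaf synthetic tree take few distinct values, so
  rank-based comparisons on synthetic runs are coarser than on the
  1,014-genome scale the method targets.
- The new-born cutoff is a configuration value (default 0.1), with an
  option that picks the cutoff equalising the new-born and ancient group
  sizes — the criterion by which the published cutoff was chosen; the
  printed value itself is not recoverable from the text.
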