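---
title: "Window-tree discordance and ancient introgression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-tree discordance and ancient introgression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topowindow)
```

## The problem

When closely related species radiate quickly, the genealogy of any one
genomic window need not match the species phylogeny. Two forces create this
discordance. **Incomplete lineage sorting (ILS)** — the retention of
ancestral polymorphism across short internodes — scatters discordant
topologies uniformly along the genome, because every window's genealogy is
an independent draw from the multispecies coalescent (MSC). **Introgression**
— hybridization followed by backcrossing — instead leaves *linked blocks*:
a donor haplotype enters the recipient genome in one piece, so many
consecutive windows share the same discordant topology and show a reduced
genetic distance to the donor.

`topowindow` implements the analysis that separates these two signatures in
a small focal taxon set: an outgroup, a two-taxon donor clade (the "steamer"
pair), two single lineages ("Baikal", "Shoveler"), and a recipient
("Pekin"). The pipeline classifies per-window trees into canonical rooted
topology classes, measures how strongly each class clusters into runs of
consecutive windows, computes ABBA-BABA D-statistics, tests candidate
regions for distance shifts by block permutation, and calls introgressed and
introgression-resistant regions.

## Topology classes

After pruning to the focal six taxa and rooting on the outgroup, a window
tree is reduced to a canonical string: children of every node are sorted by
the lexicographically smallest leaf label in their subtree and branch
lengths are stripped. Exhaustive enumeration with the donor pair constrained
as a clade and the outgroup fixed at the root yields exactly 15 classes
(four free ingroup units, (2·4−3)!! = 15). Three of them matter most:

* **t1** (species topology): (Baikal, Shoveler) joins the recipient, the
  donor clade outside.
* **t2** (introgression topology): the donor clade joins the recipient.
* **t3**: the donor clade joins (Baikal, Shoveler).

Trees that break the constrained donor pair fall outside the catalogue and
are tabulated as off-catalogue rather than forced into a class; trees that
are multifurcating on the focal set after pruning get the flag class
`"unresolved"`.

## The generative model

`sim_config()` states a six-taxon ultrametric species tree in coalescent
units (defaults: cherry nodes at 1, the recipient joins (Baikal, Shoveler)
at 3, the donor clade attaches at 4, root at 8). The focal internal branch
`T` (default 1) controls ILS: without gene flow each discordant rooted
resolution of the focal triplet has probability (1/3)e^−T — at `T = 1`,
about 0.1226 each. The introgression **pulse** reroutes the recipient
lineage into the donor ancestral population at the pulse time (default 2)
with probability γ (default 0.3), after which coalescence proceeds normally.
Both forces together reproduce the qualitative pattern the analysis targets:
an elevated t2 fraction that exceeds its ILS expectation, monotonically in
γ.

Linkage is modelled by a **geometric run-length layout**: a run length is
drawn with configurable mean (default 2 windows), one gene tree is
simulated, and all windows of the run share it. This is deliberately a
memoryless stand-in, not a sequential coalescent: the analysis consumes runs
of identical topologies, and the geometric generator is the simplest with a
controllable mean. What the generator does *not* emulate: recombination
breakpoint structure within windows, rate variation among sites or lineages,
base-composition heterogeneity, alignment error, and missing data. Green
tests therefore establish the correctness and calibration of the pipeline's
statistics on data satisfying MSC + pulse assumptions — not robustness to
real-data artefacts.

Planted truth comes in two forms. *Region* plants share one forced-pulse
gene tree across a run, with the reroute moved earlier (halfway between the
donor clade's MRCA and the pulse time) and the recipient-donor coalescence
compressed into a short span (default 0.2 units), yielding a long t2 run at
sharply reduced recipient-donor distance — the full introgressed-region
signature. *Shift* plants fill a stretch with independent forced-pulse trees
at ordinary pulse timing, the target for the permutation test. The truth set
records every plant.

## Quality filters

Windows are retained when they hold at least 30 informative columns (≥ 2
non-gap, non-N characters). The gap filter fails a window when gap
characters exceed 10% of all characters (strict `>`; the denominator is
taxa × columns, chosen for symmetry across taxa). The per-sequence
composition chi-square test compares each taxon's A/C/G/T counts with
expectations from the pooled alignment frequencies (df = 3, α = 0.05,
expected counts floored at 10⁻⁶ × sequence length); the window is discarded
when any sequence fails. The long-branch screen is a documented
simplification of specialised outlier-pruning tools: a tree is flagged when
any taxon's root-to-tip length exceeds 5× that taxon's median across trees,
with at least 20 trees required for a baseline.

4D-site extraction requires codon positions 1–2 to be ungapped, identical
across all taxa, and one of the eight fourfold-degenerate prefixes; this
strict-conservation convention is the common choice for concatenated
phylogenomics. Window trees are inferred internally by neighbor joining on
Jukes-Cantor distances over pairwise-complete columns — a stand-in for
external maximum-likelihood inference that closes the pipeline on synthetic
data; saturated pairs (p ≥ 3/4) receive a configurable distance cap (default
10) and flag the window, and negative NJ branch lengths are clamped to zero.

## Run statistics

Runs are maximal blocks of consecutive retained windows sharing one class,
computed on the ordinal window sequence (genomic gaps from filtered windows
are ignored, matching the definition that coordinate connectivity does not
matter); runs never cross chromosome boundaries, because genomic linkage
cannot. Under an i.i.d. null the expected fraction of class *c* in runs ≥ 2
is approximately 2f − f², so ~70% of a class with f ≈ 0.32 sitting in runs
is a dramatic excess — that contrast carries the introgression evidence.

## D-statistic

For an ordered quartet (P1, P2, P3, outgroup), D = (ΣABBA − ΣBABA) /
(ΣABBA + ΣBABA) over biallelic sites with the outgroup allele taken as
ancestral. The standard error is a delete-one-block jackknife in the Busing
weighted form. Because blocks are constructed with equal genomic size, the
default weighting is equal per block; weighting by per-block site totals is
available but anticonservative at desk scale, where block totals are
dominated by tree-level variance (a single deep-coalescing locus contributes
a burst of one pattern). For the same reason, Z is only approximately normal
when blocks average enough independent loci — with 50 blocks of 20 loci the
null Z has sd ≈ 1.00 in simulation; with 10 loci per block it is visibly
overdispersed (sd ≈ 1.1). The calibration experiments therefore use 50
equal-size blocks of 20 independent 10-kb loci.

## Permutation test

The observed mean of a per-window statistic (typically the path length from
the recipient-side MRCA to its joint MRCA with Baikal and Shoveler, which
introgression pushes deeper) is compared against means of contiguous blocks
of 295 windows drawn uniformly from the background of species-tree-consistent
window trees, 10,000 times. The p-value uses the add-one estimator
p = (1 + #{null ≥ obs}) / (1 + n_perm), so the smallest attainable value with
10,000 permutations is just under 10⁻⁴. The directional "increased"
alternative is the default, with `less` and `two.sided` options; the
background is sampled as contiguous blocks precisely to preserve its
autocorrelation under the null.

## Region calling

An introgressed call requires a run of the introgression class strictly
longer than 10 windows whose mean per-window recipient-donor distance falls
strictly below the genome-wide 1% quantile of all window distances; a
resistant call mirrors this with the species class, runs > 5, and the upper
1% quantile. Both thresholds are computed genome-wide (not per chromosome),
the plain reading of a "lowest 1%" criterion without a stratum. Where the
printed criteria are ambiguous between per-window and per-run quantiles, the
implementation computes per-window distances, takes run means, and requires
the run mean to beat the per-window quantile — both ingredients are exposed
so either reading can be audited. Strict inequalities are used throughout
(a run of exactly 10, or a mean exactly at the quantile, is not called), so
degenerate all-equal tracks produce zero calls. Adjacent qualifying runs
separated by a single non-qualifying window are deliberately not merged.

## Species tree

For ≤ 8 ingroup taxa the coalescent species tree is estimated exhaustively:
every rooted candidate topology is scored by the number of rooted triplets
it shares with the window trees, and the argmax wins (ties broken
lexicographically and reported). Rooted triplets rather than quartets are
used because all trees are outgroup-rooted — equivalent for ranking, and
simpler. The estimator is consistent under the MSC without gene flow; under
a strong pulse (γ = 0.45 with a short focal internode) it preferentially
returns the introgression topology — the caution that motivates checking
window support rather than trusting a single summary tree.

## Numerical and design choices

* Branch lengths serialise with up to 10 significant digits; comparisons
  use absolute tolerance 1e-9. Rooted/unrooted input for distance queries is
  immaterial: path lengths are rooting-invariant.
* Substitution model: Jukes-Cantor throughout (simulation and distance
  correction), θ = 0.002 substitutions/site per coalescent unit by default —
  a few percent root-depth divergence, typical for congeneric waterfowl.
  Repeated hits within one branch at one site collapse to a single change;
  at the default rates the bias is ≪ 1 standard error of any quantity
  tested.
* All randomness flows through R's RNG seeded once per configuration; equal
  configurations reproduce byte-identical datasets.
* Internal fast paths on the simulator's light tree representation
  (classification, tip distances) are cross-checked against the public
  phylo-based operations in the test suite.
* Simulation scales: acceptance-grade calibrations run at their stated
  sizes (10⁵ trees; 200 replicates per condition; 1,000 permutation
  repetitions). Supporting property tests of the same invariants run at
  reduced sizes (e.g. 3 × 10⁴ trees for closed-form checks at additional
  internode lengths) to keep the default suite within a practical budget.

## Known limitations

One unidirectional pulse only; no demographic change, selection, or
recombination-explicit simulation. The NJ stand-in underperforms ML on short
windows with low information — topology-recovery claims are therefore made
only on synthetic data where NJ accuracy is verified first (≥ 95% on 50-kb
windows at default rates). The composition test follows the pooled-frequency
convention of the tool it emulates, including the tested sequence in the
pool, which is slightly conservative. The exhaustive species-tree search is
factorial in the free lineage count and intentionally refuses large taxon
sets.
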