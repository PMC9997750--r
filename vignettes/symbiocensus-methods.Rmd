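---
title: "Methods: coverage-based symbiont census and transposase contact tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based symbiont census and transposase contact tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Many arthropods carry several maternally transmitted bacterial endosymbionts
at once — *Wolbachia*, *Cardinium*, '*Ca.* Tisiphia', *Rhabdochlamydia* and
relatives. Shotgun sequencing of single host individuals mixes host and
symbiont DNA in proportion to their genome copy numbers, so read depth is a
census instrument: the depth of each symbiont genome, calibrated against a
single-copy host gene, measures how many symbiont genomes are present per
host cell. symbiocensus implements that census together with the
comparative analyses that typically accompany it — pangenome partition,
ANI/AAI species delimitation, per-family transposase phylogenetics, and
fixed-variant density summaries — as a tested, seeded, desk-scale pipeline.

# Load estimation

## Model

For a sample with mean host-marker coverage $m$ (a single-copy gene such as
elongation factor 1-alpha) and symbiont median coverage $c$, the
**normalized abundance** is $a = c/m$ and the **per-host-cell load** is
$a/p$ where $p$ is the host chromosome number (2 for diploids). The median
is used on the symbiont side because bacterial genomes contain repeated and
horizontally mobile regions whose depth is inflated by multi-mapping; the
mean is used on the short host marker where no such structure exists.

Zero-depth positions are **included** in the median by default (the median
is taken across the whole genome); a covered-only mode is available via
`include_zero_depth = FALSE` for fragmented references. With an even number
of positions the median is the mean of the two central values.

## Cross-mapping and the accessory-gene restriction

When two co-infecting strains are near-identical (e.g. two *Wolbachia*
lineages at \>90 % ANI), reads from one strain also map to the other
wherever their genomes agree, inflating apparent coverage on shared genes.
If the shared fraction exceeds one half of genome positions, the
whole-genome median lands on the inflated depth and the load estimate
roughly doubles. The correction is to take the median only over each
strain's **accessory genes** — families present in exactly one strain of
the pair after removing proteins shorter than 100 aa. These sets are
computed from the pangenome stage, not hard-coded, because accessory gene
counts depend on the annotation at hand. An empty accessory set is an
error, not a fallback to the whole genome: the whole-genome estimator is
exactly the biased quantity the restriction exists to avoid.

## Presence calls and clustering

A symbiont is called present at a per-host-cell load of at least
`presence_threshold` (default 0.01) — far below biologically discussed
loads yet above the residue that cross-mapping noise leaves on absent
genomes. Samples are clustered by complete-linkage agglomeration on the
Euclidean distance between per-sample load vectors; the linkage is
configurable since only the distance is canonical (complete linkage is the
default of the `hclust` implementation this mirrors).

## A note on units

The generator draws symbiont depth at rate
$\textrm{load} \times m \times p$ and the marker track at rate
$m \times p$. Under the estimator above, the per-host-cell statistic then
has expectation $\textrm{load}/p$. The truth table therefore records both
scales explicitly (`true_abundance` and `true_load_per_cell`), and all
recovery tests compare the estimator with the truth on the estimator's own
scale. Users comparing across studies should be aware that "symbionts per
host cell" defined through division by chromosome number differs by the
factor $p$ from the normalized abundance.

# Pangenome and identity

## Ortholog families

Protein families are single-linkage clusters — connected components — of
the all-against-all blastp graph, keeping edges with e-value \< `1e-3`,
identity ≥ 35 % and ≥ 80 % coverage of both proteins. Single linkage is
deliberate: it reproduces the behaviour of de-novo family clustering tools
in this space, and its transitivity is exactly what the union-find oracle
in the tests checks. Family ids are the lexicographically smallest member,
so output is independent of edge order.

The ≥ 100 aa length filter is applied at **partition** time, not at
clustering time, so families may still be linked through short members;
"ghost" CDS fragments and transposase remnants are thereby excluded from
accessory-genome accounting without distorting family structure. Accessory
COG summaries count families by unambiguous single-letter category, pool
categories with ≤ 2 families into "Other categories", and track
unannotated families as "de novo OGs".

## ANI and AAI

ANI follows the fragment recipe: the query genome is cut into consecutive
1020-nt fragments, each aligned locally against the subject (blastn,
reward 1 / penalty −1, extended x-drop); fragments aligned at ≥ 30 %
identity over ≥ 70 % of their length contribute their identity, one-way ANI
is the mean, and the reported ANI averages the two directions. AAI is the
unweighted mean identity of reciprocal best blastp hits at ≥ 30 % identity
and ≥ 70 % coverage in both directions, undefined below 10 pairs. Both
genomes of a pair must clear 95 % on every *defined* metric for a
same-species call (strict ≥); when ANI and AAI would disagree near the
threshold the conjunction rules, a deliberate conservative choice.

# Transposase contact tracing

Shared transposase families — ortholog families whose members annotated as
transposases span ≥ 2 genomes — carry a historical signal: if two symbiont
lineages exchanged an insertion sequence recently, near-identical copies
sit in both genomes; if they merely co-resided long ago, each genome holds
its own clade and the two clades are sisters.

The per-family pipeline is: progressive multiple alignment → degradation
filter → trimming → Poisson-corrected distances → neighbor joining with
nonparametric bootstrap → classification.

* **Alignment.** k-mer distances feed a neighbor-joining guide tree;
  profiles are merged by affine-gap dynamic programming (BLOSUM62, open 11,
  extend 1) with **free terminal gaps**. The semi-global choice matters:
  with penalized end gaps, a truncated copy at moderate identity scores
  better scattered through the profile than cleanly offset, which would
  hide exactly the degradation the next step must see.
* **Degradation filter.** A member is removed iff it misses ≥ 15 % of the
  family-consensus columns contiguously at either terminus *and* is ≥ 90 %
  identical to its nearest neighbour over its aligned span — a truncated
  copy of an otherwise highly identical gene. Divergent full-length members
  are kept; they are informative, not degraded. This codifies a manual
  curation practice; both thresholds are configurable, and families
  reduced below 3 members are reported untestable rather than forced into
  a tree.
* **Trimming.** Columns with gap fraction \> 0.5 or normalized Shannon
  entropy (base 20) \> 0.6 are dropped; trimming is idempotent.
* **Distances and trees.** p-distances over mutually ungapped columns with
  the Poisson correction $d = -\ln(1-p)$, unbiased under the uniform
  site-independent substitution model the generator uses. Note the
  correction is convex, so near saturation corrected distances may
  violate the triangle inequality — one reason bootstrap support, not a
  single topology, backs each call. Neighbor joining breaks Q-criterion
  ties toward the lexicographically lowest label pair and clamps negative
  branch lengths to zero, shifting the deficit to the sister branch; on
  additive matrices it is exact, which the tests verify against a
  four-point-condition oracle. Externally computed trees (e.g.
  maximum-likelihood trees in Newick) can be fed to `classify_sharing()`
  unchanged; distance/NJ is used internally because the inferential
  target — sister clades versus near-zero cross-genome distances — is
  topological.
* **Classification.** `recent` iff the minimum cross-genome patristic
  distance is ≤ 0.02 substitutions/site (≈ 98 % identity; there is no
  canonical numeric criterion for "recent", so the threshold is explicit,
  configurable, and reported with every call). Otherwise `ancient_sister`
  iff each genome's members are monophyletic (singletons allowed) and the
  joining branch has bootstrap support ≥ 95; support is required only on
  the joining branch, not on every branch inside the clades. Everything
  else is `unresolved` — the honest label for weak support or
  intermingled topologies.

# Variant summaries

Downstream of an external caller (or the package's toy pileup caller on
synthetic base counts), samples are gated at median symbiont coverage ≥ 30
and by population exclusions (e.g. the population the references were
assembled from). Variants are kept iff their frequency equals 1 (within
1e-9) — fixed differences, not within-sample polymorphism — and they do
not overlap transposase or intron features, whose repetitive context makes
calls unreliable. The summary reports mutations/kb and variant-type
proportions per sample × genome, with cohort averages over both
sample × genome cells and samples, since either aggregation is defensible.
The toy caller reports a fixed SNP where the alternate fraction is ≥ 0.95
at depth ≥ 10; it exists so the filters can be exercised end to end on
synthetic data and is not a replacement for a production caller.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume, with
truth tables sufficient for every recovery test:

* **Genomes** of 50 kb with a pool of 200 gene families, 30 % core, the
  two designated sister strains sharing 80 % of their families at ≥ 99 %
  nucleotide identity, 10 % ghost CDS (proteins of 40–70 aa), a fraction
  of private families annotated as transposases, intron features, and a
  single-copy host marker gene. These sizes keep the full pipeline at
  seconds-to-minutes on one CPU while leaving every estimator in its
  asymptotic regime (50 kb medians, ≥ 70 accessory positions per strain).
* **Depth** is drawn per base as Poisson at rate
  load × marker-mean × ploidy, with cross-mapping modelled explicitly as
  an additional independent Poisson draw at the sister strain's rate on
  pair-shared genes, and the marker track at marker-mean × ploidy. The
  default cohort is 6 samples × 4 symbionts with loads spanning 0.1–5 at
  marker depth 30 — round values whose implied Poisson rates are integers,
  so the integer-valued median is not systematically biased by rounding.
* **Transposase histories**: `recent` families place a transferred copy at
  ≤ 1 substitution from its donor source, with both genomes' copies at
  burst-like 0.003 subs/site divergence (a recent transfer has had no time
  to diversify); `ancient` families diverge two per-genome clades by 0.3
  subs/site; `none` families stay in one genome. A configurable fraction
  of copies is truncated by 20–40 % at one terminus to exercise the
  degradation filter. Substitutions are uniform over the 20 amino acids and
  site-independent, matching the Poisson correction's assumptions.
* **Variants**: known counts of fixed variants inside and outside the
  excluded feature classes plus polymorphic variants at distinct positions;
  the true density is exactly (fixed variants outside excluded features) /
  (genome length / 1000). Base counts for the toy caller default to an
  error rate of 0 — read-level error modelling is outside the generator's
  scope.

What the generator does **not** emulate — and hence what passing recovery
tests do not certify on real data: read-level sequencing error and mapping
ambiguity (depth is simulated directly, not via reads), assembly artifacts,
GC-dependent coverage bias, intergenic homology between the sister strains
(their simulated intergenic DNA is independent, so fragment-based ANI
between simulated sisters is undefined even though their genes are
near-identical; ANI validation uses mutated-copy constructions instead),
compositional heterogeneity among amino-acid sites, and indel evolution
within transposase families.

Determinism: one root seed; each component draws from its own
deterministically derived child stream, so outputs are byte-identical
across runs and components are individually reproducible.

# Numerical and degenerate-input choices

* Median ties: mean of the two central values. Empty region unions,
  markers outside the reference, zero marker coverage, and empty accessory
  sets are errors, never silent fallbacks.
* All-gap or all-removed alignments error with advice to relax the trim
  thresholds; saturated p-distances (p ≥ 1) are an error in the main
  distance path and are capped only inside bootstrap replicates, where a
  saturated resample must not abort the support computation.
* Identity results are `NA` (undefined), not 0, when no ANI fragment or
  too few RBH pairs pass: 0 would be a claim, `NA` is an absence.
* The all-vs-all search refuses \> 5000 proteins unless the guard is
  raised, since the similarity stage is quadratic.

# Known limitations

* Distance/NJ trees stand in for maximum-likelihood inference; for
  families with strong rate heterogeneity an external ML tree should be
  imported into `classify_sharing()`.
* The degradation rule is a codification of manual curation, not its
  authors' intent; borderline pseudogenes near either threshold deserve
  inspection.
* Fragment ANI requires contiguous homology; on highly rearranged or
  gene-shuffled references AAI is the more robust metric, which is why the
  species call uses every defined metric rather than requiring ANI.
* The coverage-based census assumes symbiont genome copy number is the
  quantity of interest; polyploid host tissues or endoreduplication shift
  the marker calibration.
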