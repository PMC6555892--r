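---
title: "Seed-gene connector networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene connector networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minar)
```

## The problem

Common heritable disorders rarely trace back to a single gene. When a
handful of genes are already firmly established for a disease (or a family
of related diseases, such as the autoimmune disorders), the genes that
*physically connect* them in a molecular interaction network are promising
candidates for harbouring additional risk variants: network proximity
stands in for biological similarity. `minar` implements this idea as a
three-stage procedure — find the connecting subnetwork, show it is
non-random, and re-test the connector genes in GWAS data at a drastically
reduced multiple-testing cost (tens of SNPs rather than millions).

## The connector search

**Model.** The interactome is an undirected graph whose edges are labelled
`direct` (physical: binding, cleavage, phosphorylation) or `indirect`
(regulatory: activation, inhibition). Only direct edges are searched; the
action labels are annotation, not algorithm input. Gene symbols are matched
case-insensitively and stored uppercase.

**Objective.** Within a node budget `maxNodes` (default 35), include as
many seed genes as possible (primary criterion) through as few connector
genes as possible (secondary criterion), with the induced subgraph
connected. This is a node-weighted Steiner problem, NP-hard in general, so
the implementation is a deterministic greedy heuristic:

1. breadth-first distances are computed on the direct subgraph; the
   frontier is processed in sorted order and each newly reached node
   records its lexicographically smallest parent, so shortest paths are
   unique and reproducible;
2. starting from each seed in turn, the nearest unplaced seed is attached
   along its BFS path (a path may sweep up further seeds for free);
   seeds whose attachment would blow the budget are skipped in favour of
   cheaper ones;
3. connectors whose removal leaves the placed seeds connected are pruned,
   in lexicographic order, to a fixed point;
4. the best run wins under the ordering (more seeds, fewer connectors,
   lexicographically smaller member set). Components tied on seed count
   compete under the same ordering.

Ties are broken lexicographically at *every* choice point, so identical
inputs give bit-identical networks. The test suite checks the heuristic
against exhaustive search over all node subsets on 200 random graphs of 8
to 12 nodes; it attains the exact optimum on ≥ 95% of instances, and every
miss is a genuine greedy gap that the log reports.

**Padding.** Interactive pathway tools historically return fixed-size
networks. When the minimal connecting structure is smaller than the
budget, the remaining slots are filled with the highest-degree neighbours
of current members (ties lexicographic). Padding is on by default — a
saturated nine-seed run returns exactly 35 genes, i.e. 26 connectors — and
can be disabled (`pad = FALSE`) when only the minimal Steiner structure is
wanted, e.g. when reading connector genes as candidates.

**Unreachable and absent seeds.** Seeds missing from the interactome are
reported and excluded from the seed total used in scoring (silently
dropping them would inflate the enrichment). Seeds split across components
trigger a warning and the largest seed-holding component is used.
`rankNetworks()` repeats the search, retiring placed seeds and removing
used connectors from the working graph, and returns networks sorted by
score.

## The network score

The score asks: if `n` genes were drawn at random from the `N`-gene
interactome containing `K` seed genes, how often would they capture at
least the `k` seeds actually observed? That upper-tail hypergeometric
probability `p` gives `score = -log10(p)`; a score of 2 corresponds to a
1-in-100 chance. The universe is the loaded interactome, not the genome,
because that is the space the draw happens in.

The analytic score is complemented by an empirical permutation null:
random seed sets of the same size are drawn — uniformly, or stratified by
degree decile of the observed seeds (`degree_matched`, the default) — the
search is re-run, and the add-one estimator
`p_emp = (1 + #{score_perm ≥ score_obs}) / (n_perm + 1)` is reported.
Degree matching matters: random sets drawn uniformly tend to include hubs
and connect cheaply, so genuinely clustered but peripheral seeds can look
unremarkable against a uniform null while standing out clearly against a
degree-matched one.

**Calibration and its limits.** Under the null the add-one estimator is
valid (`P(p_emp ≤ t) ≤ t`) but *conservative* whenever the score
distribution has atoms, because ties count against the observation. The
score takes finitely many values (it depends only on network size and seed
capture), and on dense scale-free graphs the tie probability between two
random draws reaches 0.1–0.2, which visibly sub-uniformises the p-values.
The calibration experiment in the test suite therefore runs 200 replicate
experiments on sparse (attachment 1) interactomes of 201–400 genes with
six seeds each — conditions where network sizes, and hence scores, spread
over many values and each replicate has its own score support — and checks
the pooled p-values against U(0,1) with a Kolmogorov–Smirnov test at the
5% critical value. Users comparing very small, dense networks should
expect `p_emp` to err on the conservative side.

`annotationEnrichment()` provides the generic companion analysis (Fisher
one-sided tests per annotation term with Benjamini–Hochberg adjustment);
its results are entirely a function of the annotation map the user
supplies.

## The GWAS association layer

**Windows.** A SNP belongs to a gene if it lies on the same chromosome
within the gene body extended `windowKb` kb (default 100 kb, the
conventional cis-regulatory reach) either side, clipped at position 1. A
SNP in two overlapping windows counts for both genes. BED input (0-based
half-open) is converted to 1-based inclusive coordinates on read.

**Independent tests.** D′ is the normalised LD coefficient
`|D| / D_max ∈ [0, 1]`. SNPs are clustered by the transitive closure of
D′ ≥ 0.8 (connected components of the LD graph, threshold inclusive);
the component count is the Bonferroni denominator. Components were chosen
over greedy tagging because they are invariant to SNP input order. Pairs
absent from the LD table default to D′ = 0 (`missingAs = "zero"`); pass
`"error"` to insist on complete tables. The clustering is verified against
an independent component-counting oracle exhaustively over *all* LD graphs
of up to six SNPs.

**Per-gene summary.** For each gene: total SNPs, SNPs with raw p < 0.05,
independent-SNP count `m`, smallest raw p, and
`min(1, minPRaw × m)` as the corrected minimum. When any SNP has p < 0.05
this equals the corrected minimum over the p < 0.05 subset (the two
published descriptions coincide); when none does, the corrected value is
≥ 0.05 either way and the gene is not significant, so the simpler formula
is used throughout. P-values recorded as exactly 0 are floored at the
dataset's smallest positive value, with a warning, to keep the arithmetic
finite.

**Replication.** Candidate SNPs (those clearing the per-gene correction in
the primary dataset) are looked up in the secondary dataset and corrected
by the number of independent candidate SNPs carried forward; a SNP absent
from the second dataset is `"untested"`, not an error. A gene replicates
if any of its candidate SNPs does.

## The synthetic generator

`syntheticSpec()` fixes the study conditions the package is exercised
under; its defaults are: 400 genes, preferential-attachment background
with 2 edges per node (scale-free, hub-dominated, like real interactomes),
nine seeds, six planted connectors, 5% noise edges, eight SNPs per gene in
LD blocks of four at within-block D′ 0.9, and a causal p of 10⁻⁸ at the
index SNP of the causal gene's first block. Nine seeds mirrors the
motivating autoimmune-disease application; the remaining values are chosen
so the planted structure is recoverable but not trivial (noise edges can
and occasionally do reroute a shortest path around a planted connector).

Planted connectors form a path scaffold anchored to the background, and
seeds attach to connectors round-robin, so every planted connector is
load-bearing; the zero-noise limit is exactly recoverable and at default
noise the connector precision/recall across replicates exceeds 0.9.

Within an LD block, all SNPs share one p-value drawn from Uniform(0, 1).
Marginally every null SNP's p *is* uniform; the within-block dependence is
deliberate and mirrors what high within-block D′ implies. Had null
p-values been drawn independently per SNP, a gene's effective test count
would be its SNP count while the correction uses its (smaller) block
count, and the nominal 5% per-gene error rate — which the tests verify to
three binomial standard errors over 1000 simulated gene-tests — would be
violated by construction.

What the generator does *not* emulate: realistic human coordinates or
recombination maps (genes sit 400 kb apart on synthetic chromosomes so
windows never overlap), coalescent LD decay (the block model is the
minimal structure the association layer consumes), effect-size
distributions, or literature-curation biases of real interactomes.
Passing tests therefore demonstrate internal correctness and recoverable
ground truth, not field performance on any particular organism or cohort.

## End-to-end recovery and the role of replication

The full-pipeline test asks, over 100 seeded replicates: are all planted
connectors in the selected network, and is the causal gene — and only the
causal gene — flagged? With per-gene Bonferroni at 0.05, each null gene is
falsely flagged about 5% of the time *by construction*, so across ~15
candidate genes a primary-only analysis flags some null gene in roughly
half the replicates. Exactly-one-gene recovery is only achievable — and is
therefore defined — after the replication stage: a false positive must
survive two independent datasets, which drops its rate to a fraction of a
percent. This mirrors the method's own validate-then-replicate design and
is why the replication pass is part of the core pipeline rather than an
optional extra.

## Numerical and interface choices

- Thresholds are inclusive (D′ ≥ 0.8 clusters; corrected p < 0.05
  flags).
- The D′ threshold, window size, and node budget are parameters
  everywhere, with the published defaults.
- Unknown interaction kinds map to `indirect` with a warning — the
  conservative direction, since only direct edges are analysed.
- Duplicate edge-list lines collapse with provenance counts summed;
  duplicate LD pairs keep the maximum D′ (again conservative: fewer
  independent tests).
- GraphML export (via igraph) round-trips nodes, edges and seed/connector
  roles exactly and is the lossless interchange format; TSV/SIF carry the
  edge list.
- All randomness (generator, permutation null) flows from explicit integer
  seeds; reruns are bit-identical, which the pipeline test checks by
  hashing the run report.

## Problem sizes used in the test suite

Exhaustive oracle comparisons use graphs small enough to enumerate: all
node subsets of 8–12-node graphs for the search (200 instances), all LD
graphs on ≤ 6 SNPs (~34,000 graphs) for the clustering. Statistical
properties use 100–200 seeded replicates: 200 × 99 permutations for
calibration, 100 end-to-end replicates for recovery, 1000 gene-tests for
the null error rate. These sizes give binomial/KS resolution comfortably
finer than the margins being tested while keeping the whole suite quick to
run.

## Known limitations

- The connector search is a heuristic; on adversarial graphs it can return
  one more connector than optimal (observed in ~1% of small random
  instances).
- The enrichment score ignores *which* genes connect the seeds; two
  networks of equal size and seed capture score identically.
- The permutation p-value is conservative under heavy score ties (small
  dense graphs).
- Per-gene Bonferroni does not control the experiment-wide error rate
  across genes; that is what the replication stage is for.
- The package consumes summary statistics and precomputed (or
  haplotype-derived) LD; it performs no genotype QC or association testing
  from raw data.
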