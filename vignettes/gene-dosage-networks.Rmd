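---
title: "Gene dosage networks: from CNV cohorts to differential diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene dosage networks: from CNV cohorts to differential diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagenet)
```

## The problem

Copy-number variations (CNVs) — duplications and deletions of chromosomal
segments — are a first-tier diagnostic readout for neurodevelopmental
disorders. A cohort in which each participant carries one or more CNVs over
a curated panel of genes (for example, genes annotated to dopaminergic
neurotransmission) can be represented as a network: participants link to
the genes their CNVs cover, with a dosage sign (+1 duplication, −1
deletion), and genes link onward to the Gene Ontology (GO) terms describing
their function. `dosagenet` builds these networks, characterises their
topology, projects per-diagnosis similarity structure, and converts the
topology into signed feature vectors for a repeated Random-Forest
differential diagnosis between two clinical classes (canonically Autism
Spectrum Disorder, ASD, versus Developmental Delay, DD).

## The three networks

From a validated cohort (`cohort_dataset`), three undirected simple graphs
are built:

* **Gene dosage network** — participants × genes. One edge per distinct
  (participant, gene) pair; the edge sign is +1 if only duplications
  contributed, −1 if only deletions, and 0 (flagged `mixed`) when both
  occur over the same gene.
* **GO network** — participants × GO terms, obtained by replacing each
  gene with its annotated terms. The edge sign is the *sum* of the signs of
  the contributing gene links, so balanced dup/del contributions may cancel
  to 0.
* **Combined network** — the union of both edge classes plus unsigned
  gene–GO annotation edges.

Entities with no links are excluded from all graphs: by the cohort
selection rule every admitted participant carries at least one qualifying
CNV, so node counts describe connected entities only.

Two reporting conventions exist for the ratio measures of a summary table.
This package reports `⟨k⟩ = L/N` and `density = L/(N(N−1))` — the
convention under which the summary numbers of the cohorts this pipeline
targets are internally consistent — and also exposes the standard
undirected forms (`2L/N`, `2L/(N(N−1))`) in the same object. Diameter and
radius are computed on the largest connected component; on a disconnected
graph the eccentricities of smaller components are ignored, which is the
only way a finite diameter can be quoted at all.

## Degree distributions and the scale-free verdict

`degree_distribution()` tabulates the empirical degree mass;
`reference_curves()` fits the two reference models:

* Poisson, with rate λ equal to the empirical mean of the degree sequence
  (2L/N on a simple graph). The rate models the degree distribution
  itself, not the L/N reporting convention above.
* A discrete power law `p(k) ∝ k^(−γ)` with `k_min = 1`, fitted by
  maximum likelihood using the Riemann zeta normalisation; the standard
  error comes from the observed information (numerical second derivative
  of the negative log-likelihood).

`long_tail_verdict()` labels a network `scale_free_like` when the
power-law log-likelihood on the degree sequence exceeds the Poisson
log-likelihood, and `random_like` otherwise. This is a likelihood
comparison, not a formal goodness-of-fit test: no bootstrap p-value is
computed, and a `scale_free_like` verdict means "closer to a power law
than to a Poisson", nothing stronger. A sequence in which every node has
the same degree leaves γ unidentifiable; it is flagged degenerate and the
verdict falls back to `random_like` with a warning.

Hubs are ranked by `hub_report()` together with their average neighbour
degree: a value near 1 identifies a hub-and-spoke pattern (carriers touch
only that hub, so removing the hub shatters the network), while larger
values identify hubs embedded in subnetworks of co-occurring alterations.
Ties in degree are broken by node id so the ranking is total and
deterministic.

## Per-diagnosis similarity networks

The "generalized similarity" of two feature nodes (genes or GO terms) is
implemented as an explicit co-carrier projection: within one diagnosis,
two features are linked when at least `min_shared` participants carry
both, with the shared-carrier count and the Jaccard index of the two
carrier sets as edge weights. This is the transparent primitive underlying
similarity groupings produced by interactive network tools; published
network sizes obtained with such tools depend on unstated thresholds and
are therefore treated as qualitative, not exact, targets.

Communities are detected by seeded Louvain modularity optimisation on the
Jaccard weights (resolution 1 by default), and the modularity Q of the
returned partition is reported with it. Q is recomputed independently in
the test suite to guard the weighting conventions. An edgeless projection
degrades to singleton communities with Q = 0 and a warning. Gene networks
can be annotated with per-gene risk categories
(high_evidence / strong_candidate / suggestive / unscored).

## Signed importance features

The encoding that turns topology into feature vectors is deliberately
simple: the importance of a feature node is its degree divided by the
total link count of the network it belongs to, an exact ratio in (0, 1].
For each participant:

* **gene dataset** — value(p, g) = Σ over distinct signed links (p, g, s)
  of `s · importance(g)`;
* **GO dataset** — value(p, t) = Σ over the participant's signed gene
  links whose gene is annotated with t of `s · importance(t)`;
* **combined dataset** — gene columns as above but with importances from
  the combined network; GO columns use `s · (importance(g) +
  importance(t))`, so a term reached through an important gene carries
  more weight. The "+ gene importance" bonus is applied to GO columns
  only; applying it to gene columns as well is a defensible alternative
  reading, and the per-network importance tables make it a one-line
  change downstream.

The rule is additive throughout: a participant with both a duplication and
a deletion over the same gene contributes `+imp − imp = 0`. Columns that
are zero for every participant are dropped before classification to avoid
degenerate features. All three encoders are checked against brute-force
re-implementations on a worked five-participant fixture.

## The repeated classification experiment

`run_experiment()` repeats, under seeds derived from one master seed:

1. **balance** — the majority class is randomly downsampled to the
   minority size (balancing precedes the split, which is what makes the
   canonical 923+923 train / 395+395 test arithmetic come out of a
   1318/1327 cohort);
2. **split** — stratified 70/30, `round(0.7 · class size)` per class;
3. **select** — one Random Forest on all features, importances normalised
   to sum 1, features kept at importance ≥ 1e-3 (a single
   fit-then-threshold pass; no recursive elimination, since only a single
   threshold is part of the protocol). An empty selection falls back to
   the top 10 features with a warning;
4. **train and test** — a Random Forest on the selected features (100
   trees, Gini impurity, `sqrt(p)` features per split by default — the
   conventional defaults, exposed in `experiment_config()`), evaluated on
   the held-out test set.

Per repetition the confusion matrix (positive class ASD), train and test
accuracy, AUC from predicted class probabilities, and per-class
precision/recall/F1 are recorded; aggregates are means and *sample*
(n−1) standard deviations. The class balance is re-drawn every
repetition; fixing one balanced cohort for all repetitions would shrink
the spread of the counts slightly but not the means.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure this analysis
relies on, so the whole pipeline is testable without any data download:

* **hub genes** with Bernoulli attachment (default 3 hubs, attach
  probability 0.15) reproduce hub-and-spoke patterns: most carriers have
  no other links, so the hubs' average neighbour degree sits near 1.5;
* **gene blocks** (default four blocks of 20 genes and one of 42) are
  joined by a participant with a class-weighted probability; a joining
  participant links to a Poisson number of genes within the block,
  producing the subnetwork regime where hub neighbours have many links;
* **class profiles** weight block membership per diagnosis (the first
  class leans on the four small blocks, the second on the large one),
  giving class-conditional structure of realistic, imperfect strength;
* **GO annotation** is functionally coherent: each of the 110 terms draws
  `1 + Poisson(convergence_factor − 1)` genes preferentially from a single
  annotation pool (a block, the hub set, or the leftover genes), so the
  mean genes-per-term equals the convergence factor while terms inherit
  the block structure — the mechanism by which distinct genes converge on
  shared biology. Genes may remain unannotated, which exercises the
  warning path of the GO network builder;
* **dosage signs** are i.i.d. with duplication probability 0.5 (no
  empirical dup/del ratio is assumed);
* participants that would carry no CNV receive one link to a random hub,
  matching the selection rule that admitted participants carry at least
  one event.

The default scale is 1300 participants per class, 125 genes and 110 GO
terms; the test suite generates cohorts of about 100–400 participants per
class, which preserves every qualitative regime (hubs, blocks, heavy
tail) at a fraction of the cost, and the vignette-level scripts use the
full default scale.

`generate_separable_cohort(config, effect)` provides classifier ground
truth: four disjoint gene blocks reserved for the first class versus one
larger block for the second, with each participant joining exactly one
block drawn from a mixture between the class-specific and a shared
uniform distribution. At `effect = 0` labels are independent of links
(chance-level accuracy); at `effect = 1` the structure is fully
class-determined (near-perfect accuracy, and the per-class gene
similarity networks split into ≥4 versus exactly 1 connected components).
This generator plants no hub genes: hubs are carried by participants of
every block and would bridge the planted components, destroying the
ground truth the recovery tests rely on.

What the generator does **not** model: realistic genomic coordinates
(gene intervals are placed non-overlapping on one synthetic chromosome,
and each link becomes one CNV spanning exactly its gene), CNV length
distributions, linkage between neighbouring genes, ACMG classification,
or annotation depth differences between GO aspects. Passing tests
therefore demonstrate the correctness and statistical behaviour of the
pipeline under the assumed structure, not the clinical performance of the
classifier on real cohorts.

## Numerical choices and degenerate inputs

* Genomic coordinates are 0-based half-open internally; 1-based inclusive
  input is converted at the reader boundary. A CNV must overlap a gene by
  at least one base (configurable) to create a link.
* A participant listed with two diagnoses is rejected at load; cohorts are
  restricted to single-diagnosis participants.
* The power-law MLE is solved on γ ∈ [1.05, 20] by golden-section search;
  tolerances are the `stats::optimize()` defaults.
* Louvain community labels and hub rankings break ties by node id;
  connected components are numbered by their smallest node id.
* Sample (n−1) standard deviations everywhere; a single repetition
  reports sd = 0 rather than NA.
* All randomness (generation, balancing, splitting, forests, Louvain) is
  seeded; rerunning any pipeline stage with the same seeds is
  bit-identical.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_per_class = 400, seed = 1)
cohort <- generate_cohort(cfg)
g <- build_gene_dosage_network(cohort)
centrality_summary(g)
hub_report(g, 3)
long_tail_verdict(degree_distribution(g))

asd_sim <- project_similarity(g, "ASD", "gene")
detect_communities(asd_sim, seed = 1)$Q

fm <- gene_features(cohort, g)
run_experiment(fm, experiment_config(n_repetitions = 10, seed = 1))
```

## Limitations

* The similarity projection is a faithful but not byte-level replacement
  for interactive "generalized similarity" tools; exact published network
  sizes from such tools are not reproduction targets.
* The wrapper selection is single-pass; recursive elimination would give
  a different (usually smaller) feature count trajectory.
* Only degree-based importance is implemented, by design; betweenness or
  eigenvector alternatives are out of scope.
* Train accuracy is resubstitution accuracy, the convention of the
  scikit-learn-style protocol this mirrors; out-of-bag estimates read
  systematically lower and are not comparable.
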