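# dosagenet

Network analysis and machine-learning differential diagnosis for CNV
cohorts.

Participants carrying copy-number variations (CNVs — duplications or
deletions) over a curated gene panel can be represented as a tripartite
network: participants link to the genes their CNVs cover with a dosage
sign (+1 duplication, −1 deletion), and genes link to the Gene Ontology
(GO) terms describing their function. `dosagenet` implements, as a tested
and reusable pipeline, the analysis of such cohorts for two-class
differential diagnosis (canonically Autism Spectrum Disorder vs
Developmental Delay):

1. **Cohort ingestion** — four delimited tables (participants, CNVs,
   genes, gene→GO) validated and joined; CNV intervals mapped to genes by
   coordinate overlap (0-based half-open).
2. **Network construction** — the gene dosage network (participants ×
   genes, signed edges), the GO network (participants × terms, signs
   summed over contributing genes) and the combined network (both, plus
   unsigned gene–GO annotation edges).
3. **Topology** — centrality summaries (N, L, ⟨k⟩ = L/N, density,
   diameter, radius on the largest component), degree distributions
   contrasted with Poisson and discrete power-law `p(k) ∝ k^(−γ)` fits
   (maximum likelihood, `k_min = 1`), a scale-free-vs-random verdict by
   likelihood comparison, and hub reports with average neighbour degrees.
4. **Per-diagnosis similarity** — co-carrier projection of gene–gene and
   GO–GO similarity networks (shared-carrier counts and Jaccard weights),
   connected components, seeded Louvain communities with modularity Q,
   and gene-risk annotation.
5. **Feature engineering** — each participant becomes a signed vector:
   feature value = node importance (degree / total links of its network)
   × dosage sign, summed over contributing links; for the combined
   dataset a GO column adds the importance of the gene it is reached
   through.
6. **Classification** — repeated experiment: balance classes by
   downsampling, stratified 70/30 split, wrapper feature selection at
   normalized Random-Forest importance ≥ 1e-3, Random-Forest training,
   and aggregation (mean / sample sd) of confusion-matrix metrics, AUC
   and selected-feature counts.

A synthetic cohort generator (`generate_cohort()`,
`generate_separable_cohort()`) with planted hub and block structure makes
every stage testable without external data; see the methods vignette
(`vignettes/gene-dosage-networks.Rmd`) for the generative model and all
numerical conventions.

## Worked example

```r
library(dosagenet)

cfg    <- synthetic_config(n_per_class = 400, seed = 1)
cohort <- generate_cohort(cfg)
g      <- build_gene_dosage_network(cohort)

centrality_summary(g)
#> N=925  L=1406  <k>=1.520  density=0.00165  diameter=9  radius=5

hub_report(g, 3)
#>              node   label role degree avg_neighbor_degree
#> 1 ENSG00000000002 SYNG002 gene    261            1.616858
#> 2 ENSG00000000003 SYNG003 gene    242            1.537190
#> 3 ENSG00000000001 SYNG001 gene    231            1.536797

long_tail_verdict(degree_distribution(g))
#> [1] "scale_free_like"

asd <- project_similarity(g, "ASD", "gene")
detect_communities(asd, seed = 1)$Q
#> [1] 0.590

fm <- gene_features(cohort, g)
run_experiment(fm, experiment_config(n_repetitions = 10, seed = 1))
#> Random-Forest experiment [gene_dosage]: 10 repetition(s)
#>   positive class: ASD (negative: DD)
#>   test accuracy: 59.29% (sd 2.25%)  features: 115.1 (sd 2.5)
```

Reading the output: the gene dosage network has 925 connected entities
and 1406 signed links; its three hub genes each tie a few hundred
carriers whose average neighbour degree near 1.5 marks a hub-and-spoke
regime; the long-tail verdict says a power law explains the degree
sequence better than a Poisson; the ASD gene similarity network is
modular (Q = 0.59); and on this synthetic cohort — whose class signal is
deliberately mild — the repeated Random Forest reaches 59.3% test
accuracy using about 115 of 125 gene features.

To analyse a real cohort, load it with
`load_cohort(participants, cnvs, genes, gene_go)` and, if needed, restrict
it with `filter_diagnoses(cohort, c("ASD", "DD"))` before running the same
steps.

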