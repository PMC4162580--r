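# grnbench

Benchmarking de novo gene regulatory network reverse-engineering in
*Saccharomyces cerevisiae*, as a tested, reusable R pipeline.

## The problem

Reverse-engineering a transcriptional regulatory network from expression
data alone is attractive — observational microarray or RNA-seq data is cheap
— but it is hard to know how well any method actually does, because that
requires a genome-scale gold standard of *direct* regulatory interactions.
Perturbation data alone cannot provide one (a gene differentially expressed
after a TF deletion may be an indirect target), and ChIP binding data alone
cannot either (binding may be non-functional). This package implements the
benchmark design that intersects the two evidence types:

* **Regulatory network**: for each TF deletion mutant, genes called
  differentially expressed at 5% FDR (Benjamini–Hochberg per mutant
  profile), with the sign of the expression change.
* **Binding network**: ChIP interactions passing a binding p-value
  threshold and a binding-site conservation requirement, at three
  stringency levels — (0.001, 2 species), (0.005, 1), (0.005, 0) — giving
  three nested networks.
* **Gold standard** = regulatory ∩ binding: TF→gene pairs supported by both
  perturbation and physical evidence, with a hypergeometric test for the
  significance of the overlap.

Against these gold standards the package runs **18 statistical inference
approaches**: bivariate association screening and Generalized Local
Learning (GLL, local causal discovery with conditioning sets of up to 1–3
genes), each with Fisher's Z on continuous data or the G² test on
ternary-discretized data (standardize per gene; categories z < −1, −1 ≤ z ≤ 1,
z > 1), thresholded at 5% alpha or 5% per-gene FDR, and assembled
local-to-global with the AND rule (mutual neighbourhood membership) or the
OR rule (either membership). All approaches output undirected networks.

Accuracy is scored over the directed candidate universe (gold regulators ×
gold universe) with four core metrics — sensitivity, specificity, PPV
(precision), NPV — and three combined metrics, the Euclidean distance from
the ideal point for an antagonistic pair,

    d(m1, m2) = sqrt((1 − m1)² + (1 − m2)²)  ∈  [0, √2],

for sensitivity/specificity, PPV/NPV and recall/precision (smaller is
better). Per-network significance comes from an upper-tail hypergeometric
test, BH-adjusted over the whole grid of benchmark applications. Grid
results are summarized by a Pareto-frontier ROC curve with trapezoidal
AUROC (Hanley–McNeil significance), and by method/dataset/data-type average
tables. Finally, for every TF the package measures connectivity (degree in
the gold or inferred network) and sub-network reconstruction accuracy, and
tests their Spearman correlation with an exact permutation test (gene
labels shuffled on a fixed topology — TFs are not independent observations,
so an analytic null would be wrong).

Because the original 13 microarray datasets are external, the package
includes a first-class synthetic-data generator: a seeded linear-Gaussian
structural model over an acyclic, hub-heavy TF→gene network that emulates
all four study designs (wild-type replicates, environment/time series,
compendium, TF-knockout perturbation), the per-mutant differential
expression calls, and the nested binding networks. Every stage of the
pipeline is testable offline, end to end.

## A worked example

```r
library(grnbench)

# A 30-gene world with 5 TFs and a hub-heavy true network
net   <- generate_true_network(n_genes = 30, n_tfs = 5, mean_out_degree = 3, seed = 1)
world <- synthetic_world(net, noise_sd = 0.3, seed = 1)

# Gold standard: knockout DE calls intersected with conservative binding
de         <- simulate_mutant_pvalues(world, n_wt = 12, n_mut = 12, seed = 2)
regulatory <- build_regulatory_network(de, fdr_level = 0.05, universe = world$genes)
binding    <- simulate_binding(world, fnr = 0.1, fpr = 0.002, seed = 3)
gold       <- intersect_networks(regulatory, binding$conservative)
gold
#> Directed edge set: 7 edges, 4 regulators, 30 genes in universe

# Infer a network from perturbation-design expression data
expr     <- simulate_expression(world, "perturbation", n_samples = 60, seed = 4)
inferred <- run_approach(expr, inference_spec("fisher_z", 0, "fdr", "AND"))
inferred
#> Undirected network: 46 pairs over 30 genes

# Score it against the gold standard
cc <- confusion_counts(inferred, gold)
cc
#> Confusion: tp=6 fp=15 tn=94 fn=1 (universe 116: gold regulators x gold universe)
core_metrics(cc)
#> sens=0.857 spec=0.862 ppv=0.286 npv=0.989 | d_ss=0.198 d_pn=0.714 d_rp=0.728
network_significance(cc)
#> 0.000113
```

Six of the seven gold edges are recovered (sensitivity 0.857) at the cost
of 15 false pairs (precision 0.286, typical of association-based
screening); the hypergeometric p-value says the overlap with the gold
standard is far beyond chance. The TF connectivity analysis on the same
objects:

```r
connectivity_accuracy_correlation(inferred, gold, which = "inferred",
                                  metric = "d_pn", n_perm = 999, seed = 5)
#> Spearman rho = -0.400, permutation p = 0.245 (999 permutations, 4 TFs)
```

(negative: better-connected TFs tend to have more accurately learned
sub-networks, though 4 TFs give no power). `run_benchmark(read_run_config())`
runs the whole grid — 4 datasets × 18 approaches × 3 gold standards — and
writes every network, metric table, the Pareto-ROC summary and the
correlation count table as TSV; `inst/scripts/grnbench.R` exposes the same
stages as a command line (`simulate | build-gold | infer | evaluate |
subnet | all`).

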