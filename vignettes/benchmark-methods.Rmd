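---
title: "Methods: benchmarking regulatory-network reverse-engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking regulatory-network reverse-engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnbench)
```

This vignette is the package's own account of the models and procedures it
implements, the choices that were genuinely open, and what the synthetic
tests do and do not establish about real data.

## The gold-standard model

A *direct regulatory interaction* is a TF→gene pair supported by two
independent kinds of evidence. The regulatory side consumes per-mutant
differential-expression p-values: within each deletion mutant's profile,
`build_regulatory_network()` applies Benjamini–Hochberg step-up at the
requested FDR level (default 5%) and keeps survivors, signed by the
direction of the expression change with the deletion convention —
deleting an activator sends its targets *down*, so a negative change is
recorded as an excitatory (`+`) edge. BH is applied per mutant, not
globally: each mutant profile is its own family of hypotheses, and a mutant
full of null genes must not change another mutant's discoveries (this is
asserted in the tests). The binding side (`build_binding_network()`) keeps
pairs with binding p ≤ threshold and conservation count ≥ a minimum, with
the canonical stringency triples (0.001, 2), (0.005, 1), (0.005, 0)
producing nested networks by filter monotonicity. `intersect_networks()`
takes signs from the regulatory side (binding is direction-of-effect
blind), and intersects universes and regulator sets.

`overlap_significance()` is the upper-tail hypergeometric probability of
the observed overlap. The universe of candidate pairs is deliberately an
explicit argument: the natural choice — (TFs shared by both assays) ×
(shared genes − 1) — is a modelling decision, and published analyses often
leave it unstated, so the function refuses to guess. The tail is computed
in log space so that overlaps of genome-scale networks do not underflow.

## Conditional-independence tests

Two association tests drive all eighteen inference approaches.

**Fisher's Z** (`fisher_z_test()`): the partial correlation r of genes i, j
given a conditioning set S is read off the inverse of the sample
correlation matrix of {i, j} ∪ S; the statistic is
√(n − |S| − 3)·|atanh r| against the standard normal (two-sided). r is
clamped to |r| ≤ 1 − 10⁻⁷ before the transform so that numerically perfect
correlations (replicate pairs, tiny noise) give a large finite statistic
instead of ±∞. A singular submatrix — e.g. a constant gene — yields
`reliable = FALSE` and p = 1 rather than an error: in the local-learning
loop an unreliable test is simply forbidden from removing an edge.

**G²** (`g2_test()`): on ternary data (per-gene standardization with the
n − 1 sample standard deviation, categories z < −1 / [−1, 1] / z > 1,
boundaries in the middle category, constant genes wholly in the middle
category), the deviance 2·ΣO·ln(O/E) is summed over the 3×3 table of every
non-empty joint stratum of the conditioning genes, zero cells contributing
nothing. Two conventions had to be fixed because the field has no single
standard:

* degrees of freedom are 4 × (number of non-empty strata), *not* adjusted
  for zero margins — a simple rule that makes results bit-reproducible;
* the test is *unreliable* when n < 5 × 9 × (non-empty strata), the
  "five samples per cell on average" heuristic from the local-learning
  literature, and additionally whenever either tested gene occupies a
  single category. Unreliable tests never eliminate edges; at high
  conditioning orders this is what prevents vacuous independence calls.

Alternative zero-cell/df conventions would shift edge counts slightly;
that is why the convention is documented here rather than hidden.

## The eighteen approaches and the GLL loop

`inference_spec()` validates the approach grid: per test (Z or G²),
bivariate screening with FDR-AND, FDR-OR or plain alpha thresholding, and
GLL at conditioning depth 1–3 with AND or OR assembly — eighteen valid
configurations, enumerated by `benchmark_approaches()`.

Bivariate FDR is applied *per gene* across its m − 1 association p-values.
This is the reading under which the AND/OR post-processing listed for the
FDR variants is meaningful at all: per-gene thresholding is asymmetric
(gene a may retain b while b drops a), so a symmetrization rule is needed,
whereas the plain alpha rule is already symmetric.

`gll_neighbors()` implements interleaved inclusion/elimination in the
HITON-PC style. Candidates are ranked by unconditional association
strength (statistic descending, ties broken lexicographically — the
tie-break makes runs bit-reproducible); the best remaining candidate is
admitted, and every current member is then challenged against all subsets
of the other members up to size `max_k` (empty set included, smallest
first), leaving on the first reliable test with p above the alpha level.
"Conditioning on k genes" is read as subsets *up to* size k — the GLL
convention — not exactly k. Per-gene neighbourhoods are assembled with the
AND or OR rule.

Two properties of this algorithm matter for interpreting output and were
confirmed with an exact d-separation oracle plugged in as the CI test
(`gll_neighbors()` accepts any test function):

* a target's own output can contain non-adjacent genes — typically
  descendants — whose separating sets lie outside the target's
  neighbourhood. This is the classic local-search asymmetry, and it is the
  reason the AND rule exists: with a perfect oracle the AND-assembled
  skeleton is exactly the true skeleton, while per-gene outputs are only
  guaranteed to *contain* the true neighbours;
* on finite continuous data, exhaustive subset search can genuinely erase
  true edges: conditioning on a set containing a common child and a common
  parent can drive the *population* partial correlation of a directly
  connected pair arbitrarily close to zero, so some subset test reads
  independence no matter the sample size. Skeleton accuracy on data is
  therefore measured as per-pair agreement with the d-separation oracle
  (the test suite requires ≥ 95% over 100 seeded sparse 8-node worlds at
  n = 10⁴), not exact recovery.

## Scoring

`confusion_counts()` tallies tp/fp/tn/fn over the directed candidate
universe: every (TF, gene) pair with the TF among the gold standard's
regulators, gene in its universe, TF ≠ gene. An inferred unordered pair
{a, b} predicts a→b when a is a candidate regulator, and both directions
when both are; inferred pairs outside the universe are ignored, because
the inference methods are genome-wide and undirected while the gold
standard only covers assayed TFs. The universe is injectable
(`universe_spec`) because no published convention pins it down, and
headline metrics like NPV move substantially with the universe's density.
0/0 metrics are reported as `NA` with an explicit `undefined` flag, never
imputed; combined distances inherit the `NA`.

The combined metrics d = √((1−m1)² + (1−m2)²) compress an antagonistic
pair into distance-from-ideal (0 best, √2 worst). Table exports round to
two decimals; averages are computed on unrounded per-cell distances and
rounded last (for these tables the two orders agree at two decimals).

`pareto_roc()` retains points not dominated in (fpr, tpr), anchors at
(0,0) and (1,1), and integrates by trapezoid. Note one subtlety: with
trapezoidal interpolation, the frontier of a *subset* of points can have
slightly larger integral than the full frontier (removing an interior
frontier point straightens the curve), so the meaningful invariant —
asserted in the tests — is pointwise dominance of the frontier, not
monotonicity of the integral. AUROC significance uses the Hanley–McNeil
normal approximation with caller-supplied effective positive/negative
counts; it is an approximation adopted for want of a stated exact method.

## TF connectivity versus sub-network accuracy

For each gold TF, `tf_subnet_metrics()` restricts the confusion universe
to the TF's candidate row and recomputes all metrics; connectivity is the
TF's degree in the gold or the inferred network. The Spearman correlation
between the two across TFs is tested by an exact permutation test: gene
identifiers of the selected network are relabelled uniformly at random
with topology fixed, per-TF connectivity *and* accuracy are recomputed,
and the two-sided p-value is (1 + #{|ρ_perm| ≥ |ρ_obs|})/(n_perm + 1).
The add-one form avoids p = 0 (standard exact-test practice; the raw
proportion is the other defensible choice and differs by at most
1/(n_perm + 1)). A switch (`recompute_metrics = FALSE`) permutes only the
connectivity vector, for sensitivity analyses; the default recomputes,
reading "fixed network structure" as fixing topology while shuffling
identities. Constant connectivity or metric vectors make ρ undefined and
are reported as such with a reason, not coerced.

## The synthetic-data generator

`generate_true_network()` draws acyclic TF→gene networks with heavy-tailed
out-degrees: each of round(n_tfs × mean_out_degree) edges is assigned to a
TF with probability proportional to current out-degree + 1 (a Yule
process), producing hub TFs like those seen in curated regulatory
networks; targets are drawn uniformly among genes later in a fixed
ordering, which enforces acyclicity. Edge signs are Bernoulli(0.5) and
weights uniform on [0.5, 1.5] × sign — bounded away from zero so every
edge is in principle detectable.

`simulate_expression()` evaluates the linear-Gaussian structural model in
topological order. Parentless genes receive unit-variance exogenous input;
regulated genes receive N(0, noise_sd²) noise on top of their parents'
contribution. This split sets the scale of the system: with equal small
noise everywhere the roots would barely vary and nothing downstream would
be identifiable. `noise_sd` defaults to 0.3 in the pipeline configuration
— strong but not deterministic regulation; the oracle-agreement tests use
1.0 (unit noise, the standard linear-SEM benchmark regime) because
near-deterministic links degrade conditional-independence testing in ways
that are interesting but orthogonal to algorithmic correctness.

The four designs modify the model: `replicates` adds nothing;
`environment_time` feeds one sine period across the sample series into a
random half of the TFs (a smooth latent condition); `compendium` clamps
one random gene per sample to −3; `perturbation` cycles samples through TF
knockouts clamped to −3. Clamping to −3 on the standardized scale, rather
than deleting the row, keeps matrices rectangular the way real mutant
arrays are. Sample annotations record the perturbed gene but are never
shown to inference methods. `simulate_mutant_pvalues()` compares clamped
knockout replicates to one shared wild-type replicate set with Welch
t-tests — the shared reference mirrors common-reference array designs and
induces the same per-gene dependence across mutants that it does in real
compendia (the tests account for this when checking null uniformity).
`simulate_binding()` draws a per-pair score/conservation table such that
the three stringency filters reproduce the intended nesting, with missed
true edges (rate `fnr`) recorded at sub-threshold scores and false pairs
(rate `fpr`) with low conservation counts preferentially.

What the generator does *not* emulate: array-specific noise (dye bias,
probe effects, batch structure), non-linear or saturating regulation,
feedback loops (the truth is acyclic by construction), time-course
dynamics beyond the smooth latent signal, and the name-mapping mess of
real annotation. Passing tests therefore demonstrate that the pipeline's
statistics and algorithms do what they claim under the model they assume —
not that any approach will achieve a particular accuracy on real
microarray data.

## Problem sizes and reproducibility

Every operation takes an explicit seed and is bit-reproducible; the
pipeline driver derives stage seeds from the single configured seed, and
identical configurations produce byte-identical output files (asserted in
the tests). The test suite exercises: CI-test calibration on 1,000 null
simulations; GLL against a d-separation oracle on 100 seeded 8-node worlds
(exact with the oracle as CI test; ≥ 95% per-pair skeleton agreement at
n = 10⁴); hypergeometric p-values against brute-force enumeration for
universes ≤ 30; permutation-test floor and null uniformity; end-to-end
recovery of a noiseless 50-gene, 5-TF world; and the full 18-approach grid
on a 30-gene world. These sizes were chosen as the smallest at which each
property is statistically meaningful.

## Known limitations

* The default evaluation universe (gold regulators × gold universe) is one
  of several defensible choices; absolute PPV/NPV values shift with it,
  which is why it is injectable and why cross-study comparisons should fix
  it explicitly.
* The G² df/reliability conventions are fixed but not canonical.
* AUROC p-values are normal approximations.
* Inferred networks are undirected; edge orientation is out of scope.
* The permutation test relabels within the gold universe; TFs absent from
  the inferred data are treated as degree-0, which is conservative.
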