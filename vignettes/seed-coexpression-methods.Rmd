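---
title: "Seed-gene co-expression discovery and the broken-correlation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene co-expression discovery and the broken-correlation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigracoex)
```

## The scientific setting

In a degenerating brain region, genes that are co-regulated in health tend
to lose their co-expression in disease: a pair that is strongly correlated
across healthy samples and uncorrelated across patient samples is a
candidate marker of functional misregulation. `nigracoex` implements a
seed-centric version of this programme for bulk expression data, with the
substantia nigra (SN) and the alpha-synuclein gene *SNCA* as the motivating
use case:

1. correlate one **seed gene** against every other gene, per brain region;
2. keep the genes with **positive, family-wise-significant** co-expression
   that is **unique** to the target region (a Venn-style set difference);
3. enrich for the relevant cell type by intersecting with the
   co-expression sets of **marker genes** (e.g. the dopaminergic markers
   *TH* and *ALDH1A1*), and strip generic annotation categories;
4. test the surviving list for **term over-representation** and for
   **connectivity** on a protein–protein interaction (PPI) graph;
5. re-estimate the seed correlations separately in control and disease
   samples and classify each pair, with pairs that are significant in
   control but not in disease called **broken** — the broken-correlation
   index — optionally stratified over an ordinal disease-stage axis
   (Braak-style strata).

A companion module quantifies mitochondrial function from Seahorse Mito
Stress Test oxygen-consumption traces, and the corrected total cell
fluorescence (CTCF) readout used in densitometry, because the downstream
biology of such discovery lists is typically validated with exactly those
assays.

## Correlation core

For a seed vector $s$ and gene vector $g$ over $n$ samples of log2
expression values, the package computes the Pearson correlation $r$, the
statistic $t = r\sqrt{n-2}/\sqrt{1-r^2}$, and the two-sided p-value from
the $t$ distribution with $n-2$ degrees of freedom. Pearson (not Spearman)
is the default because expression is analysed on the log2 scale where
linear association is the conventional quantity; a rank-based alternative
sits behind `method = "spearman"`.

Family-wise control is Bonferroni: $p_{\mathrm{adj}} = \min(1, m\,p)$ with
$m$ the number of genes actually tested. Genes with constant expression
have no defined correlation; they are excluded from the table *and from
$m$*, since a test that cannot reject contributes nothing to the family.
A constant seed is an error. The seed is excluded from its own table
(self-correlation is trivially 1). Two-sided p-values plus the explicit
sign filter in `significant_positive()` reproduce "positive significant
co-expression" semantics without committing the test itself to one tail.

Missing values are rejected at load time by default because every formula
above assumes complete vectors; `allow_missing = TRUE` switches to
pairwise-complete observations, and the per-pair effective $n$ is then
carried through the t test, so p-values stay honest for genes with
different amounts of missingness.

### Why the t p-value is trustworthy at small n

The t-based p-value is checked against a permutation test (shuffling one
vector, $10^5$ draws) in the test suite. One subtlety matters: the
permutation null conditional on a single dataset is *discrete* — at
$n = 5$ it has at most $5! = 120$ support points — so on any one dataset
the two p-values legitimately differ by up to a granularity step, an
order of magnitude more than the Monte-Carlo standard error of the
permutation estimate. The meaningful statement is distributional: averaged
over Gaussian datasets, the mean difference between the t p-value and the
permutation p-value is statistically indistinguishable from zero at
$n \in \{5, 8, 15\}$. That is the form the test suite and the acceptance
script assert. As a point consistency check, two vectors with $r = 0.80$
exactly at $n = 8$ give a two-sided $p \approx 0.0171$, which rounds
compatibly with a printed $p = 0.016$ when $r$ itself is a rounded value.

## Set logic of discovery

`region_unique()` takes the per-region significant-positive sets and
returns the genes found only in the target region — the region-exclusive
segment of the Venn diagram. Uniqueness is deliberately defined against
the *significant* sets of the other regions, not against raw correlation
thresholds: a gene barely non-significant elsewhere still disqualifies,
which is the semantics of an exclusive Venn segment.

`marker_intersection()` then keeps genes co-expressed with every marker,
and `category_filter()` removes user-chosen annotation categories (e.g.
generic protein classes). The filter is annotation-agnostic — categories
arrive as an ordinary GMT file — because which classes count as "generic
cellular machinery" is a judgement about the data, not an algorithm. A
gene annotated to several removal categories is removed once but counted
under each, so the per-category log adds up to an auditable account.

## Over-representation

`hypergeom_enrich()` uses the exact hypergeometric upper tail
$P(X \ge k)$ for an overlap of $k$ query genes with a $K$-gene term in an
$N$-gene universe at query size $n$, with Benjamini–Hochberg adjustment
across terms. No normal approximation is involved; agreement with an
exhaustive enumeration over all $\binom{N}{n}$ query sets is asserted in
the tests for every configuration up to $N = 12$.

The default universe is the set of genes that survived correlation
testing, not all annotated genes: enrichment should be conditional on a
gene having been testable in the first place, otherwise the background is
biased toward well-measured genes. The universe is overridable for users
who prefer an annotation-wide background.

## The broken-correlation index

`delta_r()` estimates the seed–gene correlation separately in two
condition groups and reports $r_1$, $r_2$, $\Delta r = r_2 - r_1$, a
Fisher z test of $r_1 \ne r_2$,

$$ z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
            {\sqrt{1/(n_1-3) + 1/(n_2-3)}}, $$

and a four-way class from per-condition significance at `alpha`:
*maintained*, *broken* (significant in condition 1 only), *gained*,
*absent*. The class mirrors how broken correlations are called in
practice — significance in controls that disappears in disease — but that
call conflates statistical power with biology, which is why the effect
size and the formal z test are always reported alongside. Per-condition
p-values are raw, not family-wise adjusted: multiplicity was already paid
for at the discovery stage, and this module typically examines a handful
of pre-selected genes. Both choices are deliberate and documented rather
than configurable complexity.

`stage_profile()` repeats the per-stratum correlation along an ordinal
stage axis (factor levels define the order) and flags the earliest stage
at which significance is lost, where "lost" requires at least one earlier
significant stratum — a never-significant pair has nothing to lose.
Strata with fewer than 4 samples are reported as `absent` with a warning
instead of erroring, because real Braak strata can be that small (n = 5
is common); at such sizes the per-stratum test is underpowered, and the
tests of this behaviour therefore run at ~40 samples per stratum.

## PPI induced-edge enrichment

For a gene set mapped onto $k$ nodes of a graph with $N$ nodes and $M$
edges, the expected number of induced edges under uniform same-size node
sampling is $M\binom{k}{2}/\binom{N}{2}$ — the null behind the
"expected edges" figure STRING-style reports print. `edge_enrichment()`
estimates $P(\text{induced} \ge \text{observed})$ by permutation with the
add-one estimator $(1 + \#\{\text{hits}\})/(n_{\mathrm{perm}} + 1)$, which
cannot return an impossible zero; a Poisson upper tail with mean equal to
the expected count is reported as a cheap analytic approximation (checked
in the tests to track the permutation p within a factor of two on sparse
graphs — an approximation statement, not a guarantee). `exact_enrichment()`
enumerates all $\binom{N}{k}$ subsets (bounded at $10^6$) and is the
oracle the permutation estimate is tested against. The null is *not*
degree-preserving; a degree-aware null would answer a different question
(are these particular hubs connected?) and is left as future work. Query
genes absent from the graph are dropped from $k$ with a count, matching
mapped-node behaviour of the online tools. Edge lists are canonicalised
(self-loops and duplicate undirected pairs removed); a scoreless edge list
is treated as confidence 1.0 so a `min_score` filter (0.4 is the
conventional "medium confidence" cut) is a no-op on it.

## Bioenergetics

A Mito Stress trace has four phases — basal, oligomycin, FCCP,
rotenone/antimycin A — canonically three measurements each. The assay
vendors' de facto parameter definitions are adopted: non-mitochondrial
respiration is the *minimum* post-rotenone/antimycin value; basal
respiration is the *last* basal reading minus non-mitochondrial; proton
leak the *minimum* post-oligomycin minus non-mitochondrial; maximal the
*maximum* post-FCCP minus non-mitochondrial; ATP production the last
basal minus minimum post-oligomycin; spare capacity maximal minus basal;
coupling efficiency ATP/basal. Whether a given lab used last-basal or
mean-of-phase aggregation is often unstated, so `aggregate = "mean"`
provides the alternative; the canonical form is the default. The identity
$\text{basal} = \text{ATP} + \text{proton leak}$ holds exactly by
construction and is asserted on randomised traces. OCR values are
normalised to protein per well (units pmol O$_2$/min/µg); because all
parameters are linear in OCR, normalisation commutes with parameter
computation, which the tests verify. When basal respiration is
non-positive (a degenerate trace), coupling efficiency is undefined and
reported `NA` with a warning rather than a spurious ratio.

CTCF is the standard background correction:
$\mathrm{CTCF} = \text{integrated density} - \text{cell area} \times
\text{mean background fluorescence}$.

Group summaries stop at mean ± SEM with replicate counts; factorial ANOVA
on the parameters is routine statistics best left to general tools.

## The synthetic generator

`simulate_expression()` draws each group's module genes from an
equicorrelated single-factor model,
$x = \mu + \sigma(\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon)$, so any
two module genes correlate at exactly $\rho$ in expectation — a
closed-form ground truth that an arbitrary-covariance Cholesky
construction would not give so cheaply (generation is O(genes × samples)).
Defaults mirror a healthy multi-region brain design: three regions with
101/122/122 samples, a log2-like scale ($\mu = 8$, $\sigma = 1$), and one
SN-exclusive 50-gene module at $\rho = 0.75$ containing the seed and the
two marker genes. Condition- or stage-dependent breakdown is planted by
generating designated genes independently of the factor in designated
groups (`broken_pairs`, with `broken_from_stage()` to break a pair from an
ordinal stage onward, mirroring loss already at the earliest disease
stages). $\rho$ is restricted to $[0,1)$: the shared-factor construction
cannot realise negative equicorrelation across a module, and negative
planted modules are not a use case here.

What the generator does **not** emulate: microarray probe effects,
probe-to-gene collapsing, batch structure, heteroskedastic or heavy-tailed
noise, and correlated *background* genes. Green tests therefore certify
the algorithmic behaviour of the pipeline under a clean factor model, not
robustness to real-platform artefacts; counts published for specific
public accessions additionally depend on platform preprocessing and
annotation-database versions and are not reproduction targets.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run on
a laptop in well under a minute per stage: 20 replicates of the
2000-gene/3-region/100-samples-per-region discovery design, 100
replicates of the broken-pair design at 50 samples per condition, 2000
null replicates for Fisher-z calibration, $10^5$ permutation draws per
correlation dataset, and full enumeration oracles up to $N = 12$
(hypergeometric) and $\binom{N}{k} \le 10^6$ (network). All randomness
flows from a single integer seed; identical configurations and seeds
produce bit-identical matrices, intermediate gene sets and pipeline
manifests, which the determinism tests assert at the byte level.

## Known limitations

* Seed-centric only: no all-pairs differential co-expression or module
  preservation statistics.
* The broken/maintained classes inherit the power profile of the
  per-condition tests; at very small groups the class is noisy even
  though the Fisher z column is exact about its own uncertainty.
* The network null is uniform over node sets, not degree-preserving.
* The Spearman option combined with pairwise-complete missing data ranks
  each full vector once rather than re-ranking per pair.
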