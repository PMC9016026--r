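# nigracoex

Seed-gene co-expression discovery and broken-correlation analysis for
bulk brain expression data.

## The problem

Genes that act in the same pathway tend to be co-expressed, and in
neurodegenerative disease those normal co-expression patterns tend to
break down. For a gene of interest — a *seed* such as *SNCA* in the
Parkinson's substantia nigra (SN) — this yields a two-step discovery
programme: first find the genes whose co-expression with the seed is
specific to the affected region in healthy tissue, then ask which of
those correlations are *lost* in patients. A pair that is significantly
correlated in controls and uncorrelated in disease ("broken") is a
candidate marker of functional misregulation. `nigracoex` implements
this programme end to end for anyone working with genes × samples
expression matrices, plus the wet-lab quantifications usually used to
validate the resulting candidates (Seahorse Mito Stress respiratory
parameters and CTCF fluorescence densitometry).

## What it computes

* **Correlation profile** — for seed $s$ and every gene $g$ over $n$
  samples: Pearson $r$, $t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided $p$
  from $t_{n-2}$, and Bonferroni $p_{\mathrm{adj}} = \min(1, m\,p)$ over
  the $m$ genes with defined correlations
  (`seed_coexpression()`, `significant_positive()`,
  `strong_coexpression()`).
* **Discovery set logic** — region-unique Venn segment, marker-set
  intersection, annotation-category removal (`region_unique()`,
  `marker_intersection()`, `category_filter()`).
* **Over-representation** — exact hypergeometric upper tail
  $P(X \ge k)$ with Benjamini–Hochberg adjustment
  (`hypergeom_enrich()`, `bh_adjust()`).
* **Broken-correlation index** — per-condition $r_1, r_2$,
  $\Delta r = r_2 - r_1$, Fisher z test
  $z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/
  \sqrt{1/(n_1-3) + 1/(n_2-3)}$, and a
  maintained / broken / gained / absent class; ordinal-stage profiles
  with an earliest-loss flag (`delta_r()`, `fisher_z_test()`,
  `stage_profile()`).
* **PPI induced-edge enrichment** — observed vs expected
  $M\binom{k}{2}/\binom{N}{2}$ induced edges with permutation,
  exact-enumeration and Poisson-tail p-values (`edge_enrichment()`,
  `exact_enrichment()`, `induced_edges()`).
* **Bioenergetics** — Mito Stress respiratory parameters from
  phase-labelled OCR traces with protein normalisation, and
  CTCF = integrated density − area × background
  (`respiratory_parameters()`, `normalise_to_protein()`, `ctcf()`,
  `group_summary()`).
* **Synthetic data** — an equicorrelated factor-model generator that
  plants region-specific modules, marker membership and
  condition/stage-dependent correlation breakdown with full ground
  truth (`synthetic_config()`, `simulate_expression()`).
* **Pipeline** — `run_discovery()` chains the stages, writes every
  intermediate gene set, and records counts, parameters and input
  checksums in a flat manifest; `inst/cli/nigra-coex.R` exposes the
  stages as shell subcommands.

## Worked example

Plant an SN-specific 20-gene module at correlation 0.8 whose gene
`G0001` loses its seed correlation in disease, then run the two core
stages:

```r
library(nigracoex)
groups <- data.frame(
  label     = c("SN_ctrl", "hippocampus", "occipital", "SN_pd"),
  region    = c("SN", "hippocampus", "occipital", "SN"),
  condition = c("control", "control", "control", "PD"),
  n         = 60)
sim <- simulate_expression(synthetic_config(
  n_genes = 500, module_size = 20, rho = 0.8, groups = groups,
  broken_pairs = list(list(gene = "G0001", groups = "SN_pd")),
  rng_seed = 42))

ctrl_sn <- sim$metadata$region == "SN" & sim$metadata$condition == "control"
print(seed_coexpression(sim, "SNCA", samples = ctrl_sn), n_top = 5)
#> Seed co-expression profile: seed 'SNCA', 499 genes tested (pearson)
#> Top 5 by p-value:
#>   gene      r     t         p     p_adj  n
#>  G0017 0.9049 16.19 3.537e-23 1.765e-20 60
#>  G0003 0.8910 14.94 1.517e-21 7.570e-19 60
#>     TH 0.8902 14.88 1.848e-21 9.221e-19 60
#>  G0005 0.8799 14.11 2.113e-20 1.054e-17 60
#>  G0007 0.8784 14.00 2.972e-20 1.483e-17 60

in_sn <- sim$metadata$region == "SN"
sn <- list(expression = sim$expression[, in_sn],
           metadata   = sim$metadata[in_sn, ])
delta_r(sn, "SNCA", c("G0001", "G0002"), "control", "PD")
#> Differential co-expression with seed 'SNCA': control (n=60) vs PD (n=60), alpha = 0.05
#>   gene    r1       p1 n1     r2       p2 n2   delta    z   p_diff      class
#>  G0001 0.831 2.02e-16 60 -0.116 3.75e-01 60 -0.9477 6.99 2.77e-12     broken
#>  G0002 0.841 4.46e-17 60  0.800 1.68e-14 60 -0.0402 0.66 5.10e-01 maintained
```

`G0001` — planted to decorrelate in disease — is recovered as *broken*:
strongly correlated with the seed in controls ($r_1 = 0.83$,
$p = 2\times10^{-16}$), uncorrelated in disease ($r_2 = -0.12$, n.s.),
with the Fisher z test confirming the difference formally. `G0002`,
whose module membership is intact, is *maintained*.

The same machinery runs from the shell:

```sh
Rscript inst/cli/nigra-coex.R ppi-enrich --edges string_edges.tsv \
    --min-score 0.4 --genes candidates.txt --n-perm 10000 --seed 1
```

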