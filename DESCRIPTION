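Package: nigracoex
Title: Seed-Gene Co-Expression Discovery and Broken-Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for seed-gene co-expression analysis of brain expression
    data: Pearson correlation profiles of a seed gene against all other genes
    with exact small-sample p-values and Bonferroni family-wise control,
    region-unique co-expression discovery (Venn-style set logic with marker
    intersection and annotation-category filtering), hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction, Fisher-z
    comparison of correlations between disease conditions with a
    broken-correlation classification and Braak-stage stratification,
    induced-edge enrichment of gene sets on protein-protein interaction
    graphs, and Seahorse Mito Stress Test respiratory parameters with
    corrected total cell fluorescence. A synthetic-data generator plants
    known co-expression structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, tools, utils, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
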