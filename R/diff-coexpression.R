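#' Fisher z test for the difference of two correlations
#'
#' Tests `r1 != r2` for correlations estimated on independent groups of
#' sizes `n1` and `n2` via the variance-stabilising Fisher transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal tail p-value.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Group sample sizes, each greater than 3.
#' @return A list with elements `z` and `p`.
#' @examples
#' fisher_z_test(0.8, 8, 0.13, 15)
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1))
    coex_stop("nigracoex_degenerate",
              "|r| = 1: Fisher transform is infinite")
  if (any(c(n1, n2) <= 3))
    coex_stop("nigracoex_too_few_samples",
              "Fisher z variance undefined for n <= 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

classify_pair <- function(p1, p2, alpha) {
  s1 <- p1 < alpha
  s2 <- p2 < alpha
  if (s1 && s2) "maintained" else if (s1 && !s2) "broken"
  else if (!s1 && s2) "gained" else "absent"
}

#' Paired-condition seed-gene correlation comparison
#'
#' For each gene, correlates it with the seed separately within two
#' condition groups (e.g. control vs disease), reports the change
#' `delta = r2 - r1`, a Fisher z test of the difference, and a class based
#' on per-condition significance at `alpha` (raw, unadjusted p — the
#' family-wise control belongs to the discovery stage):
#' \describe{
#'   \item{maintained}{significant in both conditions}
#'   \item{broken}{significant in condition 1 only — the broken-correlation
#'     index of functional misregulation}
#'   \item{gained}{significant in condition 2 only}
#'   \item{absent}{significant in neither}
#' }
#' Significance loss alone conflates statistical power with biology, so the
#' effect size `delta` and the formal Fisher z p-value are reported
#' alongside the class.
#'
#' @param x A `coex_dataset` or a list with `expression` and `metadata`.
#' @param seed Seed gene identifier.
#' @param genes Genes to compare against the seed.
#' @param cond1,cond2 Condition labels (values of `condition_col`).
#' @param alpha Per-condition significance level.
#' @param condition_col Metadata column holding the condition labels.
#' @return A data frame of class `coex_delta` with columns `gene`, `r1`,
#'   `p1`, `n1`, `r2`, `p2`, `n2`, `delta`, `z`, `p_diff`, `class`, and
#'   attributes `seed`, `cond1`, `cond2`, `alpha`.
#' @export
delta_r <- function(x, seed, genes, cond1, cond2, alpha = 0.05,
                    condition_col = "condition") {
  assert_scalar_number(alpha, "alpha", 0, 1, open = TRUE)
  expr <- x$expression
  meta <- x$metadata
  if (is.null(expr) || is.null(meta))
    coex_stop("nigracoex_bad_argument",
              "`x` must carry `expression` and `metadata`")
  if (!condition_col %in% colnames(meta))
    coex_stop("nigracoex_bad_argument",
              sprintf("metadata has no '%s' column", condition_col))
  conds <- meta[[condition_col]]
  for (cond in c(cond1, cond2))
    if (!cond %in% conds)
      coex_stop("nigracoex_unknown_condition",
                sprintf("condition '%s' absent from metadata", cond))
  i1 <- which(conds == cond1)
  i2 <- which(conds == cond2)
  rows <- lapply(genes, function(g) {
    if (!g %in% rownames(expr))
      coex_stop("nigracoex_unknown_gene",
                sprintf("gene '%s' not in matrix", g))
    c1 <- cor_test_pair(expr[seed, i1], expr[g, i1])
    c2 <- cor_test_pair(expr[seed, i2], expr[g, i2])
    fz <- fisher_z_test(c1$r, c1$n, c2$r, c2$n)
    data.frame(gene = g, r1 = c1$r, p1 = c1$p, n1 = c1$n,
               r2 = c2$r, p2 = c2$p, n2 = c2$n,
               delta = c2$r - c1$r, z = fz$z, p_diff = fz$p,
               class = classify_pair(c1$p, c2$p, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, seed = seed, cond1 = cond1, cond2 = cond2, alpha = alpha,
            class = c("coex_delta", "data.frame"))
}

#' @export
print.coex_delta <- function(x, ...) {
  cat(sprintf(
    "Differential co-expression with seed '%s': %s (n=%d) vs %s (n=%d), alpha = %.3g\n",
    attr(x, "seed"), attr(x, "cond1"), if (nrow(x)) x$n1[1L] else NA,
    attr(x, "cond2"), if (nrow(x)) x$n2[1L] else NA, attr(x, "alpha")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Seed-gene correlation across ordinal disease stages
#'
#' Correlates a gene with the seed within each stage stratum (e.g.
#' controls, Braak 1/2, 3/4, 5/6), in the order given by the metadata's
#' ordinal coding (factor levels if `stage` is a factor, otherwise order of
#' appearance). Strata with fewer than 4 samples are reported as absent
#' with a warning rather than an error — real Braak strata can be this
#' small. The earliest stage at which significance (at `alpha`) is lost —
#' the first non-significant stage following a significant one — is
#' flagged in the `earliest_loss` attribute (`NA` if never lost).
#'
#' @param x A `coex_dataset` or list with `expression` and `metadata`.
#' @param seed Seed gene identifier.
#' @param gene Gene to profile against the seed.
#' @param stage_col Metadata column with the stage labels.
#' @param alpha Per-stage significance level.
#' @return A data frame of class `coex_stage_profile` with columns `stage`,
#'   `r`, `p`, `n`, `significant`, and attributes `seed`, `gene`, `alpha`,
#'   `earliest_loss`.
#' @export
stage_profile <- function(x, seed, gene, stage_col = "stage",
                          alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1, open = TRUE)
  expr <- x$expression
  meta <- x$metadata
  if (!stage_col %in% colnames(meta))
    coex_stop("nigracoex_no_stage_column",
              sprintf("metadata has no '%s' column", stage_col))
  stages <- meta[[stage_col]]
  keep <- !is.na(stages)
  levels_ord <- if (is.factor(stages)) levels(stages) else
    unique(as.character(stages[keep]))
  rows <- lapply(levels_ord, function(st) {
    idx <- which(keep & as.character(stages) == st)
    if (length(idx) < 4L) {
      warning(sprintf("stage '%s' has %d sample(s) (< 4): reported as absent",
                      st, length(idx)), call. = FALSE)
      return(data.frame(stage = st, r = NA_real_, p = NA_real_,
                        n = length(idx), significant = NA,
                        stringsAsFactors = FALSE))
    }
    ct <- cor_test_pair(expr[seed, idx], expr[gene, idx])
    data.frame(stage = st, r = ct$r, p = ct$p, n = ct$n,
               significant = ct$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # a "loss" needs an earlier significant stage: the paper's pattern is
  # significance in controls that disappears at some disease stage
  tested <- which(!is.na(out$significant))
  first_sig <- tested[out$significant[tested]][1L]
  loss <- if (is.na(first_sig)) integer() else
    tested[!out$significant[tested] & tested > first_sig]
  earliest_loss <- if (length(loss)) out$stage[loss[1L]] else NA_character_
  structure(out, seed = seed, gene = gene, alpha = alpha,
            earliest_loss = earliest_loss,
            class = c("coex_stage_profile", "data.frame"))
}

#' @export
print.coex_stage_profile <- function(x, ...) {
  cat(sprintf("Stage profile: %s vs %s (alpha = %.3g)\n",
              attr(x, "seed"), attr(x, "gene"), attr(x, "alpha")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 3)
  el <- attr(x, "earliest_loss")
  cat(if (is.na(el)) "Significance never lost across stages\n"
      else sprintf("Earliest loss of significance: stage '%s'\n", el))
  invisible(x)
}
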