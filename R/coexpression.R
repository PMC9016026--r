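# single-pair correlation with t-based p-value; pairwise-complete on NAs
cor_test_pair <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L)
    coex_stop("nigracoex_too_few_samples",
              sprintf("need at least 4 complete observations, got %d", n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    coex_stop("nigracoex_degenerate",
              "constant expression vector: correlation undefined")
  r <- stats::cor(x, y, method = method)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df = n - 2) else 0
  list(r = r, t = t, p = p, n = n)
}

#' Seed-gene correlation profile across all genes
#'
#' Correlates one seed gene against every other gene in the matrix over a
#' chosen sample subset: the correlation `r`, its t statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, the two-sided p-value from the t
#' distribution on `n - 2` degrees of freedom, and the Bonferroni-adjusted
#' p-value `min(1, m * p)` where the family size `m` counts the genes with
#' a defined correlation.
#'
#' Genes with constant expression over the subset have no defined
#' correlation; they are excluded from the table and from `m` (their ids
#' are kept in the `undefined_genes` attribute). A constant seed vector is
#' an error. The seed is excluded from its own table.
#'
#' @param x A `coex_dataset` from [read_expression()] /
#'   [simulate_expression()] output, or a numeric matrix with gene row
#'   names and sample column names.
#' @param seed Seed gene identifier (e.g. `"SNCA"`).
#' @param samples Optional character or logical vector selecting the sample
#'   subset (default: all samples); needs at least 4 samples.
#' @param method `"pearson"` (default; expression values are log2 scale, so
#'   linear correlation is the conventional choice) or `"spearman"`.
#' @return A data frame of class `coex_profile` with columns `gene`, `r`,
#'   `t`, `p`, `p_adj`, `n` and attributes `seed`, `m`, `method`,
#'   `undefined_genes`.
#' @examples
#' sim <- simulate_expression(synthetic_config(n_genes = 200,
#'                                             module_size = 20))
#' prof <- seed_coexpression(sim, "SNCA",
#'                           samples = sim$metadata$region == "SN")
#' head(as.data.frame(prof[order(prof$p), ]))
#' @export
seed_coexpression <- function(x, seed, samples = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- if (inherits(x, "coex_dataset") || is.list(x) && !is.matrix(x))
    x$expression else x
  if (!is.matrix(expr) || is.null(rownames(expr)))
    coex_stop("nigracoex_bad_argument",
              "`x` must be a coex_dataset or a matrix with gene row names")
  if (!seed %in% rownames(expr))
    coex_stop("nigracoex_unknown_gene",
              sprintf("seed gene '%s' not in matrix", seed))
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  if (ncol(expr) < 4L)
    coex_stop("nigracoex_too_few_samples",
              sprintf("need at least 4 samples, got %d", ncol(expr)))

  seed_v <- expr[seed, ]
  if (stats::sd(seed_v, na.rm = TRUE) == 0 || all(is.na(seed_v)))
    coex_stop("nigracoex_degenerate",
              sprintf("seed gene '%s' has constant expression: correlation undefined", seed))
  others <- expr[setdiff(rownames(expr), seed), , drop = FALSE]

  if (method == "spearman") {
    seed_u <- rank(seed_v, na.last = "keep")
    others_u <- t(apply(others, 1L, rank, na.last = "keep"))
  } else {
    seed_u <- seed_v
    others_u <- others
  }
  # constant genes yield NA correlations (flagged below); silence cor()'s
  # zero-sd warning for them
  has_na <- anyNA(expr)
  if (has_na) {
    r <- as.vector(suppressWarnings(
      stats::cor(seed_u, t(others_u), use = "pairwise.complete.obs")))
    n <- as.vector((!is.na(others)) %*% !is.na(seed_v))
  } else {
    r <- as.vector(suppressWarnings(stats::cor(seed_u, t(others_u))))
    n <- rep(ncol(expr), nrow(others))
  }
  undefined <- is.na(r) | n < 4L
  genes <- rownames(others)
  undefined_genes <- genes[undefined]
  genes <- genes[!undefined]
  r <- r[!undefined]; n <- n[!undefined]
  m <- length(genes)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df = n - 2), 0)
  out <- data.frame(gene = genes, r = r, t = tstat, p = p,
                    p_adj = pmin(1, m * p), n = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, seed = seed, m = m, method = method,
            undefined_genes = undefined_genes,
            class = c("coex_profile", "data.frame"))
}

#' @export
print.coex_profile <- function(x, n_top = 10L, ...) {
  cat(sprintf("Seed co-expression profile: seed '%s', %d genes tested (%s)\n",
              attr(x, "seed"), attr(x, "m"), attr(x, "method")))
  und <- attr(x, "undefined_genes")
  if (length(und))
    cat(sprintf("  %d gene(s) with undefined correlation excluded\n",
                length(und)))
  ord <- order(x$p, x$gene)
  cat(sprintf("Top %d by p-value:\n", min(n_top, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x)[ord, ], n_top),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.coex_profile <- function(object, alpha = 0.05, ...) {
  sp <- significant_positive(object, alpha)
  structure(list(seed = attr(object, "seed"), m = attr(object, "m"),
                 alpha = alpha, n_significant_positive = length(sp),
                 n_negative_significant =
                   sum(object$r < 0 & object$p_adj < alpha)),
            class = "summary.coex_profile")
}

#' @export
print.summary.coex_profile <- function(x, ...) {
  cat(sprintf(
    "Seed '%s': %d genes tested; at Bonferroni alpha %.3g: %d positive, %d negative\n",
    x$seed, x$m, x$alpha, x$n_significant_positive,
    x$n_negative_significant))
  invisible(x)
}

#' Positively co-expressed genes at family-wise significance
#'
#' Genes with `r > 0` and Bonferroni-adjusted p below `alpha` — the
#' "positive significant co-expression" set that feeds the region-unique
#' Venn comparison.
#'
#' @param profile A `coex_profile`.
#' @param alpha Family-wise significance level in (0, 1).
#' @return Character vector of gene identifiers.
#' @export
significant_positive <- function(profile, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1, open = TRUE)
  profile$gene[profile$r > 0 & profile$p_adj < alpha]
}

#' Strongly co-expressed genes
#'
#' Among the Bonferroni-significant positive set, the genes with
#' correlation above `r_min` (the conventional strong-co-expression cut is
#' `r > 0.7`).
#'
#' @param profile A `coex_profile`.
#' @param r_min Correlation threshold in \[0, 1).
#' @param alpha Family-wise significance level for the underlying
#'   significant set.
#' @return Character vector of gene identifiers.
#' @export
strong_coexpression <- function(profile, r_min = 0.7, alpha = 0.05) {
  assert_scalar_number(r_min, "r_min", 0, 1)
  profile$gene[profile$r > 0 & profile$p_adj < alpha & profile$r > r_min]
}
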