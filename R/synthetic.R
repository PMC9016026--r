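#' Configuration for the synthetic expression generator
#'
#' Describes a synthetic genes-by-samples study emulating a multi-region
#' brain expression dataset: several sample groups (each a combination of
#' region, condition and optionally Braak-stage stratum), one seed gene
#' carrying a planted co-expression module in a designated region, marker
#' genes belonging to that module, and designated seed-gene pairs whose
#' correlation is abolished in selected groups ("broken" pairs).
#'
#' Within a group, module genes are draws from an equicorrelated factor
#' model: each value is `base_mean + noise_sd * (sqrt(rho) * f +
#' sqrt(1 - rho) * e)` with a shared group-level latent factor `f` and
#' independent unit-variance noise `e`, so any two module genes have
#' correlation exactly `rho`. Genes outside the module (and module genes in
#' groups where their pair with the seed is broken) are independent
#' Gaussian draws.
#'
#' The defaults mirror the design of the healthy multi-region discovery
#' dataset: three regions (substantia nigra n = 101, hippocampus n = 122,
#' occipital cortex n = 122), a log2-like scale (`base_mean = 8`,
#' `noise_sd = 1`) and a substantia-nigra-exclusive module of 50 genes at
#' `rho = 0.75` containing the seed and the two dopaminergic markers.
#'
#' @param n_genes Total number of genes, including seed and markers.
#' @param groups Data frame with columns `label`, `region`, `condition`,
#'   optional `stage`, and `n` (samples per group, each at least 4).
#' @param seed_gene Identifier of the seed gene.
#' @param module_region Region whose groups carry the planted module.
#' @param module_size Number of genes in the planted module, counting the
#'   seed and the markers.
#' @param rho Within-module correlation, `|rho| < 1`.
#' @param markers Identifiers of the marker genes (members of the module).
#' @param broken_pairs List of `list(gene = , groups = )` entries: in the
#'   named groups, that gene is generated independently of the seed
#'   (correlation 0). Use `broken_from_stage()` to target every group at or
#'   beyond an ordinal stage.
#' @param noise_sd Standard deviation of a gene within a group.
#' @param base_mean Mean expression level (log2-like scale).
#' @param rng_seed Integer seed; identical configs and seeds yield
#'   bit-identical output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             groups = data.frame(
                               label = c("SN", "hippocampus", "occipital"),
                               region = c("SN", "hippocampus", "occipital"),
                               condition = "control",
                               n = c(101L, 122L, 122L),
                               stringsAsFactors = FALSE),
                             seed_gene = "SNCA",
                             module_region = "SN",
                             module_size = 50,
                             rho = 0.75,
                             markers = c("TH", "ALDH1A1"),
                             broken_pairs = list(),
                             noise_sd = 1,
                             base_mean = 8,
                             rng_seed = 1) {
  if (!all(c("label", "region", "condition", "n") %in% colnames(groups)))
    coex_stop("nigracoex_bad_argument",
              "`groups` needs columns label, region, condition, n")
  if (anyDuplicated(groups$label))
    coex_stop("nigracoex_bad_argument", "group labels must be unique")
  if (any(groups$n < 4L))
    coex_stop("nigracoex_bad_argument",
              "every group needs at least 4 samples (df >= 2 for a correlation)")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho >= 1)
    coex_stop("nigracoex_infeasible_rho",
              "`rho` must lie in [0, 1): the shared-factor construction cannot realise negative equicorrelation across a module")
  if (module_size > n_genes)
    coex_stop("nigracoex_bad_argument", "module_size exceeds n_genes")
  if (module_size < length(markers) + 2L)
    coex_stop("nigracoex_bad_argument",
              "module_size must cover the seed, the markers and at least one other gene")
  if (!module_region %in% groups$region)
    coex_stop("nigracoex_bad_argument",
              sprintf("module_region '%s' not present in `groups`", module_region))
  for (bp in broken_pairs) {
    if (is.null(bp$gene) || is.null(bp$groups))
      coex_stop("nigracoex_bad_argument",
                "each broken_pairs entry needs `gene` and `groups`")
    if (!all(bp$groups %in% groups$label))
      coex_stop("nigracoex_bad_argument",
                sprintf("broken pair for '%s' names unknown group(s)", bp$gene))
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 seed_gene = seed_gene, module_region = module_region,
                 module_size = as.integer(module_size), rho = rho,
                 markers = markers, broken_pairs = broken_pairs,
                 noise_sd = noise_sd, base_mean = base_mean,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Mark seed-gene pairs as broken from an ordinal stage onward
#'
#' Convenience constructor for `broken_pairs`: for each gene, the pair with
#' the seed is broken in every group whose `stage` is at or beyond
#' `from_stage` in the ordering of `stage_levels`.
#'
#' @param genes Character vector of genes whose seed correlation is lost.
#' @param groups The `groups` data frame of the configuration (must have a
#'   `stage` column).
#' @param from_stage Stage label at which the correlation is first lost.
#' @param stage_levels Ordinal ordering of the stage labels.
#' @return A `broken_pairs` list for [synthetic_config()].
#' @export
broken_from_stage <- function(genes, groups, from_stage,
                              stage_levels = unique(groups$stage)) {
  if (is.null(groups$stage))
    coex_stop("nigracoex_bad_argument", "`groups` has no stage column")
  ord <- match(groups$stage, stage_levels)
  cut <- match(from_stage, stage_levels)
  if (is.na(cut))
    coex_stop("nigracoex_bad_argument",
              sprintf("from_stage '%s' not in stage_levels", from_stage))
  hit <- groups$label[!is.na(ord) & ord >= cut]
  lapply(genes, function(g) list(gene = g, groups = hit))
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Draws an expression matrix, its sample metadata and the ground truth of
#' the planted structure from a [synthetic_config()]. See that help page
#' for the generative model.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `expression` (matrix, genes x samples),
#'   `metadata` (data frame: sample_id, group, region, condition, stage),
#'   `truth` (list: `module` genes per region, `markers`, `broken` — named
#'   list, per group, of genes whose seed pair is broken there) and
#'   `config`.
#' @examples
#' sim <- simulate_expression(synthetic_config(n_genes = 100, rng_seed = 7,
#'   module_size = 10))
#' cor(sim$expression["SNCA", sim$metadata$region == "SN"],
#'     sim$expression[sim$truth$module$SN[5], sim$metadata$region == "SN"])
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "synthetic_config"))
    coex_stop("nigracoex_bad_argument",
              "`config` must come from synthetic_config()")
  cfg <- config
  n_extra <- cfg$module_size - 1L - length(cfg$markers)
  background <- sprintf("G%04d", seq_len(cfg$n_genes - 1L - length(cfg$markers)))
  gene_ids <- c(cfg$seed_gene, cfg$markers, background)
  module <- c(cfg$seed_gene, cfg$markers, background[seq_len(n_extra)])

  broken_by_group <- stats::setNames(
    vector("list", nrow(cfg$groups)), cfg$groups$label)
  for (bp in cfg$broken_pairs)
    for (g in bp$groups)
      broken_by_group[[g]] <- c(broken_by_group[[g]], bp$gene)

  set.seed(cfg$rng_seed)
  mats <- vector("list", nrow(cfg$groups))
  meta <- vector("list", nrow(cfg$groups))
  for (gi in seq_len(nrow(cfg$groups))) {
    grp <- cfg$groups[gi, ]
    n <- as.integer(grp$n)
    in_module <- grp$region == cfg$module_region
    # fixed draw order (factor, then noise) keeps output reproducible
    f <- rnorm(n)
    eps <- matrix(rnorm(cfg$n_genes * n), nrow = cfg$n_genes,
                  dimnames = list(gene_ids, NULL))
    z <- eps
    if (in_module) {
      members <- setdiff(module, broken_by_group[[grp$label]])
      z[members, ] <- sqrt(cfg$rho) * rep(f, each = length(members)) +
        sqrt(1 - cfg$rho) * eps[members, , drop = FALSE]
    }
    mats[[gi]] <- cfg$base_mean + cfg$noise_sd * z
    meta[[gi]] <- data.frame(
      sample_id = sprintf("%s_%03d", grp$label, seq_len(n)),
      group = grp$label, region = grp$region, condition = grp$condition,
      stage = if ("stage" %in% colnames(cfg$groups)) grp$stage else NA,
      stringsAsFactors = FALSE)
  }
  expr <- do.call(cbind, mats)
  metadata <- do.call(rbind, meta)
  colnames(expr) <- metadata$sample_id

  truth <- list(
    module = stats::setNames(list(module), cfg$module_region),
    markers = cfg$markers,
    broken = lapply(broken_by_group, function(v) unique(v %||% character())))
  list(expression = expr, metadata = metadata, truth = truth, config = cfg)
}
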