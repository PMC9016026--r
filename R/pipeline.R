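#' Read a discovery-pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_discovery()] (`matrix_path`, `metadata_path`, `seed_gene`,
#'   `target_region`, `regions`, `markers`, `alpha`, `r_min`,
#'   `annotation_path`, `removal_terms`, `cond1`, `cond2`, `stage_col`,
#'   `out_dir`, ...).
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

write_gene_set_file <- function(genes, path) {
  writeLines(sort(genes), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the end-to-end seed-gene discovery pipeline
#'
#' Orchestrates the full discovery chain on one dataset:
#' \enumerate{
#'   \item seed-gene correlation profile per region, Bonferroni-corrected;
#'   \item genes with positive significant co-expression unique to the
#'     target region (Venn-style set difference);
#'   \item intersection with the marker genes' significant-positive sets
#'     in the target region;
#'   \item optional removal of annotation categories;
#'   \item optional term over-representation of the final list against the
#'     tested-gene universe;
#'   \item optional paired-condition comparison (`delta_r`) and stage
#'     profiling of the surviving genes.
#' }
#' Every intermediate gene set and table is written under `out_dir`, along
#' with a flat key-value `manifest.txt` recording parameters, input
#' checksums and stage counts, so each reported count is auditable and a
#' rerun with the same configuration is byte-identical.
#'
#' @param config Named list (see [read_pipeline_config()]). Either
#'   `matrix_path` + `metadata_path`, or a `dataset` element holding an
#'   in-memory `coex_dataset`-style list. Required: `seed_gene`,
#'   `target_region`. Optional with defaults: `regions` (all regions in
#'   the metadata), `markers` (character()), `alpha` (0.05), `r_min`
#'   (NULL: no strong-correlation cut), `annotation_path` /`annotation`,
#'   `removal_terms`, `cond1`/`cond2` + `condition_col`, `stage_col`,
#'   `discovery_condition` (restrict discovery samples to one condition),
#'   `out_dir` (required).
#' @return Invisibly, a list with the intermediate results (`profiles`,
#'   `region_sets`, `unique_set`, `marker_set`, `final_set`, `enrichment`,
#'   `delta`, `stage_profiles`) and the manifest path.
#' @export
run_discovery <- function(config) {
  cfg <- config
  for (key in c("seed_gene", "target_region", "out_dir"))
    if (is.null(cfg[[key]]))
      coex_stop("nigracoex_bad_argument",
                sprintf("config is missing '%s'", key))
  alpha <- cfg$alpha %||% 0.05
  assert_scalar_number(alpha, "alpha", 0, 1, open = TRUE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- c(stage = "config",
                seed_gene = cfg$seed_gene,
                target_region = cfg$target_region,
                alpha = format(alpha, digits = 15))
  checksums <- character()
  if (!is.null(cfg$matrix_path)) {
    dataset <- read_expression(cfg$matrix_path, cfg$metadata_path,
                               allow_missing = isTRUE(cfg$allow_missing))
    checksums <- c(checksums,
                   matrix_md5 = unname(tools::md5sum(cfg$matrix_path)),
                   metadata_md5 = unname(tools::md5sum(cfg$metadata_path)))
  } else if (!is.null(cfg$dataset)) {
    dataset <- cfg$dataset
  } else {
    coex_stop("nigracoex_bad_argument",
              "config needs matrix_path/metadata_path or a dataset")
  }
  meta <- dataset$metadata
  regions <- cfg$regions %||% unique(meta$region)
  if (!cfg$target_region %in% regions)
    coex_stop("nigracoex_unknown_region",
              sprintf("target region '%s' not among regions", cfg$target_region))

  discovery_keep <- if (!is.null(cfg$discovery_condition))
    meta$condition == cfg$discovery_condition else rep(TRUE, nrow(meta))

  # stage 1: per-region seed profiles and significant-positive sets
  profiles <- list()
  region_sets <- list()
  for (rg in regions) {
    samples <- meta$sample_id[meta$region == rg & discovery_keep]
    prof <- seed_coexpression(dataset, cfg$seed_gene, samples = samples)
    profiles[[rg]] <- prof
    region_sets[[rg]] <- significant_positive(prof, alpha)
    write_tsv(prof, file.path(out_dir, sprintf("profile_%s.tsv", rg)))
    manifest[sprintf("n_significant_positive_%s", rg)] <-
      length(region_sets[[rg]])
  }

  # stage 2: region-unique set
  unique_set <- region_unique(region_sets, cfg$target_region)
  write_gene_set_file(unique_set, file.path(out_dir, "region_unique.txt"))
  manifest["n_region_unique"] <- length(unique_set)

  # stage 3: marker intersection in the target region
  markers <- cfg$markers %||% character()
  current <- unique_set
  if (length(markers)) {
    target_samples <- meta$sample_id[meta$region == cfg$target_region &
                                       discovery_keep]
    marker_sets <- lapply(markers, function(mk)
      significant_positive(
        seed_coexpression(dataset, mk, samples = target_samples), alpha))
    names(marker_sets) <- markers
    current <- marker_intersection(current, marker_sets)
    write_gene_set_file(current,
                        file.path(out_dir, "marker_intersection.txt"))
  }
  manifest["n_marker_intersection"] <- length(current)
  marker_set <- current

  # stage 4: annotation-category removal
  annotation <- NULL
  if (!is.null(cfg$annotation_path)) {
    annotation <- read_gene_sets(cfg$annotation_path)
    checksums <- c(checksums,
                   annotation_md5 = unname(tools::md5sum(cfg$annotation_path)))
  } else if (!is.null(cfg$annotation)) {
    annotation <- cfg$annotation
  }
  if (!is.null(annotation) && length(cfg$removal_terms %||% character())) {
    current <- category_filter(current, annotation, cfg$removal_terms)
    rc <- attr(current, "removed_counts")
    for (term in names(rc))
      manifest[sprintf("n_removed_%s", term)] <- rc[[term]]
    write_gene_set_file(current, file.path(out_dir, "category_filtered.txt"))
  }
  final_set <- as.character(current)
  write_gene_set_file(final_set, file.path(out_dir, "final_set.txt"))
  manifest["n_final"] <- length(final_set)

  # stage 5: over-representation against the tested universe
  enrichment <- NULL
  if (!is.null(annotation) && length(final_set)) {
    universe <- profiles[[cfg$target_region]]$gene
    enrichment <- hypergeom_enrich(final_set, annotation, universe)
    write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    manifest["n_terms_tested"] <- nrow(enrichment)
  }

  # stage 6: differential co-expression across conditions / stages,
  # within the target region's samples
  in_target <- meta$region == cfg$target_region
  target_ds <- list(expression = dataset$expression[, in_target,
                                                    drop = FALSE],
                    metadata = meta[in_target, , drop = FALSE])
  delta <- NULL
  stage_profiles <- NULL
  if (!is.null(cfg$cond1) && !is.null(cfg$cond2) && length(final_set)) {
    delta <- delta_r(target_ds, cfg$seed_gene, final_set,
                     cfg$cond1, cfg$cond2, alpha = alpha,
                     condition_col = cfg$condition_col %||% "condition")
    write_tsv(delta, file.path(out_dir, "delta_r.tsv"))
    manifest["n_broken"] <- sum(delta$class == "broken")
  }
  if (!is.null(cfg$stage_col) &&
      (cfg$stage_col %in% colnames(meta)) && length(final_set)) {
    stage_profiles <- lapply(final_set, function(g)
      stage_profile(target_ds, cfg$seed_gene, g,
                    stage_col = cfg$stage_col, alpha = alpha))
    names(stage_profiles) <- final_set
    stage_tab <- do.call(rbind, lapply(final_set, function(g)
      cbind(gene = g, as.data.frame(stage_profiles[[g]]))))
    write_tsv(stage_tab, file.path(out_dir, "stage_profiles.tsv"))
  }

  manifest <- c(manifest, checksums)
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(sprintf("%s=%s", names(manifest), manifest), manifest_path)

  invisible(list(profiles = profiles, region_sets = region_sets,
                 unique_set = unique_set, marker_set = marker_set,
                 final_set = final_set, enrichment = enrichment,
                 delta = delta, stage_profiles = stage_profiles,
                 manifest_path = manifest_path))
}
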