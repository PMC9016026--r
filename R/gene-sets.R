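#' Genes unique to one region's co-expression set
#'
#' Given per-region sets of (typically significant-positive) co-expressed
#' genes, returns the genes present in the target region's set and in no
#' other region's set — the region-exclusive segment of the Venn diagram.
#'
#' @param sets Named list of character vectors, one per region.
#' @param target_region Name of the region of interest.
#' @return Character vector of genes unique to `target_region`.
#' @examples
#' region_unique(list(SN = c("g1", "g2", "g3"), Hip = "g2", OCTX = "g3"),
#'               "SN")
#' @export
region_unique <- function(sets, target_region) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    coex_stop("nigracoex_bad_argument",
              "`sets` must be a uniquely named list of gene sets")
  if (!target_region %in% names(sets))
    coex_stop("nigracoex_unknown_region",
              sprintf("region '%s' not among: %s", target_region,
                      paste(names(sets), collapse = ", ")))
  others <- unlist(sets[setdiff(names(sets), target_region)],
                   use.names = FALSE)
  setdiff(sets[[target_region]], others)
}

#' Intersect a gene set with marker co-expression sets
#'
#' Keeps the members of `target_set` present in every marker set — used to
#' enrich a discovery list for genes co-expressed with cell-type markers
#' (e.g. the dopaminergic markers TH and ALDH1A1).
#'
#' @param target_set Character vector of genes.
#' @param marker_sets Non-empty list of character vectors, one per marker.
#' @return Character vector: `target_set` restricted to genes in all marker
#'   sets.
#' @export
marker_intersection <- function(target_set, marker_sets) {
  if (!length(marker_sets))
    coex_stop("nigracoex_bad_argument", "need at least one marker set")
  Reduce(intersect, marker_sets, accumulate = FALSE, init = target_set)
}

#' Remove genes belonging to designated annotation categories
#'
#' Deletes from `genes` every gene annotated to any of the removal terms
#' (e.g. generic cellular-function protein classes); unannotated genes are
#' retained. Per-term removal counts are reported via `message()` and kept
#' in the `removed_counts` attribute; a gene in several removal terms is
#' removed once but counted under each term.
#'
#' @param genes Character vector of gene identifiers.
#' @param annotation A `gene_set_collection` mapping terms to member genes.
#' @param removal_terms Term identifiers to remove; must all exist in
#'   `annotation`.
#' @return Character vector of surviving genes, with attribute
#'   `removed_counts` (named integer vector, one entry per removal term).
#' @export
category_filter <- function(genes, annotation, removal_terms) {
  if (!inherits(annotation, "gene_set_collection"))
    coex_stop("nigracoex_bad_argument",
              "`annotation` must be a gene_set_collection")
  if (!length(removal_terms)) return(genes)
  unknown <- setdiff(removal_terms, names(annotation$sets))
  if (length(unknown))
    coex_stop("nigracoex_unknown_term",
              sprintf("removal term(s) not in annotation: %s",
                      paste(unknown, collapse = ", ")))
  removed_counts <- stats::setNames(integer(length(removal_terms)),
                                    removal_terms)
  drop <- character()
  for (term in removal_terms) {
    hit <- intersect(genes, annotation$sets[[term]])
    removed_counts[[term]] <- length(hit)
    drop <- union(drop, hit)
  }
  if (length(removal_terms))
    message(sprintf("category_filter: removed %d gene(s) [%s]",
                    length(drop),
                    paste(sprintf("%s: %d", names(removed_counts),
                                  removed_counts), collapse = ", ")))
  structure(setdiff(genes, drop), removed_counts = removed_counts)
}
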