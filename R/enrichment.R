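#' Hypergeometric over-representation of annotation terms
#'
#' Tests each annotation term for over-representation in a query gene set
#' relative to a gene universe, using the exact upper-tail hypergeometric
#' probability `P(X >= k)` where `k` is the query/term overlap, `K` the
#' term size in the universe, `n` the query size in the universe and `N`
#' the universe size. P-values are adjusted across all tested terms with
#' the Benjamini-Hochberg procedure.
#'
#' Query genes outside the universe are dropped (with a message); terms
#' with no universe member are not tested. A sensible universe is the set
#' of genes that actually entered correlation testing, so enrichment is
#' conditional on testability.
#'
#' @param query Character vector of query genes.
#' @param annotation A `gene_set_collection`.
#' @param universe Character vector: the gene universe.
#' @return A data frame of class `enrichment_result`, sorted by `p` then
#'   term id, with columns `term`, `name`, `N`, `K`, `n`, `k`, `p`,
#'   `p_adj`.
#' @examples
#' ann <- gene_set_collection(list(T1 = letters[1:5]))
#' hypergeom_enrich(letters[1:5], ann, letters[1:20])
#' @export
hypergeom_enrich <- function(query, annotation, universe) {
  if (!inherits(annotation, "gene_set_collection"))
    coex_stop("nigracoex_bad_argument",
              "`annotation` must be a gene_set_collection")
  universe <- unique(universe)
  if (!length(universe))
    coex_stop("nigracoex_empty_universe", "the gene universe is empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    message(sprintf("hypergeom_enrich: dropped %d query gene(s) outside the universe",
                    length(outside)))
  query <- intersect(query, universe)
  if (!length(query))
    coex_stop("nigracoex_empty_query",
              "no query genes remain after restriction to the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotation$sets), function(term) {
    members <- intersect(annotation$sets[[term]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    # exact upper tail: P(X >= k)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term,
               name = unname(annotation$term_names[term]),
               N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric())
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, n_top = 10L, ...) {
  cat(sprintf("Term over-representation: %d term(s) tested, universe N = %s, query n = %s\n",
              nrow(x), if (nrow(x)) x$N[1L] else "-",
              if (nrow(x)) x$n[1L] else "-"))
  print.data.frame(utils::head(as.data.frame(x), n_top),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values, with
#' monotonicity enforcement and capping at 1; the input order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0 | p > 1)))
    coex_stop("nigracoex_bad_argument", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
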