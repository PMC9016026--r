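# node universe of an edge list
edge_nodes <- function(edges) unique(c(edges$from, edges$to))

#' Count edges induced by a gene set
#'
#' Number of edges of the graph with both endpoints inside `gene_set`.
#' Genes absent from the graph simply cannot match an endpoint.
#'
#' @param edges An `edge_list` (see [read_edges()] / [edge_list()]).
#' @param gene_set Character vector of gene identifiers.
#' @return Integer edge count.
#' @export
induced_edges <- function(edges, gene_set) {
  sum(edges$from %in% gene_set & edges$to %in% gene_set)
}

new_network_enrichment <- function(k, N, M, observed, expected,
                                   p_perm = NA_real_, p_analytic = NA_real_,
                                   p_exact = NA_real_, n_perm = NA_integer_,
                                   n_unmapped = 0L) {
  structure(list(k = k, N = N, M = M, observed = observed,
                 expected = expected, p_perm = p_perm,
                 p_analytic = p_analytic, p_exact = p_exact,
                 n_perm = n_perm, n_unmapped = n_unmapped),
            class = "coex_network_enrichment")
}

#' @export
print.coex_network_enrichment <- function(x, ...) {
  cat(sprintf("PPI induced-edge enrichment: %d node(s) mapped of graph N = %d, M = %d\n",
              x$k, x$N, x$M))
  if (x$n_unmapped > 0)
    cat(sprintf("  (%d query gene(s) not in the graph, excluded)\n",
                x$n_unmapped))
  cat(sprintf("  observed = %d, expected = %.4g\n", x$observed, x$expected))
  if (!is.na(x$p_exact))
    cat(sprintf("  exact p (full enumeration)   = %.4g\n", x$p_exact))
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation p (%d perms)     = %.4g\n", x$n_perm,
                x$p_perm))
  if (!is.na(x$p_analytic))
    cat(sprintf("  Poisson-tail approximation p = %.4g\n", x$p_analytic))
  invisible(x)
}

# map a query onto the graph, with shared validation
map_gene_set <- function(edges, gene_set) {
  nodes <- edge_nodes(edges)
  gene_set <- unique(gene_set)
  mapped <- intersect(gene_set, nodes)
  list(nodes = nodes, mapped = mapped,
       n_unmapped = length(gene_set) - length(mapped))
}

#' Permutation enrichment of induced edges
#'
#' Is a gene set more internally connected in a protein-protein interaction
#' graph than a random node set of the same size? The expected induced-edge
#' count under uniform same-size node sampling is `M * C(k,2) / C(N,2)`
#' (the null STRING reports against). The permutation p-value uses the
#' add-one estimator `(1 + #{permutations with induced >= observed}) /
#' (n_perm + 1)`; a Poisson upper tail with mean equal to the expected
#' count is reported as an analytic approximation.
#'
#' Query genes absent from the graph are excluded from `k` (count kept in
#' the result), matching the mapped-node behaviour of STRING.
#'
#' @param edges An `edge_list`.
#' @param gene_set Character vector of query genes.
#' @param n_perm Number of random same-size node sets to draw.
#' @param rng_seed Optional integer seed for reproducible permutations.
#' @return A `coex_network_enrichment` with fields `k`, `N`, `M`,
#'   `observed`, `expected`, `p_perm`, `p_analytic`, `n_perm`,
#'   `n_unmapped`.
#' @export
edge_enrichment <- function(edges, gene_set, n_perm = 10000,
                            rng_seed = NULL) {
  if (n_perm < 1) coex_stop("nigracoex_bad_argument", "n_perm must be >= 1")
  gm <- map_gene_set(edges, gene_set)
  k <- length(gm$mapped)
  if (k < 2L)
    coex_stop("nigracoex_degenerate_set",
              sprintf("only %d query gene(s) map to the graph; need >= 2", k))
  N <- length(gm$nodes)
  M <- nrow(edges)
  observed <- induced_edges(edges, gm$mapped)
  expected <- M * choose(k, 2) / choose(N, 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  e1 <- match(edges$from, gm$nodes)
  e2 <- match(edges$to, gm$nodes)
  hits <- 0L
  sel <- logical(N)
  for (b in seq_len(n_perm)) {
    sel[] <- FALSE
    sel[sample.int(N, k)] <- TRUE
    if (sum(sel[e1] & sel[e2]) >= observed) hits <- hits + 1L
  }
  new_network_enrichment(
    k = k, N = N, M = M, observed = observed, expected = expected,
    p_perm = (1 + hits) / (n_perm + 1),
    p_analytic = stats::ppois(observed - 1L, lambda = expected,
                              lower.tail = FALSE),
    n_perm = as.integer(n_perm), n_unmapped = gm$n_unmapped)
}

#' Exact induced-edge enrichment by subset enumeration
#'
#' Enumerates every size-`k` node subset of the graph and reports the exact
#' probability that a uniformly drawn subset induces at least as many edges
#' as the query set. Feasible only while `C(N, k) <= 1e6`; intended as the
#' small-graph oracle for [edge_enrichment()].
#'
#' @inheritParams edge_enrichment
#' @return A `coex_network_enrichment` with `p_exact` filled in.
#' @export
exact_enrichment <- function(edges, gene_set) {
  gm <- map_gene_set(edges, gene_set)
  k <- length(gm$mapped)
  if (k < 2L)
    coex_stop("nigracoex_degenerate_set",
              sprintf("only %d query gene(s) map to the graph; need >= 2", k))
  N <- length(gm$nodes)
  if (choose(N, k) > 1e6)
    coex_stop("nigracoex_combinatorial_bound",
              sprintf("C(%d, %d) subsets exceed the 1e6 enumeration bound",
                      N, k))
  M <- nrow(edges)
  observed <- induced_edges(edges, gm$mapped)
  expected <- M * choose(k, 2) / choose(N, 2)
  e1 <- match(edges$from, gm$nodes)
  e2 <- match(edges$to, gm$nodes)
  subsets <- utils::combn(N, k)
  ge <- 0L
  sel <- logical(N)
  for (j in seq_len(ncol(subsets))) {
    sel[] <- FALSE
    sel[subsets[, j]] <- TRUE
    if (sum(sel[e1] & sel[e2]) >= observed) ge <- ge + 1L
  }
  new_network_enrichment(
    k = k, N = N, M = M, observed = observed, expected = expected,
    p_exact = ge / ncol(subsets), n_unmapped = gm$n_unmapped)
}
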