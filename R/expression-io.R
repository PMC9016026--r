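#' Read an expression matrix with sample metadata
#'
#' Loads a genes-by-samples matrix of log2 expression values from delimited
#' text (first column gene identifiers, header row sample identifiers)
#' together with a sample metadata table describing, for each sample, its
#' brain region, disease condition and (optionally) ordinal disease stage.
#'
#' The loader enforces the invariants the downstream correlation analyses
#' rely on: identifiers are unique and matched exactly (case-sensitively),
#' every sample in the matrix has a metadata row, and all values are finite.
#' Missing values are rejected unless `allow_missing = TRUE`, in which case
#' they are kept as `NA` and correlations downstream use pairwise-complete
#' observations, recording the effective n per pair.
#'
#' @param matrix_path Path to the expression matrix (`.tsv` or `.csv`;
#'   delimiter auto-detected from the extension, overridable via `sep`).
#' @param metadata_path Path to the sample metadata table. Must contain a
#'   `sample_id` column; `region`, `condition` and `stage` columns are used
#'   by the pipeline when present.
#' @param sep Field delimiter override applied to both files.
#' @param allow_missing Keep `NA` cells instead of rejecting them.
#' @return A list of class `coex_dataset` with elements `expression`
#'   (numeric matrix, genes in rows) and `metadata` (data frame, one row per
#'   sample, in matrix column order).
#' @examples
#' sim <- simulate_expression(synthetic_config(n_genes = 20,
#'   groups = data.frame(label = "SN", region = "SN", condition = "control",
#'                       n = 10),
#'   module_size = 5, rng_seed = 1))
#' d <- tempfile(fileext = ".tsv"); m <- tempfile(fileext = ".tsv")
#' write_expression(sim$expression, d)
#' write.table(sim$metadata, m, sep = "\t", row.names = FALSE, quote = FALSE)
#' ds <- read_expression(d, m)
#' dim(ds$expression)
#' @export
read_expression <- function(matrix_path, metadata_path, sep = NULL,
                            allow_missing = FALSE) {
  msep <- detect_sep(matrix_path, sep)
  raw <- utils::read.table(matrix_path, header = TRUE, sep = msep,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    coex_stop("nigracoex_parse_error",
              sprintf("expression matrix '%s' has no sample columns",
                      matrix_path))
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    coex_stop("nigracoex_duplicate_id",
              sprintf("duplicate gene identifier(s): %s",
                      paste(unique(gene_ids[duplicated(gene_ids)]),
                            collapse = ", ")))
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    coex_stop("nigracoex_duplicate_id",
              sprintf("duplicate sample identifier(s): %s",
                      paste(unique(sample_ids[duplicated(sample_ids)]),
                            collapse = ", ")))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- is.na(vals) & !is.na(cells) & cells != "NA" & cells != ""
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    coex_stop("nigracoex_non_numeric",
              sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                      cells[bad][1L], gene_ids[idx[1L]], sample_ids[idx[2L]]))
  }
  if (!allow_missing && anyNA(vals))
    coex_stop("nigracoex_missing_values",
              "expression matrix contains missing values; pass allow_missing = TRUE for pairwise-complete handling")
  if (any(is.infinite(vals)))
    coex_stop("nigracoex_non_finite",
              "expression matrix contains non-finite values")
  dimnames(vals) <- list(gene_ids, sample_ids)

  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = detect_sep(metadata_path, sep),
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  if (!"sample_id" %in% colnames(meta))
    coex_stop("nigracoex_parse_error",
              "metadata table has no 'sample_id' column")
  if (anyDuplicated(meta$sample_id))
    coex_stop("nigracoex_duplicate_id",
              "duplicate sample_id in metadata")
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta))
    coex_stop("nigracoex_metadata_mismatch",
              sprintf("samples present in matrix but absent from metadata: %s",
                      paste(missing_meta, collapse = ", ")))
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(expression = vals, metadata = meta),
            class = "coex_dataset")
}

#' Write an expression matrix to delimited text
#'
#' Values are written at full double precision so that a write/read
#' round-trip reproduces the matrix bit-exactly.
#'
#' @param expression Numeric matrix with gene row names and sample column
#'   names.
#' @param path Output path; delimiter from extension unless `sep` given.
#' @param sep Field delimiter override.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expression, path, sep = NULL) {
  sep <- detect_sep(path, sep)
  txt <- apply(expression, c(1, 2), function(v) sprintf("%.17g", v))
  out <- cbind(gene = rownames(expression), txt)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Parses the GMT dialect: one term per line, tab-separated fields
#' `term id`, `description`, then one or more member gene identifiers.
#'
#' @param path Path to the GMT file.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors of members) and `term_names` (named
#'   character vector of descriptions).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  term_names <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      coex_stop("nigracoex_malformed_record",
                sprintf("GMT line %d: term '%s' has no member genes",
                        i, if (length(fields)) fields[1L] else ""))
    id <- fields[1L]
    sets[[id]] <- unique(fields[-(1:2)])
    term_names[[id]] <- fields[2L]
  }
  structure(list(sets = sets, term_names = term_names),
            class = "gene_set_collection")
}

#' Construct a gene-set collection in memory
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param term_names Optional named character vector of term descriptions;
#'   defaults to the term ids.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, term_names = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    coex_stop("nigracoex_bad_argument",
              "`sets` must be a uniquely named list")
  if (any(lengths(sets) == 0L))
    coex_stop("nigracoex_malformed_record", "gene sets must be non-empty")
  tn <- term_names %||% stats::setNames(names(sets), names(sets))
  structure(list(sets = lapply(sets, unique),
                 term_names = tn[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d terms, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

# canonical undirected edge key: lexicographically ordered endpoint pair
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read a protein-protein interaction edge list
#'
#' Reads a two- or three-column delimited file of undirected edges
#' (`gene_a`, `gene_b`, optional confidence score in \[0, 1\]). Edges with
#' score below `min_score` are dropped, matching the STRING convention of a
#' minimum required interaction score (0.4 is STRING's "medium confidence"
#' setting). Scoreless files are treated as score 1.0, so a `min_score`
#' filter is a no-op on them. Self-loops and duplicate edges (after
#' canonical ordering of the endpoint pair) are removed, with counts
#' reported via `message()`.
#'
#' @param path Path to the edge list.
#' @param min_score Minimum confidence score to retain an edge.
#' @param sep Field delimiter override.
#' @param header Whether the file has a header row.
#' @return A data frame of class `edge_list` with columns `from`, `to`,
#'   `score`, one row per canonical undirected edge.
#' @export
read_edges <- function(path, min_score = 0, sep = NULL, header = FALSE) {
  assert_scalar_number(min_score, "min_score", 0, 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1L]
  sep <- detect_sep(path, sep)
  from <- to <- character(length(lines))
  score <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], sep, fixed = TRUE)[[1L]]
    if (!(length(f) %in% c(2L, 3L)))
      coex_stop("nigracoex_parse_error",
                sprintf("edge list line %d: expected 2 or 3 fields, got %d",
                        i + header, length(f)))
    s <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3L])) else 1.0
    if (is.na(s))
      coex_stop("nigracoex_parse_error",
                sprintf("edge list line %d: non-numeric score '%s'",
                        i + header, f[3L]))
    from[i] <- f[1L]; to[i] <- f[2L]; score[i] <- s
  }
  edges <- data.frame(from = from, to = to, score = score,
                      stringsAsFactors = FALSE)
  edge_list(edges, min_score = min_score)
}

#' Canonicalise an edge table into an `edge_list`
#'
#' @param edges Data frame with columns `from`, `to` and optionally `score`
#'   (missing score treated as 1.0).
#' @param min_score Minimum score to retain an edge.
#' @return A canonical `edge_list` (no self-loops, no duplicates, endpoint
#'   pairs lexicographically ordered).
#' @export
edge_list <- function(edges, min_score = 0) {
  if (is.null(edges$score)) edges$score <- 1.0
  n0 <- nrow(edges)
  edges <- edges[edges$score >= min_score, , drop = FALSE]
  n_filtered <- n0 - nrow(edges)
  loops <- edges$from == edges$to
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  n_dup <- sum(dup)
  out <- data.frame(from = a[!dup], to = b[!dup],
                    score = edges$score[!dup], stringsAsFactors = FALSE)
  if (n_filtered + n_loops + n_dup > 0)
    message(sprintf(
      "edge_list: removed %d below score %.3g, %d self-loop(s), %d duplicate(s); %d edge(s) kept",
      n_filtered, min_score, n_loops, n_dup, nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' @export
print.coex_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  for (col in intersect(c("region", "condition", "stage"),
                        colnames(x$metadata))) {
    tab <- table(x$metadata[[col]], useNA = "no")
    cat(sprintf("  %s: %s\n", col,
                paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
  invisible(x)
}
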