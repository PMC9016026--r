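# shared fixture builders; everything is generated in code at test time

quiet <- function(expr) suppressMessages(expr)

# two vectors of length n with Pearson correlation exactly r (up to fp),
# built from a deterministic basis: x is the standardised ramp, e an
# alternating pattern orthogonalised against x
vectors_with_r <- function(r, n) {
  x <- seq_len(n)
  xs <- (x - mean(x)) / sd(x)
  e0 <- rep_len(c(1, -1, 2, -2), n)
  e0 <- e0 - mean(e0)
  e0 <- e0 - sum(e0 * xs) / sum(xs * xs) * xs
  es <- e0 / sd(e0)
  y <- r * xs + sqrt(1 - r^2) * es
  list(x = x, y = y)
}

# minimal coex_dataset-style list from a matrix and per-sample labels
make_dataset <- function(expr, region = "SN", condition = "control",
                         stage = NA) {
  metadata <- data.frame(sample_id = colnames(expr), region = region,
                         condition = condition, stage = stage,
                         stringsAsFactors = FALSE)
  list(expression = expr, metadata = metadata)
}

# random valid Mito Stress trace: positive rates, canonical 3-per-phase run
random_trace <- function(well = "w") {
  ocr_trace(well, "g",
            rep(c("basal", "oligomycin", "FCCP", "rotenone_antimycin"),
                each = 3),
            c(runif(3, 80, 120), runif(3, 30, 50), runif(3, 120, 180),
              runif(3, 10, 25)),
            protein = runif(1, 5, 40))
}

# path graph 1-2-...-n as an edge_list
path_edges <- function(n) {
  ids <- as.character(seq_len(n))
  quiet(edge_list(data.frame(from = ids[-n], to = ids[-1])))
}

edge_nodes_for_test <- function(e) unique(c(e$from, e$to))

# independent enumeration oracle for the hypergeometric upper tail:
# fraction of all C(N, n) query sets with at least k members in the
# first-K "term" prefix of the universe
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}
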