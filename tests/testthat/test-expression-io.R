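test_that("expression write/read round-trips bit-exactly with metadata", {
  set.seed(11)
  expr <- matrix(rnorm(12, mean = 8), nrow = 3,
                 dimnames = list(c("SNCA", "g1", "g2"),
                                 sprintf("s%d", 1:4)))
  mpath <- withr::local_tempfile(fileext = ".tsv")
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, mpath)
  meta <- data.frame(sample_id = colnames(expr), region = "SN",
                     condition = "control")
  write.table(meta, dpath, sep = "\t", row.names = FALSE, quote = FALSE)
  ds <- read_expression(mpath, dpath)
  expect_identical(dim(ds$expression), c(3L, 4L))
  expect_identical(ds$expression, expr)
  expect_identical(ds$metadata$sample_id, colnames(expr))
})

test_that("csv delimiter is auto-detected from the extension", {
  expr <- matrix(1:4 + 0.5, nrow = 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  mpath <- withr::local_tempfile(fileext = ".csv")
  dpath <- withr::local_tempfile(fileext = ".csv")
  write_expression(expr, mpath)
  write.table(data.frame(sample_id = c("s1", "s2")), dpath, sep = ",",
              row.names = FALSE, quote = FALSE)
  expect_identical(read_expression(mpath, dpath)$expression, expr)
})

test_that("loader raises distinct named failures", {
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = c("s1", "s2")), dpath, sep = "\t",
              row.names = FALSE, quote = FALSE)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "a\t1\t2", "a\t3\t4"), dup)
  expect_error(read_expression(dup, dpath),
               class = "nigracoex_duplicate_id")

  nonnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "a\t1\tx"), nonnum)
  expect_error(read_expression(nonnum, dpath),
               class = "nigracoex_non_numeric")

  ok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3", "a\t1\t2\t3"), ok)
  expect_error(read_expression(ok, dpath),
               class = "nigracoex_metadata_mismatch")

  na <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "a\t1\tNA"), na)
  expect_error(read_expression(na, dpath),
               class = "nigracoex_missing_values")
  expect_true(is.na(read_expression(na, dpath,
                                    allow_missing = TRUE)$expression[1, 2]))
})

test_that("GMT parsing handles members, empty files and malformed lines", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("GO:0000118\thistone deacetylase complex\tZNHIT1\tHDAC5", gmt)
  gs <- read_gene_sets(gmt)
  expect_identical(gs$sets[["GO:0000118"]], c("ZNHIT1", "HDAC5"))
  expect_identical(unname(gs$term_names["GO:0000118"]),
                   "histone deacetylase complex")

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), empty)
  expect_length(read_gene_sets(empty)$sets, 0L)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("TERM\tdescription only", bad)
  expect_error(read_gene_sets(bad), class = "nigracoex_malformed_record")
})

test_that("edge reading filters scores, self-loops and duplicates", {
  ep <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "b\ta\t0.9", "a\ta\t0.9"), ep)
  e <- quiet(read_edges(ep, min_score = 0.4))
  expect_identical(nrow(e), 1L)
  expect_identical(e$from, "a")

  low <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\t0.3", low)
  expect_identical(nrow(quiet(read_edges(low, min_score = 0.4))), 0L)

  noscore <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc"), noscore)
  e2 <- read_edges(noscore, min_score = 0.4)
  expect_identical(nrow(e2), 2L)
  expect_true(all(e2$score == 1.0))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.5", "oops"), bad)
  expect_error(read_edges(bad), class = "nigracoex_parse_error",
               regexp = "line 2")
})

test_that("edge canonicalisation is idempotent", {
  raw <- data.frame(from = c("z", "a", "m", "m"),
                    to = c("a", "z", "m", "q"),
                    score = c(0.5, 0.9, 1, 1))
  once <- quiet(edge_list(raw))
  twice <- quiet(edge_list(once))
  expect_identical(as.data.frame(once), as.data.frame(twice))
  expect_true(all(once$from <= once$to))
})
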