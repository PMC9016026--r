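canonical_trace <- function(protein = 1) {
  ocr_trace("A1", "ctrl",
            rep(c("basal", "oligomycin", "FCCP", "rotenone_antimycin"),
                each = 3),
            c(100, 98, 96, 40, 38, 36, 150, 148, 146, 20, 19, 18),
            protein = protein)
}

test_that("respiratory parameters match the hand-derived values", {
  rp <- respiratory_parameters(canonical_trace())
  expect_equal(rp$non_mito, 18)
  expect_equal(rp$basal, 78)
  expect_equal(rp$proton_leak, 18)
  expect_equal(rp$atp_production, 60)
  expect_equal(rp$maximal, 132)
  expect_equal(rp$spare_capacity, 54)
  expect_equal(rp$coupling_efficiency, 60 / 78)
})

test_that("basal = ATP production + proton leak on random valid traces", {
  set.seed(40)
  for (i in 1:200) {
    rp <- respiratory_parameters(random_trace())
    expect_equal(rp$basal, rp$atp_production + rp$proton_leak,
                 tolerance = 1e-12)
    expect_equal(rp$spare_capacity, rp$maximal - rp$basal,
                 tolerance = 1e-12)
    if (rp$basal > 0)
      expect_equal(rp$coupling_efficiency, rp$atp_production / rp$basal,
                   tolerance = 1e-12)
  }
})

test_that("degenerate and shifted traces behave as the formulas dictate", {
  flat <- ocr_trace("f", "g",
                    rep(c("basal", "oligomycin", "FCCP",
                          "rotenone_antimycin"), each = 3),
                    rep(50, 12), protein = 1)
  expect_warning(rp <- respiratory_parameters(flat), "coupling")
  expect_equal(rp$basal, 0)
  expect_equal(rp$maximal, 0)
  expect_true(is.na(rp$coupling_efficiency))

  # adding a constant shifts non_mito only; differences are invariant
  tr <- canonical_trace()
  shifted <- tr
  shifted$measurements$ocr <- shifted$measurements$ocr + 7
  a <- respiratory_parameters(tr)
  b <- respiratory_parameters(shifted)
  expect_equal(b$non_mito, a$non_mito + 7)
  for (f in c("basal", "proton_leak", "maximal", "atp_production",
              "spare_capacity"))
    expect_equal(b[[f]], a[[f]])
})

test_that("protein normalisation commutes with parameter computation", {
  tr <- canonical_trace(protein = 20)
  norm_first <- respiratory_parameters(normalise_to_protein(tr))
  raw <- respiratory_parameters(tr)
  for (f in c("non_mito", "basal", "proton_leak", "maximal",
              "atp_production", "spare_capacity"))
    expect_equal(norm_first[[f]], raw[[f]] / 20, tolerance = 1e-12)
  # coupling efficiency is a ratio: normalisation cancels
  expect_equal(norm_first$coupling_efficiency, raw$coupling_efficiency)
  # OCR 100 at 20 ug -> 5 per ug
  expect_equal(normalise_to_protein(tr)$measurements$ocr[1], 5)
  expect_identical(normalise_to_protein(canonical_trace(1))$measurements$ocr,
                   canonical_trace(1)$measurements$ocr)
})

test_that("mean-of-phase aggregation is available behind the flag", {
  rp <- respiratory_parameters(canonical_trace(), aggregate = "mean")
  expect_equal(rp$non_mito, 19)
  expect_equal(rp$basal, 98 - 19)
  expect_equal(rp$atp_production, 98 - 38)
})

test_that("trace validation rejects bad input", {
  expect_error(ocr_trace("w", "g", c("basal", "FCCP"), c(1, 2), protein = 0),
               class = "nigracoex_bad_protein")
  expect_error(ocr_trace("w", "g", rep("basal", 12), rnorm(12), protein = 1),
               class = "nigracoex_missing_phase")
  expect_error(
    ocr_trace("w", "g",
              c("oligomycin", "basal", "FCCP", "rotenone_antimycin"),
              1:4, protein = 1),
    class = "nigracoex_phase_order")
})

test_that("CTCF is the background-corrected integrated density", {
  expect_equal(ctcf(1000, 50, 2), 900)
  expect_equal(ctcf(1000, 50, 0), 1000)
  expect_equal(ctcf(100, 50, 2), 0)
  expect_error(ctcf(100, 0, 1), class = "nigracoex_bad_argument")
  expect_error(ctcf(100, 10, -1), class = "nigracoex_bad_argument")
})

test_that("group summaries report mean, SEM and replicate counts", {
  t1 <- canonical_trace(); t2 <- canonical_trace()
  t2$measurements$ocr <- t2$measurements$ocr + 0  # identical well
  same <- group_summary(list(respiratory_parameters(t1),
                             respiratory_parameters(t2)))
  expect_true(all(same$sem[same$parameter == "basal"] == 0))

  df <- data.frame(group = "g", basal = c(70, 90))
  gs <- group_summary(df)
  expect_equal(gs$mean[gs$parameter == "basal"], 80)
  expect_equal(gs$sem[gs$parameter == "basal"], 10)  # sd sqrt(200)/sqrt(2)
  expect_identical(gs$n[gs$parameter == "basal"], 2L)

  one <- group_summary(data.frame(group = "g", basal = 70))
  expect_true(is.na(one$sem))
})

test_that("long-format plate files round-trip into traces", {
  tr <- canonical_trace(protein = 12)
  tab <- cbind(well = "A1", group = "ctrl", tr$measurements, protein = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  traces <- read_ocr_traces(path)
  expect_length(traces, 1L)
  expect_equal(traces[["A1"]]$measurements$ocr, tr$measurements$ocr)
  expect_equal(traces[["A1"]]$protein, 12)
})
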