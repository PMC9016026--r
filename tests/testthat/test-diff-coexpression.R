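test_that("fisher_z_test matches the closed form", {
  # z = (atanh(.8) - atanh(.13)) / sqrt(1/5 + 1/12) = 1.8183, p = 0.0690
  fz <- fisher_z_test(0.8, 8, 0.13, 15)
  expect_equal(fz$z, 1.8183, tolerance = 1e-4)
  expect_equal(fz$p, 0.0690, tolerance = 1e-3)

  same <- fisher_z_test(0.5, 10, 0.5, 20)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  # antisymmetry under swapping the two groups
  a <- fisher_z_test(0.7, 12, 0.2, 30)
  b <- fisher_z_test(0.2, 30, 0.7, 12)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  expect_error(fisher_z_test(1, 10, 0.5, 10), class = "nigracoex_degenerate")
  expect_error(fisher_z_test(0.5, 3, 0.5, 10),
               class = "nigracoex_too_few_samples")
})

test_that("delta_r reports r per condition, the delta, and the class", {
  # exact r1 = 0.80 (n = 8) and r2 = 0.13 (n = 15): delta = -0.67
  v1 <- vectors_with_r(0.80, 8)
  v2 <- vectors_with_r(0.13, 15)
  expr <- rbind(SNCA = c(v1$x, v2$x), ZNHIT1 = c(v1$y, v2$y))
  colnames(expr) <- sprintf("s%02d", 1:23)
  ds <- make_dataset(expr, condition = rep(c("control", "PD"), c(8, 15)))
  res <- delta_r(ds, "SNCA", "ZNHIT1", "control", "PD")
  expect_equal(res$r1, 0.80, tolerance = 1e-10)
  expect_equal(res$r2, 0.13, tolerance = 1e-10)
  expect_equal(res$delta, -0.67, tolerance = 1e-10)
  # significant in control (p = 0.017), n.s. in disease: a broken pair
  expect_identical(res$class, "broken")
  expect_equal(res$z, 1.8183, tolerance = 1e-3)
})

test_that("identical condition groups give delta 0 and p_diff 1", {
  set.seed(30)
  expr <- matrix(rnorm(20), nrow = 2,
                 dimnames = list(c("seed", "g"), sprintf("s%d", 1:10)))
  ds <- make_dataset(expr, condition = "control")
  res <- delta_r(ds, "seed", "g", "control", "control")
  expect_equal(res$delta, 0)
  expect_equal(res$z, 0)
  expect_equal(res$p_diff, 1)
})

test_that("delta_r is antisymmetric under condition swap", {
  set.seed(31)
  expr <- matrix(rnorm(60), nrow = 2,
                 dimnames = list(c("seed", "g"), sprintf("s%d", 1:30)))
  ds <- make_dataset(expr, condition = rep(c("A", "B"), c(14, 16)))
  ab <- delta_r(ds, "seed", "g", "A", "B")
  ba <- delta_r(ds, "seed", "g", "B", "A")
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_diff, ba$p_diff)
})

test_that("planted correlation loss is classified broken", {
  # rho 0.8 in control, 0 in disease, n = 50 per condition
  hits_class <- 0; hits_fz <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    sim <- simulate_expression(synthetic_config(
      n_genes = 10, module_size = 4, rho = 0.8,
      groups = data.frame(label = c("ctrl", "pd"), region = "SN",
                          condition = c("control", "PD"), n = 50),
      broken_pairs = list(list(gene = "G0001", groups = "pd")),
      rng_seed = 500 + i))
    res <- delta_r(sim, "SNCA", "G0001", "control", "PD")
    hits_class <- hits_class + (res$class == "broken")
    hits_fz <- hits_fz + (res$p_diff < 0.05)
  }
  expect_gte(hits_class / n_rep, 0.9)
  expect_gte(hits_fz / n_rep, 0.9)
})

test_that("broken rate under the null stays near alpha", {
  # identical strong correlation in both conditions: 'broken' only through
  # a type-II event in condition 2, which at rho = .8, n = 50 is ~ alpha
  set.seed(77)
  broken <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    x1 <- rnorm(50); y1 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(50)
    x2 <- rnorm(50); y2 <- 0.8 * x2 + sqrt(1 - 0.64) * rnorm(50)
    expr <- rbind(seed = c(x1, x2), g = c(y1, y2))
    colnames(expr) <- sprintf("s%03d", 1:100)
    ds <- make_dataset(expr, condition = rep(c("A", "B"), each = 50))
    res <- delta_r(ds, "seed", "g", "A", "B")
    broken <- broken + (res$class == "broken")
  }
  # power at rho=.8, n=50 is essentially 1, so broken ~ Binom(200, ~0)
  mc_err <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(broken / n_rep, 0.05 + mc_err)
})

test_that("stage_profile orders strata and flags the earliest loss", {
  groups <- data.frame(label = c("ctrl", "b12", "b34", "b56"),
                       region = "SN",
                       condition = c("control", rep("PD", 3)),
                       stage = c("control", "1/2", "3/4", "5/6"), n = 40)
  cfg <- synthetic_config(
    n_genes = 10, module_size = 4, rho = 0.8, groups = groups,
    broken_pairs = broken_from_stage(
      "G0001", groups, "1/2",
      stage_levels = c("control", "1/2", "3/4", "5/6")),
    rng_seed = 61)
  sim <- simulate_expression(cfg)
  sim$metadata$stage <- factor(sim$metadata$stage,
                               levels = c("control", "1/2", "3/4", "5/6"))
  sp <- stage_profile(sim, "SNCA", "G0001")
  expect_identical(sp$stage, c("control", "1/2", "3/4", "5/6"))
  expect_true(sp$significant[1])
  expect_identical(attr(sp, "earliest_loss"), "1/2")

  # intact correlation at every stage: no loss flag
  intact <- simulate_expression(synthetic_config(
    n_genes = 10, module_size = 4, rho = 0.8, groups = groups,
    rng_seed = 62))
  intact$metadata$stage <- factor(intact$metadata$stage,
                                  levels = c("control", "1/2", "3/4", "5/6"))
  sp2 <- stage_profile(intact, "SNCA", "G0001")
  expect_true(is.na(attr(sp2, "earliest_loss")))
})

test_that("small strata are reported absent with a warning, not an error", {
  set.seed(63)
  expr <- matrix(rnorm(22), nrow = 2,
                 dimnames = list(c("seed", "g"), sprintf("s%d", 1:11)))
  ds <- make_dataset(expr, stage = rep(c("control", "1/2"), c(8, 3)))
  ds$metadata$stage <- factor(ds$metadata$stage,
                              levels = c("control", "1/2"))
  expect_warning(sp <- stage_profile(ds, "seed", "g"), "absent")
  expect_true(is.na(sp$r[sp$stage == "1/2"]))
  expect_identical(sp$n[sp$stage == "1/2"], 3L)

  ds$metadata$stage <- NULL
  expect_error(stage_profile(ds, "seed", "g"),
               class = "nigracoex_no_stage_column")
})

test_that("a single stage yields a length-1 profile without a loss flag", {
  set.seed(64)
  expr <- matrix(rnorm(16), nrow = 2,
                 dimnames = list(c("seed", "g"), sprintf("s%d", 1:8)))
  ds <- make_dataset(expr, stage = "control")
  sp <- stage_profile(ds, "seed", "g")
  expect_identical(nrow(sp), 1L)
})
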