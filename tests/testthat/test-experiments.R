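test_that("replicate aggregation computes mean and standard error", {
  res <- tibble::tibble(
    method = "lt_bayescpi", trait = "binary", generation = 3L,
    accuracy = c(0.5, 0.6, 0.7), slope = 1, slope_rescaled = 1)
  s <- summarize_scenario(res)
  expect_equal(s$mean_accuracy, 0.6)
  expect_equal(s$se_accuracy, 0.0577, tolerance = 1e-3)
  expect_identical(s$n_replicates, 3L)
})

test_that("increment rows are joint minus single-trait accuracy", {
  s <- tibble::tibble(
    method = c("bayescpi", "bayestcpi", "lt_bayescpi", "lt_bayescpi"),
    trait = c("continuous", "binary", "continuous", "binary"),
    generation = 3L,
    mean_accuracy = c(0.771, 0.465, 0.761, 0.581))
  inc <- accuracy_increment(s)
  expect_equal(inc$increment[inc$trait == "continuous"], -0.010)
  expect_equal(inc$increment[inc$trait == "binary"], 0.116)
})

test_that("the scenario grid varies one factor at a time around the standard", {
  grid <- ltbc_scenarios()
  expect_identical(grid$scenario[1], "standard")
  std <- grid[1, c("h2_A", "h2_B", "n_qtl", "r_AB", "incidence")]
  expect_equal(unname(unlist(std)), c(0.3, 0.1, 60, 0.5, 0.3))
  expect_identical(nrow(grid), 14L)  # standard + 13 variations
  for (i in 2:nrow(grid)) {
    row <- grid[i, c("h2_A", "h2_B", "n_qtl", "r_AB", "incidence")]
    expect_identical(sum(unlist(row) != unlist(std)), 1L)
  }
  expect_identical(unique(grid$n_replicates), 20)
})

test_that("desk-scale scenario runs are reproducible replicate by replicate", {
  r1 <- run_scenario("standard", n_replicates = 1, scale_factor = 0.02,
                     base_seed = 5, methods = c("bayescpi", "lt_bayescpi"))
  r2 <- run_scenario("standard", n_replicates = 1, scale_factor = 0.02,
                     base_seed = 5, methods = c("bayescpi", "lt_bayescpi"))
  expect_identical(nrow(r1), 12L)  # 4 gens x (1 single-trait + 2 joint) rows
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(c("scenario", "replicate", "accuracy") %in% names(r1)))
  s <- attr(r1, "summaries")
  expect_identical(nrow(s), 2L)
  expect_identical(nrow(attr(r1, "failures")), 0L)
  expect_error(run_scenario("nope"), "unknown scenario")
})
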