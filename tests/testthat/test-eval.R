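make_fit_stub <- function(g1, g2 = NULL, snps) {
  structure(list(
    method = if (is.null(g2)) "bayescpi" else "lt_bayescpi",
    snp_effects = tibble::tibble(
      snp = snps,
      effect_continuous = g1,
      effect_binary = if (is.null(g2)) NA_real_ else g2,
      inclusion = 0.5, monomorphic = FALSE)),
    class = "ltbc_fit")
}

test_that("GEBVs sum marker effects over raw dosages", {
  Z <- sim_genotypes(10, 3, seed = 1)
  # all effects zero -> everyone zero
  f0 <- make_fit_stub(rep(0, 3), snps = colnames(Z))
  expect_true(all(predict_gebv(f0, Z)$gebv_continuous == 0))
  # one SNP with effect 0.5 -> GEBV = 0.5 x dosage
  f1 <- make_fit_stub(c(0.5, 0, 0), snps = colnames(Z))
  expect_equal(predict_gebv(f1, Z)$gebv_continuous, 0.5 * Z[, 1],
               ignore_attr = TRUE)
  # permutation equivariance
  perm <- sample(10)
  expect_equal(predict_gebv(f1, Z[perm, ])$gebv_continuous,
               predict_gebv(f1, Z)$gebv_continuous[perm], ignore_attr = TRUE)
  # SNP panel mismatch names the missing ids
  expect_error(predict_gebv(f1, Z[, 1:2]), "snp0003")
})

test_that("accuracy is the Pearson correlation with guarded degeneracy", {
  x <- rnorm(50)
  expect_equal(accuracy(x, x), 1.0)
  expect_equal(accuracy(x, -x), -1.0)
  expect_warning(a <- accuracy(x, rep(1, 50)), "zero-variance")
  expect_true(is.na(a))
  # invariant to positive affine transforms of the GEBV
  g <- rnorm(50)
  expect_equal(accuracy(x, g), accuracy(x, 2.5 * g + 3))
})

test_that("bias slope and liability-scale rescaling behave as defined", {
  set.seed(2)
  tbv <- rnorm(100)
  expect_equal(bias_slope(tbv, tbv)$slope, 1.0)
  expect_equal(bias_slope(tbv, 2 * tbv)$slope, 0.5)
  # slope scales inversely with the GEBV scale
  g <- tbv + rnorm(100, 0, 0.5)
  expect_equal(bias_slope(tbv, 3 * g)$slope, bias_slope(tbv, g)$slope / 3)
  bs <- bias_slope(tbv, g, threshold_trait = TRUE, v_e2 = 9)
  expect_equal(bs$slope_rescaled, bs$slope / 9)
  expect_equal(bs$slope_rescaled_sd, bs$slope / 3)
  expect_error(bias_slope(tbv, g, threshold_trait = TRUE), "v_e2")
  expect_warning(b <- bias_slope(tbv, rep(0, 100)), "zero-variance")
  expect_true(is.na(b$slope))
})

test_that("paired accuracy test matches the reference implementation", {
  set.seed(3)
  for (i in 1:5) {
    a1 <- runif(20, 0.3, 0.8)
    a2 <- a1 + rnorm(20, 0.05, 0.03)
    mine <- paired_accuracy_test(a1, a2)
    ref <- stats::t.test(a1, a2, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
  # degenerate conventions
  x <- runif(5)
  expect_equal(paired_accuracy_test(x, x)$p_value, 1)
  expect_equal(paired_accuracy_test(x, x)$statistic, 0)
  d <- paired_accuracy_test(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_identical(d$statistic, Inf)
  expect_identical(d$p_value, 0)
  expect_error(paired_accuracy_test(1, 1), "replicates")
})

test_that("evaluate_fit produces per-generation rows consistent with its parts", {
  dat <- small_sim()
  fit <- ltbc_fit(dat$phenotypes, dat$genotypes, method = "lt_bayescpi",
                  n_cycles = 800, burn_in = 400, seed = 30)
  ev <- evaluate_fit(fit, dat, generations = 3:4)
  expect_identical(nrow(ev), 4L)   # 2 generations x 2 traits
  expect_true(all(ev$trait %in% c("continuous", "binary")))
  expect_true(all(abs(ev$accuracy) <= 1, na.rm = TRUE))
  # recompute one cell by hand
  g3 <- dat$phenotypes[dat$phenotypes$generation == 3, ]
  gebv <- predict_gebv(fit, dat$genotypes[g3$id, ])
  expect_equal(ev$accuracy[ev$trait == "continuous" & ev$generation == 3],
               cor(g3$tbv_A, gebv$gebv_continuous))
  expect_equal(ev$v_e2[ev$trait == "binary"][1], dat$v_e2)
})
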