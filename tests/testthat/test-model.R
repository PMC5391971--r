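test_that("training-data validation accepts consistent input", {
  Z <- sim_genotypes(4, 3, seed = 1)
  expect_invisible(validate_training(Z, y1 = rnorm(4), y2 = c(0L, 1L, 0L, 1L)))
  out <- validate_training(Z, y1 = rnorm(4))
  expect_length(out$monomorphic, 3)
})

test_that("validation rejects malformed input with informative errors", {
  Z <- sim_genotypes(4, 3, seed = 1)
  Zbad <- Z
  Zbad[2, 3] <- 3L
  expect_error(validate_training(Zbad), "ind0002")
  expect_error(validate_training(Zbad), "snp0003")
  expect_error(validate_training(Z, y2 = c(0L, 2L, 0L, 2L), k = 2),
               "contiguous")
  expect_error(validate_training(Z, y1 = rnorm(3)), "match")
  expect_error(validate_training(Z, y2 = c(0L, 1L, 0L, 1L), k = 1), "k >= 2")
})

test_that("monomorphic SNPs are flagged and pinned to zero effect", {
  Z <- sim_genotypes(60, 5, seed = 2)
  Z[, 3] <- 2L
  out <- validate_training(Z)
  expect_identical(unname(which(out$monomorphic)), 3L)
  set.seed(4)
  y <- rnorm(60) + Z[, 1]
  fit <- ltbc_fit(data.frame(id = rownames(Z), pheno_A = y), Z,
                  method = "bayescpi", n_cycles = 400, burn_in = 200, seed = 5)
  expect_true(fit$snp_effects$monomorphic[3])
  expect_identical(fit$snp_effects$effect_continuous[3], 0)
  expect_identical(fit$snp_effects$inclusion[3], 0)
})

test_that("initial state respects the fixed parameterisation of the binary trait", {
  Z <- sweep(sim_genotypes(100, 8, seed = 6) + 0, 2,
             colMeans(sim_genotypes(100, 8, seed = 6)))
  set.seed(10)
  y2 <- rbinom(100, 1, 0.3)
  st <- initialize_state(y1 = NULL, y2 = y2, Z = Z, seed = 11)
  # liabilities truncated on the side implied by the category
  expect_true(all(st$liability[y2 == 1] > 0))
  expect_true(all(st$liability[y2 == 0] < 0))
  # binary residual variance fixed at 1 (threshold fixed at 0 in the chain)
  expect_identical(st$Re[2, 2], 1)
  expect_identical(st$pi, 0.5)
  expect_true(all(st$delta == 0L) && all(st$g1 == 0) && all(st$g2 == 0))
  # determinism
  st2 <- initialize_state(y1 = NULL, y2 = y2, Z = Z, seed = 11)
  expect_identical(st, st2)
})

test_that("prior construction: flat scales give zero inverse, proper ones invert", {
  p <- ltbc_priors()
  expect_identical(p$V_g_inv, matrix(0, 2, 2))
  expect_identical(p$v_g, -3)
  V <- matrix(c(2, 0.5, 0.5, 1), 2)
  pp <- ltbc_priors(v_g = 8, V_g = V)
  expect_equal(pp$V_g_inv, solve(V))
  expect_error(ltbc_priors(beta_bounds = c(1, -1)))
})
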