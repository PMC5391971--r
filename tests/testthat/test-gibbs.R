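test_that("liability conditional moments follow the closed form", {
  Re <- matrix(c(2, 1, 1, 1), 2)
  lc <- liability_conditional(Re, fitted2 = 0.3, e1 = 0.8)
  expect_equal(lc$var, 0.5)                      # 1 - 1^2 / (2 * 1) halves it
  expect_equal(lc$mean, 0.3 + (1 / 2) * 0.8)
  # no residual information from the continuous trait: mean reduces to the
  # linear predictor
  expect_equal(liability_conditional(matrix(c(2, 0, 0, 1), 2), 0.3, 0.8)$mean, 0.3)
  expect_error(liability_conditional(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("truncated-normal draws match the independent oracle", {
  set.seed(1)
  x <- rtnorm_rng(2e4, 0, 1, 0, Inf)
  expect_equal(mean(x), dnorm(0) / (1 - pnorm(0)), tolerance = 0.01)
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) truncnorm::ptruncnorm(q, a = 0)))
  expect_lt(unname(ks$statistic), 0.02)
  # two-sided interval against the oracle's moments
  y <- rtnorm_rng(2e4, 1, 2, -1, 0.5)
  expect_equal(mean(y), truncnorm::etruncnorm(-1, 0.5, 1, 2), tolerance = 0.02)
  # deep tail stays inside its bounds and near the oracle mean
  z <- rtnorm_rng(2e4, 0, 1, 8, Inf)
  expect_true(all(z >= 8))
  expect_equal(mean(z), truncnorm::etruncnorm(8, Inf), tolerance = 0.01)
})

test_that("bivariate inclusion odds factorise when both covariances vanish", {
  set.seed(2)
  for (i in 1:20) {
    czz <- runif(1, 10, 800)
    v1 <- rnorm(1, 0, 40)
    v2 <- rnorm(1, 0, 40)
    G0 <- diag(c(runif(1, 0.01, 0.2), runif(1, 0.01, 0.2)))
    Re <- diag(c(runif(1, 0.5, 3), 1))
    biv <- snp_inclusion_log_bf(czz, v1, v2, G0 = G0, Re = Re)
    uni <- snp_inclusion_log_bf(czz, v1, G0 = G0[1, 1], Re = Re[1, 1]) +
      snp_inclusion_log_bf(czz, v2, G0 = G0[2, 2], Re = Re[2, 2])
    expect_equal(biv, uni, tolerance = 1e-10)
  }
})

test_that("pi updates follow the Beta conditional of the uniform prior", {
  set.seed(3)
  d0 <- sample_pi(0, 10, 5e4)
  expect_equal(mean(d0), 11 / 12, tolerance = 3 * sd(d0) / sqrt(5e4) + 1e-3)
  dq <- sample_pi(10, 10, 5e4)
  expect_equal(mean(dq), 1 / 12, tolerance = 3 * sd(dq) / sqrt(5e4) + 1e-3)
  expect_true(all(d0 > 0 & d0 < 1))
})

test_that("inverse-Wishart draws concentrate at the analytic mean and stay PD", {
  # IW2(Sg^{-1}, df): mean Sg / (df - 3); with Sg = c I and df = m - 3 the
  # draws concentrate at ~ c/m I as m grows
  cc <- 4
  for (m in c(50, 500, 5000)) {
    Sg <- diag(c(cc, cc))
    set.seed(m)
    dr <- riw2(solve(Sg), m - 3, 2000)
    expect_equal(mean(dr$v11), cc / (m - 6), tolerance = 0.02)
    expect_equal(mean(dr$v12), 0, tolerance = 4 * sd(dr$v12) / sqrt(2000))
  }
  set.seed(8)
  dr <- riw2(matrix(c(0.8, 0.3, 0.3, 1.2), 2), 12, 1e4)
  expect_true(all(dr$v11 > 0 & dr$v22 > 0))
  expect_true(all(dr$v11 * dr$v22 - dr$v12^2 > 0))
})

test_that("conditional residual draws keep the binary variance at 1 and stay PD", {
  Se <- matrix(c(150, 25, 25, 110), 2)
  set.seed(9)
  dr <- sample_re_conditional(Se, n_obs = 120, ndraws = 1e4)
  expect_true(all(dr$t22 == 1))
  # T11 - T12^2 = 1/x1 > 0: positive definiteness by construction
  expect_true(all(dr$t11 - dr$t12^2 > 0))
  # explicit zero-scale prior equals the flat default bit for bit
  set.seed(10)
  a <- sample_re_conditional(Se, 120, 100)
  set.seed(10)
  b <- sample_re_conditional(Se, 120, 100,
                             priors = ltbc_priors(v_e = -3, V_e = matrix(0, 2, 2)))
  expect_identical(a, b)
})

test_that("location sampler reproduces the least-squares solution of the MME", {
  # pi fixed at 1 empties the genome, leaving the fixed-effect system
  # C theta = r whose posterior mean under flat priors is the OLS solution
  set.seed(12)
  n <- 80
  x <- rnorm(n)
  y <- 1.5 + 2 * x + rnorm(n, 0, 1)
  Z <- sim_genotypes(n, 2, seed = 13)
  phen <- data.frame(id = rownames(Z), pheno_A = y, x = x)
  fit <- ltbc_fit(phen, Z, method = "bayescpi", covariates = "x",
                  n_cycles = 20000, burn_in = 2000, seed = 14, fixed_pi = 1)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(fit$beta_continuous), unname(ols), tolerance = 0.05)
  # the spike-only limit zeroes every SNP effect, hence every GEBV
  expect_true(all(fit$snp_effects$effect_continuous == 0))
  gebv <- predict_gebv(fit, Z)
  expect_true(all(gebv$gebv_continuous == 0))
  # the residual variance draw is the scaled inverse chi-square with df n-3;
  # its mean is close to SSE/(n-5) (beta sampling adds O(1/n) slack)
  sse <- sum(resid(lm(y ~ x))^2)
  expect_equal(mean(fit$traces$sigma2_e1), sse / (n - 5), tolerance = 0.05 * sse / (n - 5))
})

test_that("a single strongly associated SNP is almost always included", {
  set.seed(15)
  n <- 200
  Z <- sim_genotypes(n, 1, seed = 16, maf = 0.4)
  y <- 1.2 * Z[, 1] + rnorm(n, 0, 1)
  phen <- data.frame(id = rownames(Z), pheno_A = y)
  fit <- ltbc_fit(phen, Z, method = "bayescpi",
                  n_cycles = 3000, burn_in = 1000, seed = 17, fixed_pi = 0.5)
  expect_gt(fit$snp_effects$inclusion[1], 0.95)
})

test_that("a null-signal chain shrinks all effects towards zero", {
  set.seed(18)
  n <- 300
  Z <- sim_genotypes(n, 500, seed = 19)
  y <- rnorm(n)
  phen <- data.frame(id = rownames(Z), pheno_A = y)
  fit <- ltbc_fit(phen, Z, method = "bayescpi",
                  n_cycles = 3000, burn_in = 1500, seed = 20)
  expect_lt(mean(abs(fit$snp_effects$effect_continuous)), 0.02)
})

test_that("every chain mode passes the per-cycle invariant and bookkeeping checks", {
  dat <- small_sim()
  phen <- dat$phenotypes
  for (m in c("bayescpi", "bayestcpi", "lt_bayescpi")) {
    expect_no_error(
      ltbc_fit(phen, dat$genotypes, method = m, n_cycles = 300,
               burn_in = 100, seed = 21, check_invariants = TRUE))
  }
})

test_that("fits are bit-identical given the same seed", {
  dat <- small_sim()
  f1 <- ltbc_fit(dat$phenotypes, dat$genotypes, method = "lt_bayescpi",
                 n_cycles = 500, burn_in = 200, seed = 22)
  f2 <- ltbc_fit(dat$phenotypes, dat$genotypes, method = "lt_bayescpi",
                 n_cycles = 500, burn_in = 200, seed = 22)
  expect_identical(f1$snp_effects, f2$snp_effects)
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$G0_hat, f2$G0_hat)
})

test_that("threshold updates are a no-op for binary and ordered beyond", {
  set.seed(23)
  liab <- rnorm(200)
  y2 <- cut(liab, c(-Inf, 0, 1, 1.5, Inf), labels = FALSE) - 1L
  t0 <- c(0, 1, 1.5)
  expect_identical(sample_thresholds(liab, y2, k = 2, t = 0), 0)
  expect_identical(sample_thresholds(liab, y2, k = 3, t = c(0, 1)), c(0, 1))
  tb <- mean(liab) + c(-10, 10) * sd(liab)
  for (i in 1:50) {
    t1 <- sample_thresholds(liab, y2, k = 4, t = t0, t_bounds = tb)
    expect_true(all(diff(t1) > 0))
    expect_identical(t1[1:2], c(0, 1))
    expect_true(t1[3] >= max(liab[y2 == 2]) && t1[3] <= min(liab[y2 == 3]))
    expect_true(t1[3] >= tb[1] && t1[3] <= tb[2])
  }
})
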