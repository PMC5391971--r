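#' Joint-distribution (Geweke-style) correctness check of the Gibbs sampler
#'
#' The standard simulator test for MCMC software: with *proper* priors, the
#' marginal distribution of the parameters is the prior both under direct
#' prior sampling and under the successive-conditional simulator that
#' alternates one full Gibbs sweep with a fresh data draw from the sampling
#' model. Any error in a conditional distribution shows up as a mismatch of
#' the marginal moments. Run on a tiny bivariate instance with proper
#' inverse-Wishart priors for `G0`, a conditional inverse-Wishart prior for
#' `Re` (given the binary residual variance 1), bounded-uniform intercepts
#' and uniform pi.
#'
#' @param n Individuals.
#' @param q SNPs.
#' @param n_sweeps Successive-conditional iterations.
#' @param n_prior Direct prior draws.
#' @param seed Integer seed.
#' @param batch Batch size for the batch-means standard error of the
#'   autocorrelated successive-conditional chain.
#' @return Tibble with one row per checked moment: the two means, their
#'   standard errors, and the z statistic of the difference.
#' @export
geweke_joint_test <- function(n = 25, q = 10, n_sweeps = 40000,
                              n_prior = 40000, seed = 1, batch = 200) {
  set.seed(seed)
  v_g <- 8; v_e <- 8
  V_g <- diag(2) / 2.25       # E[G0] = solve(V_g) / (v_g - 3) = 0.45 I
  V_e <- solve(5 * matrix(c(1.2, 0.15, 0.15, 1), 2))
  priors <- ltbc_priors(v_g = v_g, V_g = V_g, v_e = v_e, V_e = V_e,
                        beta_bounds = c(-1, 1))
  Z <- matrix(rbinom(n * q, 2, 0.5) + 0, n, q)
  X <- matrix(1, n, 1)

  draw_prior_state <- function() {
    pi <- runif(1)
    delta <- rbinom(q, 1, 1 - pi)
    G0 <- solve(stats::rWishart(1, v_g, V_g)[, , 1])
    Re <- matrix(c(0, 0, 0, 1), 2)
    kd <- cpp_korsgaard(V_e, v_e, 1L)
    Re[1, 1] <- kd[1, 1]; Re[1, 2] <- kd[1, 2]; Re[2, 1] <- kd[1, 2]
    U <- chol(G0)
    g <- matrix(0, q, 2)
    m1 <- sum(delta)
    if (m1 > 0) g[delta == 1, ] <- matrix(rnorm(2 * m1), m1, 2) %*% U
    list(beta1 = runif(1, -1, 1), beta2 = runif(1, -1, 1),
         g1 = g[, 1], g2 = g[, 2], delta = as.integer(delta),
         liability = numeric(n), G0 = G0, Re = Re, pi = pi)
  }

  draw_data <- function(state) {
    e <- matrix(rnorm(2 * n), n, 2) %*% chol(state$Re)
    y1 <- X[, 1] * state$beta1 + as.numeric(Z %*% state$g1) + e[, 1]
    l <- X[, 1] * state$beta2 + as.numeric(Z %*% state$g2) + e[, 2]
    list(y1 = y1, liability = l, y2 = as.integer(l > 0))
  }

  record <- function(state, m1) {
    c(pi = state$pi, G0_11 = state$G0[1, 1], G0_22 = state$G0[2, 2],
      G0_12 = state$G0[1, 2], Re_11 = state$Re[1, 1],
      Re_12 = state$Re[1, 2], m1 = m1)
  }

  # direct prior sampling
  prior_mat <- matrix(NA_real_, n_prior, 7)
  for (i in seq_len(n_prior)) {
    s <- draw_prior_state()
    prior_mat[i, ] <- record(s, sum(s$delta))
  }

  # successive-conditional: one Gibbs sweep, then a fresh data draw
  state <- draw_prior_state()
  dat <- draw_data(state)
  state$liability <- dat$liability
  sc_mat <- matrix(NA_real_, n_sweeps, 7)
  plist <- priors[c("v_g", "V_g_inv", "v_e", "V_e_inv", "beta_min", "beta_max")]
  for (i in seq_len(n_sweeps)) {
    res <- cpp_run_chain(dat$y1, dat$y2, X, X, Z, 2L, plist,
                         1L, 0L, 1L, FALSE, FALSE, state, FALSE, -1)
    state <- res$state
    state$beta1 <- as.numeric(state$beta1)
    state$beta2 <- as.numeric(state$beta2)
    sc_mat[i, ] <- record(state, sum(state$delta))
    dat <- draw_data(state)
    state$liability <- dat$liability
  }

  batch_se <- function(x, b) {
    nb <- floor(length(x) / b)
    bm <- colMeans(matrix(x[seq_len(nb * b)], b, nb))
    sd(bm) / sqrt(nb)
  }
  nm <- c("pi", "G0_11", "G0_22", "G0_12", "Re_11", "Re_12", "m1")
  mean_prior <- colMeans(prior_mat)
  se_prior <- apply(prior_mat, 2, sd) / sqrt(n_prior)
  mean_chain <- colMeans(sc_mat)
  se_chain <- vapply(seq_len(7), function(j) batch_se(sc_mat[, j], batch), 0.0)
  tibble::tibble(
    stat = nm, mean_prior = mean_prior, se_prior = se_prior,
    mean_chain = mean_chain, se_chain = se_chain,
    z = (mean_chain - mean_prior) / sqrt(se_chain^2 + se_prior^2))
}
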