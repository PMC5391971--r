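#' Truncated-normal random draws
#'
#' Inverse-CDF sampling with an exponential-rejection fallback deep in the
#' tails (beyond 6 standard deviations), so draws stay usable at extreme
#' incidences of the binary trait. Uses R's RNG stream.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale.
#' @param lower,upper Truncation bounds (may be infinite).
#' @return Numeric vector of draws.
#' @export
rtnorm_rng <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  cpp_rtnorm(as.integer(n), mean, sd, lower, upper)
}

#' Inverse-Wishart draws (2 x 2)
#'
#' `IW2(V, df)` here means the inverse of a Wishart matrix with scale `V` and
#' `df` degrees of freedom (Bartlett construction), the convention in which
#' the flat-prior conditional of the SNP-effect covariance is
#' `IW2(Sg^{-1}, m - 3)` with mean `Sg / (m - 6)`.
#'
#' @param scale 2 x 2 Wishart scale matrix (positive definite).
#' @param df Degrees of freedom (> 1).
#' @param ndraws Number of draws.
#' @return A tibble with columns `v11`, `v12`, `v22`, one row per draw.
#' @export
riw2 <- function(scale, df, ndraws = 1) {
  stopifnot(df > 1, nrow(scale) == 2)
  tibble::as_tibble(cpp_riw2(as.matrix(scale), df, as.integer(ndraws)))
}

#' Conditional residual-covariance draws with the binary variance fixed at 1
#'
#' Samples the 2 x 2 residual covariance from its conditional inverse-Wishart
#' distribution given the (2,2) element equals 1, by the Korsgaard-type
#' algorithm: with `V = (V_e^{-1} + Se)^{-1}` partitioned as usual,
#' `x1 ~ W1(V11, df)`, `x2 ~ N(V11^{-1} V12, x1^{-1} V22.1)` with
#' `V22.1 = V22 - V12^2 / V11`, and the draw is `T11 = 1/x1 + x2^2`,
#' `T12 = -x2`, `T22 = 1`. Under flat priors `V = Se^{-1}` and
#' `df = n - 3`.
#'
#' @param Se 2 x 2 residual cross-product matrix (trait 2 on the liability
#'   scale).
#' @param n_obs Number of observations.
#' @param ndraws Number of draws.
#' @param priors An [ltbc_priors()] object (defaults flat).
#' @return A tibble with columns `t11`, `t12`, `t22` (`t22` is always 1).
#' @export
sample_re_conditional <- function(Se, n_obs, ndraws = 1, priors = ltbc_priors()) {
  Se <- as.matrix(Se)
  stopifnot(nrow(Se) == 2, ncol(Se) == 2)
  S <- priors$V_e_inv + Se
  df <- priors$v_e + n_obs
  if (df <= 1) stop("need v_e + n > 1 degrees of freedom", call. = FALSE)
  V <- solve(S)
  out <- tibble::as_tibble(cpp_korsgaard(V, df, as.integer(ndraws)))
  out$t22 <- 1
  out
}

#' Conditional draw of the exclusion probability pi
#'
#' Under the uniform(0,1) prior and pi = probability of a zero effect,
#' `pi | delta ~ Beta(q - m1 + 1, m1 + 1)` where `m1` is the number of
#' currently included SNPs out of `q`.
#'
#' @param m1 Included-SNP count.
#' @param q Total SNP count.
#' @param ndraws Number of draws.
#' @return Numeric vector of draws in (0, 1).
#' @export
sample_pi <- function(m1, q, ndraws = 1) {
  stopifnot(m1 >= 0, m1 <= q)
  rbeta(ndraws, q - m1 + 1, m1 + 1)
}

#' Log Bayes factor of the per-SNP inclusion odds
#'
#' The slab-vs-spike marginal-likelihood ratio for one SNP with the effect
#' pair integrated out: with `v = (z'e1*, z'e2*)` the residual projections
#' (SNP's own contribution added back), `b = Re^{-1} v` and
#' `Omega = (z'z) Re^{-1} + G0^{-1}`,
#' `log BF = -(log|G0| + log|Omega|)/2 + b' Omega^{-1} b / 2`.
#' The inclusion probability is `(1-pi) BF / (pi + (1-pi) BF)`. Passing
#' scalars for `G0`/`Re` (or `v2 = NULL`) gives the single-trait version.
#'
#' @param czz `z'z` of the (centered) dosage column.
#' @param v1,v2 Residual projections per trait (`v2 = NULL` for single trait).
#' @param G0 Slab covariance (2 x 2, or scalar variance).
#' @param Re Residual covariance (2 x 2, or scalar variance).
#' @return The log Bayes factor (slab over spike).
#' @export
snp_inclusion_log_bf <- function(czz, v1, v2 = NULL, G0, Re) {
  if (is.null(v2)) {
    return(cpp_snp_log_bf_single(czz, v1, as.numeric(G0)[1], as.numeric(Re)[1]))
  }
  cpp_snp_log_bf(czz, v1, v2, as.matrix(G0), as.matrix(Re))
}

#' Conditional moments of one liability
#'
#' For the bivariate model the fully conditional posterior of a liability is
#' normal with mean `x2'beta2 + z'g2 + (sigma_e12 / sigma_e1^2) * e1` (the
#' continuous-trait residual regression adjustment) and variance
#' `sigma_e2^2 (1 - sigma_e12^2 / (sigma_e1^2 sigma_e2^2))`, truncated to the
#' observed category's threshold interval.
#'
#' @param Re 2 x 2 residual covariance.
#' @param fitted2 `x2'beta2 + z'g2` for the individual.
#' @param e1 Continuous-trait residual for the individual (0 if absent).
#' @return List with `mean` and `var` of the untruncated conditional.
#' @export
liability_conditional <- function(Re, fitted2 = 0, e1 = 0) {
  Re <- as.matrix(Re)
  v <- Re[2, 2] - Re[1, 2]^2 / Re[1, 1]
  if (v <= 0) stop("residual covariance is not positive definite", call. = FALSE)
  list(mean = fitted2 + Re[1, 2] / Re[1, 1] * e1, var = v)
}

#' Threshold update for an ordinal trait
#'
#' With `k` categories there are `k - 1` thresholds; `t1 = 0` (and `t2 = 1`
#' when `k >= 3`) are fixed for identifiability, so free thresholds exist
#' only for `k >= 4`. Each free threshold is drawn uniformly between the
#' largest liability in its lower category and the smallest liability in its
#' upper category, intersected with the prior support `t_bounds` and the
#' order constraints. For `k <= 3` this is a no-op.
#'
#' @param liability Current liability vector.
#' @param y2 Category labels `0:(k-1)`.
#' @param k Number of categories.
#' @param t Current threshold vector (length `k - 1`).
#' @param t_bounds Prior support `[t_min, t_max]` (default mu +/- 10 sigma of
#'   the liabilities).
#' @return Updated threshold vector.
#' @export
sample_thresholds <- function(liability, y2, k, t,
                              t_bounds = mean(liability) + c(-10, 10) * sd(liability)) {
  stopifnot(length(t) == k - 1)
  if (k <= 3) return(t)
  for (j in 3:(k - 1)) { # t1 = 0, t2 = 1 fixed
    lo <- max(liability[y2 == j - 1], t[j - 1], t_bounds[1])
    hi <- min(liability[y2 == j], if (j < k - 1) t[j + 1] else Inf, t_bounds[2])
    if (!(hi > lo)) stop("empty admissible threshold interval", call. = FALSE)
    t[j] <- runif(1, lo, hi)
  }
  t
}
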