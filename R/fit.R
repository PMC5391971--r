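#' Fit a Bayesian mixture model for genomic prediction
#'
#' Fits one of three spike-and-slab (BayesCpi-type) models by single-site
#' Gibbs sampling:
#'
#' * `"lt_bayescpi"` — the bivariate linear-threshold model: one continuous
#'   trait and one binary trait analysed jointly, a shared per-SNP inclusion
#'   indicator with bivariate-normal slab `N(0, G0)`, residual covariance
#'   `Re` with the binary residual variance fixed at 1 (sampled by the
#'   conditional inverse-Wishart algorithm) and the threshold fixed at 0;
#' * `"bayescpi"` — the single continuous trait special case;
#' * `"bayestcpi"` — the single binary trait special case on the liability
#'   scale.
#'
#' Each Gibbs cycle sweeps liabilities, fixed effects, per-SNP
#' (indicator, effect) blocks with the slab integrated out of the inclusion
#' odds, `G0`, `Re`, and pi (Beta-updated under its uniform prior, with pi
#' the probability of a zero effect). Posterior means are accumulated over
#' post-burn-in cycles.
#'
#' @param phenotypes Data frame with an `id` column matching
#'   `rownames(genotypes)` plus the trait columns. Rows with missing values
#'   in the required trait(s) are dropped (candidates carry no phenotype).
#' @param genotypes Individuals x SNPs dosage matrix (0/1/2) with row and
#'   column names.
#' @param method One of `"lt_bayescpi"`, `"bayescpi"`, `"bayestcpi"`.
#' @param trait_continuous,trait_binary Column names of the traits.
#' @param covariates Optional character vector of fixed-effect columns (an
#'   intercept is always included).
#' @param n_cycles,burn_in,thin Chain settings (defaults 50000 / 30000 / 1).
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @param priors An [ltbc_priors()] object.
#' @param df_mode `"included"` (degrees of freedom of the `G0` update count
#'   the currently included SNPs, the default) or `"all"` (count all SNPs).
#' @param constrain_zero_covariance If `TRUE`, the off-diagonals of `G0` and
#'   `Re` are pinned to zero (the bivariate chain then factorises into the
#'   two single-trait chains except for the shared indicator).
#' @param check_invariants If `TRUE`, every cycle verifies the state
#'   invariants and the incremental residual bookkeeping (slow; for tests).
#' @param fixed_pi Optional fixed value for pi instead of sampling it.
#' @return An object of class `ltbc_fit`. Use [tidy()] for per-SNP posterior
#'   summaries, [glance()] for variance components and chain settings,
#'   `$traces` for per-cycle posterior draws, and [predict_gebv()] for
#'   breeding-value prediction.
#' @export
ltbc_fit <- function(phenotypes, genotypes,
                     method = c("lt_bayescpi", "bayescpi", "bayestcpi"),
                     trait_continuous = "pheno_A", trait_binary = "pheno_B",
                     covariates = NULL,
                     n_cycles = 50000, burn_in = 30000, thin = 1,
                     seed = NULL, priors = ltbc_priors(),
                     df_mode = c("included", "all"),
                     constrain_zero_covariance = FALSE,
                     check_invariants = FALSE, fixed_pi = NULL) {
  method <- match.arg(method)
  df_mode <- match.arg(df_mode)
  stopifnot(inherits(priors, "ltbc_priors"))
  mode <- match(method, c("bayescpi", "bayestcpi", "lt_bayescpi")) - 1L

  phenotypes <- as.data.frame(phenotypes)
  if (!"id" %in% names(phenotypes)) stop("phenotypes needs an `id` column", call. = FALSE)
  need <- c(if (mode != 1) trait_continuous, if (mode != 0) trait_binary)
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("missing trait column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(phenotypes[, need, drop = FALSE])
  phen <- phenotypes[keep, , drop = FALSE]
  rows <- match(phen$id, rownames(genotypes))
  if (anyNA(rows)) stop("phenotype ids missing from genotype rownames", call. = FALSE)
  Zraw <- genotypes[rows, , drop = FALSE]

  y1 <- if (mode != 1) as.numeric(phen[[trait_continuous]]) else NULL
  y2 <- if (mode != 0) as.integer(phen[[trait_binary]]) else NULL
  validate_training(Zraw, y1, y2, k = 2)

  X <- cbind(`(Intercept)` = rep(1, nrow(Zraw)))
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(phen))
    if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    X <- cbind(X, as.matrix(phen[, covariates, drop = FALSE]))
  }

  centers <- colMeans(Zraw)
  Z <- sweep(Zraw + 0, 2, centers)

  if (!is.null(seed)) set.seed(seed)
  init <- initialize_state(y1, y2, Z, p1 = ncol(X), p2 = ncol(X))
  res <- cpp_run_chain(
    y1 %||% numeric(0), y2 %||% integer(0), X, X, Z,
    mode, priors[c("v_g", "V_g_inv", "v_e", "V_e_inv", "beta_min", "beta_max")],
    as.integer(n_cycles), as.integer(burn_in), as.integer(thin),
    df_mode == "all", constrain_zero_covariance, init,
    check_invariants, fixed_pi %||% -1)

  traces <- tibble::as_tibble(res$traces)
  if (mode == 2L) {
    traces$r_g <- traces$sigma_g12 / sqrt(traces$sigma2_g1 * traces$sigma2_g2)
    traces$r_e <- traces$sigma_e12 / sqrt(traces$sigma2_e1 * traces$sigma2_e2)
  }

  snp_effects <- tibble::tibble(
    snp = colnames(genotypes),
    effect_continuous = if (mode != 1) res$g1_hat else NA_real_,
    effect_binary = if (mode != 0) res$g2_hat else NA_real_,
    inclusion = res$inclusion,
    monomorphic = res$monomorphic)

  structure(
    list(method = method,
         snp_effects = snp_effects,
         traces = traces,
         pi_hat = res$pi_hat,
         prop_included = mean(traces$n_included) / res$q_eff,
         G0_hat = res$G0_hat, Re_hat = res$Re_hat,
         beta_continuous = if (mode != 1) drop(res$beta1_hat) else NULL,
         beta_binary = if (mode != 0) drop(res$beta2_hat) else NULL,
         n_fallback = res$n_fallback,
         state = res$state,
         residuals = list(continuous = if (mode != 1) res$e1,
                          binary = if (mode != 0) res$e2),
         settings = list(
           method = method, n = nrow(Z), q = ncol(Z), q_eff = res$q_eff,
           n_cycles = n_cycles, burn_in = burn_in, thin = thin,
           n_kept = res$n_kept, seed = seed, df_mode = df_mode,
           constrain_zero_covariance = constrain_zero_covariance,
           trait_continuous = trait_continuous, trait_binary = trait_binary,
           covariates = covariates, centers = centers)),
    class = "ltbc_fit")
}

#' @export
print.ltbc_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<ltbc_fit> %s: n = %d, q = %d (%d informative)\n",
              x$method, s$n, s$q, s$q_eff))
  cat(sprintf("  %d cycles (%d burn-in, thin %d), %d kept\n",
              s$n_cycles, s$burn_in, s$thin, s$n_kept))
  cat(sprintf("  pi_hat = %.4f (proportion included %.4f)\n",
              x$pi_hat, x$prop_included))
  if (x$method == "lt_bayescpi")
    cat(sprintf("  genetic correlation %.3f, residual correlation %.3f\n",
                mean(x$traces$r_g), mean(x$traces$r_e)))
  invisible(x)
}

#' Tidy a fitted mixture model
#'
#' Per-SNP posterior summary: posterior-mean effects for each trait and the
#' posterior inclusion frequency.
#'
#' @param x An `ltbc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per SNP.
#' @method tidy ltbc_fit
#' @export
tidy.ltbc_fit <- function(x, ...) x$snp_effects

#' Model-level summary of a fitted mixture model
#'
#' One row: pi, proportion of SNPs included, posterior-mean variance
#' components and the implied genetic / residual correlations.
#'
#' @param x An `ltbc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance ltbc_fit
#' @export
glance.ltbc_fit <- function(x, ...) {
  G <- x$G0_hat; R <- x$Re_hat
  tibble::tibble(
    method = x$method,
    n = x$settings$n, q = x$settings$q, q_eff = x$settings$q_eff,
    pi_hat = x$pi_hat, prop_included = x$prop_included,
    sigma2_g1 = G[1, 1], sigma_g12 = G[1, 2], sigma2_g2 = G[2, 2],
    sigma2_e1 = R[1, 1], sigma_e12 = R[1, 2], sigma2_e2 = R[2, 2],
    r_g_hat = if (x$method == "lt_bayescpi") mean(x$traces$r_g) else NA_real_,
    r_e_hat = if (x$method == "lt_bayescpi") mean(x$traces$r_e) else NA_real_,
    n_kept = x$settings$n_kept, n_fallback = x$n_fallback)
}
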