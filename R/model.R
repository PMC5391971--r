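#' Prior settings for the Bayesian mixture models
#'
#' Defaults reproduce the flat (improper uniform) priors: degrees of freedom
#' `-3` and zero scale for both covariance matrices, effectively unbounded
#' uniforms for fixed effects, and a uniform prior on the exclusion
#' probability pi. `V_g` / `V_e` are the inverse-Wishart scale matrices
#' (2 x 2, or scalars for a single-trait model); `NULL` means the flat zero
#' scale. The threshold prior is an ordered uniform on
#' `[mu - 10 sigma, mu + 10 sigma]` of the liability scale; for a binary
#' trait the single threshold is fixed at 0 and the binary residual variance
#' at 1, so `t_bounds` only matters for `k >= 4` categories.
#'
#' @param v_g,v_e Inverse-Wishart degrees of freedom (default -3, flat).
#' @param V_g,V_e Inverse-Wishart scale matrices; `NULL` = flat (zero).
#' @param beta_bounds Length-2 numeric, uniform prior support for fixed
#'   effects.
#' @param t_bounds Length-2 numeric or `NULL` (derived as mu +/- 10 sigma).
#' @return An object of class `ltbc_priors`.
#' @export
ltbc_priors <- function(v_g = -3, V_g = NULL, v_e = -3, V_e = NULL,
                        beta_bounds = c(-1e8, 1e8), t_bounds = NULL) {
  as_inv <- function(V) {
    if (is.null(V)) return(matrix(0, 2, 2))
    V <- as.matrix(V)
    if (all(V == 0)) return(matrix(0, 2, 2))
    if (nrow(V) == 1) V <- diag(c(V[1, 1], V[1, 1]))
    solve(V)
  }
  stopifnot(length(beta_bounds) == 2, beta_bounds[1] < beta_bounds[2])
  structure(
    list(v_g = v_g, v_e = v_e,
         V_g = V_g, V_e = V_e,
         V_g_inv = as_inv(V_g), V_e_inv = as_inv(V_e),
         beta_min = beta_bounds[1], beta_max = beta_bounds[2],
         t_bounds = t_bounds),
    class = "ltbc_priors")
}

#' Validate training data for the samplers
#'
#' Checks dosage domain (0/1/2), shape consistency, and that categorical
#' labels are contiguous from 0. SNPs that are monomorphic in training are
#' flagged (they are retained in the panel but their effect is pinned to
#' zero, since a zero-variance genotype column has an improper conditional).
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param y1 Continuous observations or `NULL`.
#' @param y2 Integer category labels in `0:(k-1)` or `NULL`.
#' @param k Number of categories for `y2` (>= 2).
#' @return (Invisibly) a list with the checked pieces and a logical
#'   `monomorphic` flag per SNP.
#' @export
validate_training <- function(genotypes, y1 = NULL, y2 = NULL, k = 2) {
  if (!is.matrix(genotypes)) stop("genotypes must be a matrix", call. = FALSE)
  n <- nrow(genotypes)
  bad <- which(!(genotypes %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% n) + 1
    j <- ((bad[1] - 1) %/% n) + 1
    stop(sprintf("dosage outside {0,1,2} at row %s, column %s",
                 rownames(genotypes)[i] %||% i,
                 colnames(genotypes)[j] %||% j), call. = FALSE)
  }
  if (!is.null(y1)) {
    if (length(y1) != n) stop("length(y1) does not match genotype rows", call. = FALSE)
    if (anyNA(y1)) stop("y1 contains missing values", call. = FALSE)
  }
  if (!is.null(y2)) {
    if (k < 2) stop("a threshold trait needs k >= 2 categories", call. = FALSE)
    if (length(y2) != n) stop("length(y2) does not match genotype rows", call. = FALSE)
    if (anyNA(y2)) stop("y2 contains missing values", call. = FALSE)
    lab <- sort(unique(as.integer(y2)))
    if (!all(lab %in% 0:(k - 1)) || !identical(lab, seq_len(length(lab)) - 1L))
      stop("y2 labels must be contiguous integers starting at 0", call. = FALSE)
  }
  mono <- matrixStats_colVars(genotypes) == 0
  invisible(list(genotypes = genotypes, y1 = y1, y2 = y2, k = k,
                 monomorphic = mono))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial Gibbs state
#'
#' Intercepts start at the trait mean (probit of the observed incidence for
#' the liability scale), SNP effects and indicators at zero, pi at 0.5, the
#' SNP-effect covariance at a diagonal heuristic (half the phenotypic
#' variance spread over half the markers), the residual covariance at a
#' diagonal start with the binary variance fixed at 1, and liabilities at
#' truncated standard normals on the side implied by each observed category.
#'
#' @param y1 Continuous trait (or `NULL`).
#' @param y2 Binary 0/1 trait (or `NULL`).
#' @param Z Centered dosage matrix used by the chain.
#' @param p1,p2 Number of fixed-effect columns per trait.
#' @param seed Optional integer seed.
#' @return A list holding the full `ModelState`.
#' @export
initialize_state <- function(y1, y2, Z, p1 = 1, p2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Z)
  q <- ncol(Z)
  czz_total <- sum(colSums(Z^2)) / n
  gvar <- function(vy) 0.5 * vy / max(0.5 * czz_total, 1e-8)

  beta1 <- numeric(max(p1, 1))
  beta2 <- numeric(max(p2, 1))
  G0 <- diag(c(1e-4, 1e-4))
  Re <- diag(2)
  liab <- numeric(n)
  if (!is.null(y1)) {
    beta1[1] <- mean(y1)
    G0[1, 1] <- gvar(var(y1))
    Re[1, 1] <- 0.5 * var(y1)
  }
  if (!is.null(y2)) {
    inc <- min(max(mean(y2 == 1), 1 / (n + 1)), n / (n + 1))
    beta2[1] <- qnorm(inc)
    G0[2, 2] <- gvar(1)
    ones <- which(y2 == 1)
    zeros <- which(y2 == 0)
    liab[ones] <- cpp_rtnorm(length(ones), 0, 1, 0, Inf)
    liab[zeros] <- cpp_rtnorm(length(zeros), 0, 1, -Inf, 0)
  }
  list(beta1 = beta1, beta2 = beta2,
       g1 = numeric(q), g2 = numeric(q), delta = integer(q),
       liability = liab, G0 = G0, Re = Re, pi = 0.5)
}
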