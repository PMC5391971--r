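#' Genomic estimated breeding values for candidates
#'
#' `GEBV = Z %*% g_hat` per trait, summing posterior-mean marker effects over
#' the candidate's raw dosages. The candidate panel must contain every SNP of
#' the training panel (matched by name).
#'
#' @param fit An [ltbc_fit()] object.
#' @param genotypes Candidate dosage matrix with column names matching the
#'   training panel.
#' @return Tibble with `id` and `gebv_continuous` / `gebv_binary` columns
#'   (as available for the fitted method).
#' @export
predict_gebv <- function(fit, genotypes) {
  stopifnot(inherits(fit, "ltbc_fit"))
  snps <- fit$snp_effects$snp
  missing <- setdiff(snps, colnames(genotypes))
  if (length(missing))
    stop("candidate panel is missing SNPs: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5),
         call. = FALSE)
  Z <- genotypes[, snps, drop = FALSE]
  out <- tibble::tibble(id = rownames(Z) %||% seq_len(nrow(Z)))
  if (!all(is.na(fit$snp_effects$effect_continuous)))
    out$gebv_continuous <- as.numeric(Z %*% fit$snp_effects$effect_continuous)
  if (!all(is.na(fit$snp_effects$effect_binary)))
    out$gebv_binary <- as.numeric(Z %*% fit$snp_effects$effect_binary)
  out
}

#' Accuracy of genomic prediction
#'
#' Pearson correlation between true and estimated breeding values.
#'
#' @param tbv,gebv Numeric vectors of equal length (>= 3).
#' @return Correlation, or `NA` with a warning when either input has zero
#'   variance.
#' @export
accuracy <- function(tbv, gebv) {
  stopifnot(length(tbv) == length(gebv), length(tbv) >= 3)
  if (var(tbv) == 0 || var(gebv) == 0) {
    warning("zero-variance input: accuracy undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(tbv, gebv)
}

#' Bias of genomic prediction (regression of TBV on GEBV)
#'
#' The ordinary least-squares slope of TBV on GEBV; an unbiased prediction
#' has slope 1. For the threshold trait the GEBV lives on the model liability
#' scale (residual variance fixed at 1) while the TBV lives on the simulated
#' scale, so the slope is additionally rescaled by the true residual
#' liability variance `v_e2`: the primary output divides by `v_e2`; a
#' standard-deviation-based alternative (`/ sqrt(v_e2)`) is reported
#' alongside since the liability scales differ by a factor proportional to
#' the residual standard deviation.
#'
#' @param tbv,gebv Numeric vectors.
#' @param threshold_trait Is this the binary/liability trait?
#' @param v_e2 True residual liability variance (required when
#'   `threshold_trait = TRUE`).
#' @return Tibble with `slope`, and for the threshold trait
#'   `slope_rescaled` (`slope / v_e2`) and `slope_rescaled_sd`
#'   (`slope / sqrt(v_e2)`).
#' @export
bias_slope <- function(tbv, gebv, threshold_trait = FALSE, v_e2 = NULL) {
  stopifnot(length(tbv) == length(gebv))
  if (var(gebv) == 0) {
    warning("zero-variance GEBV: slope undefined", call. = FALSE)
    return(tibble::tibble(slope = NA_real_,
                          slope_rescaled = NA_real_,
                          slope_rescaled_sd = NA_real_))
  }
  b <- cov(tbv, gebv) / var(gebv)
  if (!threshold_trait)
    return(tibble::tibble(slope = b, slope_rescaled = NA_real_,
                          slope_rescaled_sd = NA_real_))
  if (is.null(v_e2) || v_e2 <= 0)
    stop("rescaling the threshold-trait slope needs v_e2 > 0", call. = FALSE)
  tibble::tibble(slope = b, slope_rescaled = b / v_e2,
                 slope_rescaled_sd = b / sqrt(v_e2))
}

#' Evaluate a fit against simulated truth
#'
#' Computes per-generation accuracy and bias slope of the GEBVs for every
#' candidate generation, using the true breeding values carried by the
#' simulated dataset. Threshold-trait slopes are rescaled with the dataset's
#' true residual liability variance.
#'
#' @param fit An [ltbc_fit()] object.
#' @param dataset The `ltbc_sim` dataset the fit was trained on.
#' @param generations Candidate generations to evaluate (default 3:6).
#' @return Tibble (method, trait, generation, n, accuracy, slope,
#'   slope_rescaled, v_e2).
#' @export
evaluate_fit <- function(fit, dataset, generations = 3:6) {
  stopifnot(inherits(dataset, "ltbc_sim"))
  phen <- dataset$phenotypes
  cand <- phen[phen$generation %in% generations, ]
  gebv <- predict_gebv(fit, dataset$genotypes[cand$id, , drop = FALSE])
  cand <- dplyr::bind_cols(cand, gebv[, -1, drop = FALSE])

  one <- function(d, trait) {
    if (trait == "continuous") {
      tbv <- d$tbv_A; g <- d$gebv_continuous; thr <- FALSE
    } else {
      tbv <- d$tbv_B; g <- d$gebv_binary; thr <- TRUE
    }
    bs <- bias_slope(tbv, g, threshold_trait = thr, v_e2 = dataset$v_e2)
    tibble::tibble(
      method = fit$method, trait = trait,
      generation = d$generation[1], n = nrow(d),
      accuracy = accuracy(tbv, g),
      slope = bs$slope, slope_rescaled = bs$slope_rescaled,
      v_e2 = if (thr) dataset$v_e2 else NA_real_)
  }

  traits <- c(if ("gebv_continuous" %in% names(cand)) "continuous",
              if ("gebv_binary" %in% names(cand)) "binary")
  grid <- expand.grid(generation = sort(unique(cand$generation)),
                      trait = traits, stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(generation, trait)
    one(cand[cand$generation == generation, ], trait))
}

#' Paired t-test on replicate accuracies
#'
#' Two-sided paired t-test of per-replicate accuracy differences between two
#' methods evaluated on the same replicates. Degenerate cases: identical
#' vectors give `t = 0, p = 1` by convention; a constant nonzero difference
#' gives an infinite statistic and `p = 0`.
#'
#' @param acc1,acc2 Paired accuracy vectors (>= 2 replicates each).
#' @return Tibble with `estimate` (mean difference), `statistic`, `df`,
#'   `p_value`.
#' @export
paired_accuracy_test <- function(acc1, acc2) {
  if (length(acc1) != length(acc2) || length(acc1) < 2)
    stop("need >= 2 paired replicates", call. = FALSE)
  d <- acc1 - acc2
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(tibble::tibble(estimate = 0, statistic = 0,
                                      df = n - 1, p_value = 1))
    return(tibble::tibble(estimate = m, statistic = sign(m) * Inf,
                          df = n - 1, p_value = 0))
  }
  t <- m / (s / sqrt(n))
  tibble::tibble(estimate = m, statistic = t, df = n - 1,
                 p_value = 2 * pt(-abs(t), n - 1))
}
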