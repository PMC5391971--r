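#' Plot a fitted model
#'
#' `type = "effects"` shows the absolute posterior-mean SNP effects along the
#' genome per trait (the usual whole-genome regression effect plot);
#' `type = "trace"` shows the post-burn-in traces of pi, the variance
#' components, and the included-SNP count.
#'
#' @param object An [ltbc_fit()] object.
#' @param type `"effects"` or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ltbc_fit
#' @export
autoplot.ltbc_fit <- function(object, type = c("effects", "trace"), ...) {
  type <- match.arg(type)
  if (type == "effects") {
    d <- object$snp_effects
    d$index <- seq_len(nrow(d))
    long <- tidyr::pivot_longer(
      d, dplyr::any_of(c("effect_continuous", "effect_binary")),
      names_to = "trait", values_to = "effect", names_prefix = "effect_")
    long <- long[!is.na(long$effect), ]
    return(
      ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = abs(.data$effect))) +
        ggplot2::geom_point(size = 0.4, alpha = 0.6) +
        ggplot2::facet_wrap(~trait, ncol = 1, scales = "free_y") +
        ggplot2::labs(x = "SNP index", y = "|posterior-mean effect|",
                      title = object$method))
  }
  keepcols <- intersect(
    c("pi", "sigma2_g1", "sigma2_g2", "sigma_g12",
      "sigma2_e1", "sigma_e12", "n_included"),
    names(object$traces))
  long <- tidyr::pivot_longer(object$traces[, c("cycle", keepcols)],
                              -"cycle", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Gibbs cycle", y = NULL, title = object$method)
}

#' Plot aggregated scenario accuracies
#'
#' Mean accuracy with standard-error bars by generation, method and trait,
#' from [summarize_scenario()] output.
#'
#' @param summary Tibble from [summarize_scenario()].
#' @return A ggplot object.
#' @export
plot_scenario_accuracy <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$generation, y = .data$mean_accuracy,
                               colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$se_accuracy,
                   ymax = .data$mean_accuracy + .data$se_accuracy),
      width = 0.1) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "Candidate generation", y = "Accuracy (r TBV,GEBV)")
}
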