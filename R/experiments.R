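#' Scenario grid of the simulation study
#'
#' The standard scenario (h2_A = 0.3, h2_B = 0.1, 60 QTL, r_AB = 0.5,
#' incidence 0.30) plus one-factor-at-a-time variations of the genetic
#' correlation, QTL number, both heritabilities, and the incidence.
#'
#' @param n_replicates Replicates per scenario (default 20).
#' @return Tibble with one row per scenario (id plus architecture fields).
#' @export
ltbc_scenarios <- function(n_replicates = 20) {
  std <- list(h2_A = 0.3, h2_B = 0.1, n_qtl = 60, r_AB = 0.5, incidence = 0.3)
  vary <- list(r_AB = c(0, 0.2, 0.8), n_qtl = c(20, 200, 500),
               h2_A = c(0.5, 0.8), h2_B = c(0.3, 0.5),
               incidence = c(0.05, 0.1, 0.5))
  rows <- list(tibble::as_tibble(c(scenario = "standard", std)))
  for (par in names(vary)) {
    for (v in vary[[par]]) {
      s <- std
      s[[par]] <- v
      rows[[length(rows) + 1]] <-
        tibble::as_tibble(c(scenario = sprintf("%s_%g", par, v), s))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$n_replicates <- n_replicates
  out
}

#' Run one simulation replicate through all methods
#'
#' Simulates a dataset, fits the requested methods on the training
#' generations, and evaluates candidate generations; also records the
#' model-level posterior summaries ([glance()]).
#'
#' @param architecture An [architecture_config()].
#' @param genome,demography Configurations (defaults = full-scale design).
#' @param seed Integer seed for this replicate.
#' @param methods Methods to fit.
#' @param n_cycles,burn_in Chain settings.
#' @param n_training If smaller than the available training individuals,
#'   a random subset of this size keeps phenotypes (desk-scaling).
#' @param generations Candidate generations to evaluate.
#' @return List with `evaluation` (tibble) and `summaries` (tibble of glance
#'   rows per method).
#' @export
run_replicate <- function(architecture,
                          genome = genome_config(),
                          demography = demography_config(),
                          seed = 1,
                          methods = c("bayescpi", "bayestcpi", "lt_bayescpi"),
                          n_cycles = 50000, burn_in = 30000,
                          n_training = NULL, generations = 3:6) {
  dat <- simulate_dataset(genome, demography, architecture, seed = seed)
  phen <- dat$phenotypes
  if (!is.null(n_training)) {
    tr <- which(phen$role == "training")
    if (n_training < length(tr)) {
      drop <- sample(tr, length(tr) - n_training)
      phen$pheno_A[drop] <- NA
      phen$pheno_B[drop] <- NA
    }
  }
  evals <- list()
  sums <- list()
  for (m in methods) {
    fit <- ltbc_fit(phen, dat$genotypes, method = m,
                    n_cycles = n_cycles, burn_in = burn_in,
                    seed = seed + 10000L)
    evals[[m]] <- evaluate_fit(fit, dat, generations)
    sums[[m]] <- glance(fit)
  }
  list(evaluation = dplyr::bind_rows(evals),
       summaries = dplyr::bind_rows(sums),
       dataset_truth = tibble::tibble(
         r_AB = architecture$r_AB,
         realized_r_g = cor(dat$phenotypes$tbv_A, dat$phenotypes$tbv_B),
         v_e2 = dat$v_e2))
}

#' Run a scenario with replicates
#'
#' Repeats [run_replicate()] `n_replicates` times (replicate `r` uses seed
#' `base_seed + r`) and returns the stacked long-format results.
#' `scale_factor` in (0, 1] uniformly shrinks the design for desk-scale
#' runs: markers per chromosome and training individuals are reduced
#' proportionally and the chain length is scaled with a floor of 3000 cycles
#' / 1500 burn-in. `scale_factor = 1` is the full-scale design
#' (several CPU-hours per scenario).
#'
#' @param scenario One row of [ltbc_scenarios()] (or a scenario id string).
#' @param n_replicates Number of replicates.
#' @param scale_factor Design shrink factor in (0, 1].
#' @param base_seed Seed base; replicate r uses `base_seed + r`.
#' @param methods Methods to fit.
#' @return Tibble of per-replicate evaluation rows (scenario, replicate,
#'   method, trait, generation, accuracy, slope, slope_rescaled) with the
#'   per-method posterior summaries attached as attribute `"summaries"` and
#'   any replicate failures as attribute `"failures"`.
#' @export
run_scenario <- function(scenario = "standard", n_replicates = 2,
                         scale_factor = 0.1, base_seed = 1,
                         methods = c("bayescpi", "bayestcpi", "lt_bayescpi")) {
  grid <- ltbc_scenarios()
  if (is.character(scenario)) {
    row <- grid[grid$scenario == scenario, ]
    if (nrow(row) != 1) stop("unknown scenario id: ", scenario, call. = FALSE)
  } else row <- scenario
  stopifnot(scale_factor > 0, scale_factor <= 1)

  genome <- genome_config(
    n_markers_per_chrom = max(20, round(2000 * scale_factor)))
  demo <- demography_config()
  arch <- architecture_config(
    n_qtl = row$n_qtl, r_AB = row$r_AB, h2_A = row$h2_A, h2_B = row$h2_B,
    incidence = row$incidence)
  n_train <- max(100, round(2000 * scale_factor))
  n_cycles <- max(3000, round(50000 * scale_factor))
  burn_in <- max(1500, round(30000 * scale_factor))

  res <- list()
  sums <- list()
  fails <- list()
  for (r in seq_len(n_replicates)) {
    out <- tryCatch(
      run_replicate(arch, genome, demo, seed = base_seed + r,
                    methods = methods, n_cycles = n_cycles,
                    burn_in = burn_in, n_training = n_train),
      error = function(e) e)
    if (inherits(out, "error")) {
      fails[[length(fails) + 1]] <-
        tibble::tibble(scenario = row$scenario, replicate = r,
                       message = conditionMessage(out))
      next
    }
    ev <- out$evaluation
    ev$scenario <- row$scenario
    ev$replicate <- r
    res[[r]] <- ev
    s <- out$summaries
    s$scenario <- row$scenario
    s$replicate <- r
    sums[[r]] <- s
  }
  out <- dplyr::bind_rows(res)
  attr(out, "summaries") <- dplyr::bind_rows(sums)
  attr(out, "failures") <- dplyr::bind_rows(fails)
  out
}

#' Aggregate replicate results
#'
#' Mean and standard error of accuracy (and slopes) across replicates, by
#' method, trait and generation — the layout of the result tables.
#'
#' @param results Long tibble from [run_scenario()].
#' @return Tibble with mean and s.e. columns.
#' @export
summarize_scenario <- function(results) {
  se <- function(x) sd(x) / sqrt(sum(!is.na(x)))
  dplyr::summarise(
    dplyr::group_by(results, .data$method, .data$trait, .data$generation),
    n_replicates = dplyr::n(),
    mean_accuracy = mean(.data$accuracy), se_accuracy = se(.data$accuracy),
    mean_slope = mean(.data$slope), se_slope = se(.data$slope),
    mean_slope_rescaled = mean(.data$slope_rescaled),
    se_slope_rescaled = se(.data$slope_rescaled),
    .groups = "drop")
}

#' Accuracy increment of the joint model over single-trait prediction
#'
#' For each trait and generation, the difference between the joint-model
#' accuracy and the matching single-trait accuracy (BayesCpi for the
#' continuous trait, BayesTCpi for the binary trait) — the "Increment" rows
#' of the result tables.
#'
#' @param summary Output of [summarize_scenario()].
#' @return Tibble (trait, generation, single, joint, increment).
#' @export
accuracy_increment <- function(summary) {
  single <- summary[summary$method %in% c("bayescpi", "bayestcpi"), ]
  joint <- summary[summary$method == "lt_bayescpi", ]
  merged <- dplyr::inner_join(
    dplyr::select(single, "trait", "generation", single = "mean_accuracy"),
    dplyr::select(joint, "trait", "generation", joint = "mean_accuracy"),
    by = c("trait", "generation"))
  merged$increment <- merged$joint - merged$single
  merged
}
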