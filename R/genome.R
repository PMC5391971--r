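#' Haldane's map function
#'
#' Converts a map distance in Morgan to a recombination fraction assuming no
#' crossover interference: `(1 - exp(-2 d)) / 2`, which lies in `[0, 0.5)`.
#'
#' @param d Map distance in Morgan (non-negative, vectorised).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane(0.0005) # adjacent markers at 1 Morgan / 2000
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d))
}

#' Genome configuration for the forward simulator
#'
#' Markers are evenly spaced along each chromosome (spacing
#' `chrom_length / n_markers_per_chrom`). Every interval between two adjacent
#' markers harbours one candidate QTL position at its midpoint, so QTL are
#' separate loci from markers and genomic prediction has to act through
#' linkage disequilibrium. Set `qtl_on_markers = TRUE` for the alternative
#' reading in which candidate QTL coincide with marker loci.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Genetic length per chromosome in Morgan.
#' @param n_markers_per_chrom Markers per chromosome.
#' @param mutation_rate Per-locus per-gamete probability of an allele-state
#'   flip during the historical (mutation-drift) phase.
#' @param qtl_on_markers If `TRUE`, candidate QTL are the marker loci
#'   themselves instead of interstitial midpoints.
#' @return An object of class `ltbc_genome`: the configuration plus the
#'   derived locus map (`loci`, a tibble with chromosome, position, type) and
#'   the per-interval recombination fractions used by meiosis.
#' @export
genome_config <- function(n_chromosomes = 5, chrom_length = 1,
                          n_markers_per_chrom = 2000,
                          mutation_rate = 1.25e-3,
                          qtl_on_markers = FALSE) {
  if (n_chromosomes < 1 || n_markers_per_chrom < 2)
    stop("need at least one chromosome with two markers", call. = FALSE)
  if (mutation_rate < 0) stop("mutation_rate must be >= 0", call. = FALSE)
  if (chrom_length < 0) stop("chrom_length must be >= 0", call. = FALSE)

  per_chrom <- function(chr) {
    spacing <- chrom_length / n_markers_per_chrom
    mpos <- (seq_len(n_markers_per_chrom) - 0.5) * spacing
    if (qtl_on_markers) {
      tibble::tibble(chrom = chr, pos = mpos, is_marker = TRUE,
                     is_candidate = TRUE)
    } else {
      cpos <- head(mpos, -1) + spacing / 2
      out <- tibble::tibble(
        chrom = chr,
        pos = c(mpos, cpos),
        is_marker = c(rep(TRUE, length(mpos)), rep(FALSE, length(cpos))),
        is_candidate = c(rep(FALSE, length(mpos)), rep(TRUE, length(cpos))))
      out[order(out$pos, !out$is_marker), ]
    }
  }
  loci <- dplyr::bind_rows(lapply(seq_len(n_chromosomes), per_chrom))
  loci$locus <- seq_len(nrow(loci))

  # recombination fraction with the previous locus; 0.5 across chromosome
  # boundaries (independent assortment)
  rec <- numeric(nrow(loci))
  d <- c(0, diff(loci$pos))
  new_chrom <- c(TRUE, diff(loci$chrom) != 0)
  rec[!new_chrom] <- haldane(d[!new_chrom])
  rec[new_chrom] <- 0.5

  structure(
    list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
         n_markers_per_chrom = n_markers_per_chrom,
         mutation_rate = mutation_rate, qtl_on_markers = qtl_on_markers,
         loci = loci, rec = rec),
    class = "ltbc_genome")
}

#' Demography configuration for the forward simulator
#'
#' The default design: a base population of 100 (50 males, 50 females) mated
#' at random for 1,000 non-overlapping historical generations of constant
#' size (one male and one female offspring per mating) to reach
#' mutation-drift equilibrium; generation 1 expands to 1,000 by giving each
#' generation-0 mating 20 offspring (10 male, 10 female); generations 2-6 are
#' produced by 50 randomly chosen sires, each mated to 10 dams, every dam
#' leaving one male and one female offspring.
#'
#' @param base_size Historical population size (even; half of each sex).
#' @param n_historical Number of historical random-mating generations.
#' @param expansion_size Size of generation 1 (and later generations).
#' @param n_sires Sires selected per recent generation.
#' @param n_recent Number of recent generations to breed (1 = expansion only).
#' @return An object of class `ltbc_demography`.
#' @export
demography_config <- function(base_size = 100, n_historical = 1000,
                              expansion_size = 1000, n_sires = 50,
                              n_recent = 6) {
  if (base_size < 2 || base_size %% 2 != 0)
    stop("base_size must be even and >= 2", call. = FALSE)
  if (n_historical < 0) stop("n_historical must be >= 0", call. = FALSE)
  if (expansion_size %% base_size != 0)
    stop("expansion_size must be a multiple of base_size (equal family sizes)",
         call. = FALSE)
  if (n_recent < 1) stop("n_recent must be >= 1", call. = FALSE)
  if (n_sires < 1 || n_sires > expansion_size / 2)
    stop("n_sires must be between 1 and the number of males", call. = FALSE)
  structure(
    list(base_size = base_size, n_historical = n_historical,
         expansion_size = expansion_size, n_sires = n_sires,
         n_recent = n_recent),
    class = "ltbc_demography")
}

#' Genetic-architecture configuration for the two simulated traits
#'
#' Trait A is continuous, trait B binary on the liability scale. QTL fall in
#' three groups: pleiotropic (effects on both traits), A-only and B-only,
#' with ratio `group_ratio` (forced to 0:0.5:0.5 when `r_AB = 0`).
#' Pleiotropic allele-substitution effect pairs are bivariate normal.
#'
#' With `target_correlation = "genetic"` (default) the effect-pair
#' correlation is inflated to
#' `r_AB * sqrt((n1 + n2) (n1 + n3)) / n1` (n_i = group sizes) so that the
#' *realized* genetic correlation between the two true-breeding-value vectors
#' targets `r_AB` despite the dilution from the single-trait groups;
#' `"effect"` uses `r_AB` for the pair correlation literally.
#'
#' @param n_qtl Number of QTL.
#' @param r_AB Genetic correlation between traits A and B, in `[-1, 1]`.
#' @param group_ratio Proportions (pleiotropic, A-only, B-only); must sum to 1.
#' @param var_A,var_B Total additive-genetic variance targets after rescaling.
#' @param h2_A,h2_B Heritabilities (trait B on the liability scale).
#' @param incidence Proportion of training individuals observed as 1 for
#'   trait B.
#' @param env_corr Environmental correlation between the traits.
#' @param target_correlation `"genetic"` or `"effect"` (see Details).
#' @return An object of class `ltbc_architecture`.
#' @export
architecture_config <- function(n_qtl = 60, r_AB = 0.5,
                                group_ratio = c(0.8, 0.1, 0.1),
                                var_A = 2.0, var_B = 1.0,
                                h2_A = 0.3, h2_B = 0.1,
                                incidence = 0.3, env_corr = 0,
                                target_correlation = c("genetic", "effect")) {
  target_correlation <- match.arg(target_correlation)
  if (abs(sum(group_ratio)) < 1e-12 || abs(sum(group_ratio) - 1) > 1e-8)
    stop("group_ratio must sum to 1", call. = FALSE)
  if (abs(r_AB) > 1) stop("r_AB must be in [-1, 1]", call. = FALSE)
  if (r_AB == 0) group_ratio <- c(0, 0.5, 0.5)
  if (h2_A <= 0 || h2_A > 1 || h2_B <= 0 || h2_B > 1)
    stop("heritabilities must be in (0, 1]", call. = FALSE)
  if (incidence <= 0 || incidence >= 1)
    stop("incidence must be in (0, 1)", call. = FALSE)
  if (n_qtl < 1) stop("n_qtl must be >= 1", call. = FALSE)
  structure(
    list(n_qtl = n_qtl, r_AB = r_AB, group_ratio = group_ratio,
         var_A = var_A, var_B = var_B, h2_A = h2_A, h2_B = h2_B,
         incidence = incidence, env_corr = env_corr,
         target_correlation = target_correlation),
    class = "ltbc_architecture")
}

# largest-remainder rounding of n * p to integers summing to n
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
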