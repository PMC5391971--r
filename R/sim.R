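#' Simulate the historical (mutation-drift equilibrium) population
#'
#' All loci start monomorphic in the base population; polymorphism arises by
#' allele-state mutation during `n_historical` generations of random mating
#' (each of the `base_size / 2` matings leaves one male and one female
#' offspring), with Haldane-model meiosis along the locus map.
#'
#' @param genome An [genome_config()] object.
#' @param demography A [demography_config()] object.
#' @param seed Optional integer; if given, `set.seed()` is called first.
#' @return An object of class `ltbc_founders`: the generation-0 haplotypes
#'   (loci x 2N matrix of 0/1 allele states) plus the configurations.
#' @export
run_historical <- function(genome, demography, seed = NULL) {
  stopifnot(inherits(genome, "ltbc_genome"), inherits(demography, "ltbc_demography"))
  if (!is.null(seed)) set.seed(seed)
  H <- cpp_sim_history(demography$base_size, demography$n_historical,
                       genome$rec, genome$mutation_rate)
  structure(list(haplotypes = H, genome = genome, demography = demography),
            class = "ltbc_founders")
}

#' Expand the base population and breed the recent generations
#'
#' Generation 1 expands the base to `expansion_size` via equal family sizes
#' (with the defaults, 20 offspring per generation-0 mating, 10 of each sex).
#' Each later generation is produced by `n_sires` randomly selected males,
#' each mated to an equal share of all females, every female leaving one male
#' and one female offspring. New mutation is disabled in these generations;
#' polymorphism is inherited from the equilibrium history.
#'
#' @param founders An `ltbc_founders` object from [run_historical()].
#' @param seed Optional integer seed.
#' @return An object of class `ltbc_pop`: integer dosage matrix `genotypes`
#'   (individuals x all loci, generations 0 to `n_recent`), a `pedigree`
#'   tibble (id, generation, sex, sire, dam), and the configurations.
#' @export
expand_and_breed <- function(founders, seed = NULL) {
  stopifnot(inherits(founders, "ltbc_founders"))
  if (!is.null(seed)) set.seed(seed)
  genome <- founders$genome
  demo <- founders$demography
  rec <- genome$rec
  nb <- demo$base_size
  nexp <- demo$expansion_size
  half <- nb / 2

  ids <- function(gen, n) sprintf("G%d_%04d", gen, seq_len(n))
  ped <- list()
  geno <- list()

  H <- founders$haplotypes
  ped[[1]] <- tibble::tibble(
    id = ids(0, nb), generation = 0L,
    sex = rep(c("M", "F"), each = half), sire = NA_character_, dam = NA_character_)
  geno[[1]] <- cpp_dosage(H)
  rownames(geno[[1]]) <- ped[[1]]$id

  # generation 1: random pairing of the base sexes, equal expanded families
  fam <- nexp / nb * 2            # offspring per mating
  males <- sample.int(half)                 # columns 1..half are males
  females <- half + sample.int(half)
  sire_idx <- rep(males, each = fam)
  dam_idx <- rep(females, each = fam)
  sex <- rep(rep(c("M", "F"), each = fam / 2), half)
  Hoff <- cpp_breed(H, sire_idx - 1L, dam_idx - 1L, rec, 0)
  ped[[2]] <- tibble::tibble(
    id = ids(1, nexp), generation = 1L, sex = sex,
    sire = ped[[1]]$id[sire_idx], dam = ped[[1]]$id[dam_idx])
  geno[[2]] <- cpp_dosage(Hoff)
  rownames(geno[[2]]) <- ped[[2]]$id
  H <- Hoff
  prev <- ped[[2]]

  for (g in seq_len(demo$n_recent - 1) + 1) {
    male_rows <- which(prev$sex == "M")
    female_rows <- which(prev$sex == "F")
    sires <- sample(male_rows, demo$n_sires)
    dams_per_sire <- length(female_rows) / demo$n_sires
    if (dams_per_sire != round(dams_per_sire))
      stop("females must divide evenly among sires", call. = FALSE)
    dam_order <- sample(female_rows)
    sire_of_dam <- rep(sires, each = dams_per_sire)
    # each dam: one male and one female offspring
    sire_idx <- rep(sire_of_dam, each = 2)
    dam_idx <- rep(dam_order, each = 2)
    sex <- rep(c("M", "F"), length(dam_order))
    Hoff <- cpp_breed(H, sire_idx - 1L, dam_idx - 1L, rec, 0)
    n_off <- length(sire_idx)
    ped[[g + 1]] <- tibble::tibble(
      id = ids(g, n_off), generation = as.integer(g), sex = sex,
      sire = prev$id[sire_idx], dam = prev$id[dam_idx])
    geno[[g + 1]] <- cpp_dosage(Hoff)
    rownames(geno[[g + 1]]) <- ped[[g + 1]]$id
    H <- Hoff
    prev <- ped[[g + 1]]
  }

  genotypes <- do.call(rbind, geno)
  colnames(genotypes) <- sprintf("L%05d", genome$loci$locus)
  structure(
    list(genotypes = genotypes, pedigree = dplyr::bind_rows(ped),
         genome = genome, demography = demo),
    class = "ltbc_pop")
}

#' Sample QTL positions and allele-substitution effects
#'
#' QTL are drawn without replacement from the candidate loci that segregate
#' in the training generations. Group sizes follow largest-remainder rounding
#' of `n_qtl * group_ratio`. Pleiotropic pairs are bivariate normal (see
#' [architecture_config()] for the correlation convention); single-trait
#' effects are univariate standard normal with a zero effect on the other
#' trait.
#'
#' @param pop An `ltbc_pop` object.
#' @param architecture An [architecture_config()] object.
#' @param training_generations Generations whose individuals define
#'   segregation (default 1:2).
#' @param seed Optional integer seed.
#' @return A tibble of class `ltbc_qtl` with columns `locus`, `group`
#'   (`"pleiotropic"`, `"A_only"`, `"B_only"`), `a_A`, `a_B`.
#' @export
sample_qtl <- function(pop, architecture, training_generations = 1:2,
                       seed = NULL) {
  stopifnot(inherits(pop, "ltbc_pop"), inherits(architecture, "ltbc_architecture"))
  if (!is.null(seed)) set.seed(seed)
  arch <- architecture
  loci <- pop$genome$loci
  train <- pop$pedigree$generation %in% training_generations
  cand <- which(loci$is_candidate)
  seg <- cand[matrixStats_colVars(pop$genotypes[train, cand, drop = FALSE]) > 0]
  if (length(seg) < arch$n_qtl)
    stop(sprintf(paste0("only %d segregating candidate loci for %d QTL; ",
                        "re-run the history or enlarge the genome"),
                 length(seg), arch$n_qtl), call. = FALSE)

  sizes <- largest_remainder(arch$n_qtl, arch$group_ratio)
  picked <- sample(seg, arch$n_qtl)
  group <- rep(c("pleiotropic", "A_only", "B_only"), times = sizes)

  rho <- qtl_pair_correlation(arch, sizes)
  n1 <- sizes[1]
  a_A <- numeric(arch$n_qtl)
  a_B <- numeric(arch$n_qtl)
  if (n1 > 0) {
    z1 <- rnorm(n1); z2 <- rnorm(n1)
    a_A[group == "pleiotropic"] <- z1
    a_B[group == "pleiotropic"] <- rho * z1 + sqrt(1 - rho^2) * z2
  }
  a_A[group == "A_only"] <- rnorm(sizes[2])
  a_B[group == "B_only"] <- rnorm(sizes[3])

  out <- tibble::tibble(locus = picked, group = group, a_A = a_A, a_B = a_B)
  class(out) <- c("ltbc_qtl", class(out))
  out
}

# effect-pair correlation for the pleiotropic group; under the default
# "genetic" targeting the pair correlation is inflated to undo the dilution
# caused by the single-trait groups
qtl_pair_correlation <- function(arch, sizes) {
  if (sizes[1] == 0) {
    if (arch$r_AB != 0)
      stop("nonzero r_AB requires a pleiotropic QTL group", call. = FALSE)
    return(0)
  }
  if (arch$target_correlation == "effect") return(arch$r_AB)
  rho <- arch$r_AB * sqrt((sizes[1] + sizes[2]) * (sizes[1] + sizes[3])) / sizes[1]
  if (abs(rho) > 1)
    stop("r_AB unreachable with this group ratio (required pair correlation > 1)",
         call. = FALSE)
  rho
}

#' Rescale QTL effects and assign phenotypes
#'
#' Effects are rescaled (per trait) so that the realized variance of the true
#' breeding values in the training generations equals `var_A` / `var_B`.
#' Environmental effects are drawn with variance `var * (1 - h2) / h2`
#' (correlation `env_corr`); trait A phenotypes are TBV + environment, trait B
#' liabilities likewise, and the binary phenotype is 1 when the liability
#' exceeds the empirical `(1 - incidence)` quantile of training liabilities.
#' Phenotypes exist only for training individuals; every genotyped individual
#' keeps its TBVs for validation.
#'
#' @param pop An `ltbc_pop` object.
#' @param qtl An `ltbc_qtl` tibble from [sample_qtl()].
#' @param architecture The [architecture_config()] used.
#' @param training_generations Generations that receive phenotypes.
#' @param seed Optional integer seed.
#' @return An object of class `ltbc_sim` with elements `phenotypes` (tibble:
#'   id, generation, role, pheno_A, pheno_B, liability_B, tbv_A, tbv_B),
#'   `genotypes` (individuals x segregating markers, generations >= 1),
#'   `map` (marker map tibble), `qtl` (rescaled effects), `threshold`,
#'   `v_e1`, `v_e2` (true residual variances; `v_e2` is needed to rescale
#'   bias slopes for the threshold trait), and the configurations.
#' @export
rescale_and_phenotype <- function(pop, qtl, architecture,
                                  training_generations = 1:2, seed = NULL) {
  stopifnot(inherits(pop, "ltbc_pop"), inherits(architecture, "ltbc_architecture"))
  if (!is.null(seed)) set.seed(seed)
  arch <- architecture
  ped <- pop$pedigree
  recent <- ped$generation >= 1L
  train <- ped$generation %in% training_generations

  Zq <- pop$genotypes[, qtl$locus, drop = FALSE]
  tbv_A <- as.numeric(Zq %*% qtl$a_A)
  tbv_B <- as.numeric(Zq %*% qtl$a_B)
  vA <- var(tbv_A[train])
  vB <- var(tbv_B[train])
  if (vA <= 0 || vB <= 0)
    stop("zero realized genetic variance in the training generations", call. = FALSE)
  sA <- sqrt(arch$var_A / vA)
  sB <- sqrt(arch$var_B / vB)
  qtl$a_A <- qtl$a_A * sA
  qtl$a_B <- qtl$a_B * sB
  tbv_A <- tbv_A * sA
  tbv_B <- tbv_B * sB

  v_e1 <- arch$var_A * (1 - arch$h2_A) / arch$h2_A
  v_e2 <- arch$var_B * (1 - arch$h2_B) / arch$h2_B
  n_train <- sum(train)
  eA <- rnorm(n_train, 0, sqrt(v_e1))
  eB_ind <- rnorm(n_train, 0, sqrt(v_e2))
  eB <- arch$env_corr * sqrt(v_e2 / v_e1) * eA +
    sqrt(1 - arch$env_corr^2) * eB_ind

  pheno_A <- rep(NA_real_, nrow(ped))
  liab <- rep(NA_real_, nrow(ped))
  pheno_A[train] <- tbv_A[train] + eA
  liab[train] <- tbv_B[train] + eB

  # threshold at the empirical (1 - incidence) quantile: exactly
  # round(n * incidence) training individuals are scored 1
  k1 <- round(n_train * arch$incidence)
  srt <- sort(liab[train])
  threshold <- srt[n_train - k1]
  pheno_B <- rep(NA_integer_, nrow(ped))
  pheno_B[train] <- as.integer(liab[train] > threshold)

  role <- dplyr::case_when(
    ped$generation %in% training_generations ~ "training",
    ped$generation >= 1L ~ "candidate",
    TRUE ~ "founder")

  phen <- tibble::tibble(
    id = ped$id, generation = ped$generation, role = role,
    pheno_A = pheno_A, pheno_B = pheno_B, liability_B = liab,
    tbv_A = tbv_A, tbv_B = tbv_B)[recent, ]

  loci <- pop$genome$loci
  markers <- which(loci$is_marker)
  Zm <- pop$genotypes[recent, markers, drop = FALSE]
  seg <- matrixStats_colVars(Zm) > 0
  Zm <- Zm[, seg, drop = FALSE]
  map <- tibble::tibble(
    snp = colnames(Zm),
    locus = loci$locus[markers][seg],
    chrom = loci$chrom[markers][seg],
    pos = loci$pos[markers][seg])

  structure(
    list(phenotypes = phen, genotypes = Zm, map = map, qtl = qtl,
         threshold = threshold, v_e1 = v_e1, v_e2 = v_e2,
         architecture = arch, genome = pop$genome,
         demography = pop$demography, pedigree = ped[recent, ]),
    class = "ltbc_sim")
}

#' Simulate a complete two-trait dataset
#'
#' Runs the full pipeline: mutation-drift history, population expansion and
#' breeding, QTL sampling, rescaling and phenotyping. A single seed makes the
#' whole dataset reproducible bit-for-bit.
#'
#' @param genome,demography,architecture Configuration objects.
#' @param seed Integer seed for the whole pipeline.
#' @param training_generations Generations that receive phenotypes.
#' @return An `ltbc_sim` object; see [rescale_and_phenotype()].
#' @export
simulate_dataset <- function(genome = genome_config(),
                             demography = demography_config(),
                             architecture = architecture_config(),
                             seed = NULL, training_generations = 1:2) {
  if (!is.null(seed)) set.seed(seed)
  founders <- run_historical(genome, demography)
  pop <- expand_and_breed(founders)
  qtl <- sample_qtl(pop, architecture, training_generations)
  rescale_and_phenotype(pop, qtl, architecture, training_generations)
}

# column variances without matrixStats (integer-safe)
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' @export
print.ltbc_sim <- function(x, ...) {
  cat("Simulated two-trait dataset\n")
  cat(sprintf("  individuals: %d (%d training, %d candidates)\n",
              nrow(x$phenotypes), sum(x$phenotypes$role == "training"),
              sum(x$phenotypes$role == "candidate")))
  cat(sprintf("  segregating markers: %d; QTL: %d\n",
              ncol(x$genotypes), nrow(x$qtl)))
  cat(sprintf("  incidence target %.3f; liability threshold %.3f; v_e2 = %.3f\n",
              x$architecture$incidence, x$threshold, x$v_e2))
  invisible(x)
}
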