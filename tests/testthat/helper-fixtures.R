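# Shared small-scale fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small two-trait dataset with decent signal, used across modules
small_sim <- function() {
  memo("small_sim", {
    g <- genome_config(n_chromosomes = 2, n_markers_per_chrom = 100,
                       chrom_length = 1)
    d <- demography_config(base_size = 40, n_historical = 300,
                           expansion_size = 200, n_sires = 10)
    a <- architecture_config(n_qtl = 20, r_AB = 0.5, h2_A = 0.5, h2_B = 0.3,
                             incidence = 0.3)
    simulate_dataset(g, d, a, seed = 42)
  })
}

# a small population (pre-QTL) for Mendelian / pedigree checks
small_pop <- function() {
  memo("small_pop", {
    g <- genome_config(n_chromosomes = 2, n_markers_per_chrom = 80,
                       chrom_length = 1)
    d <- demography_config(base_size = 20, n_historical = 400,
                           expansion_size = 100, n_sires = 5)
    set.seed(7)
    expand_and_breed(run_historical(g, d))
  })
}

# genotype matrix drawn marker-by-marker from binomial allele frequencies
sim_genotypes <- function(n, q, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(q, 0.1, 0.5)
  Z <- sapply(maf, function(p) rbinom(n, 2, p))
  rownames(Z) <- sprintf("ind%04d", seq_len(n))
  colnames(Z) <- sprintf("snp%04d", seq_len(q))
  Z
}
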