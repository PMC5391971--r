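test_that("Haldane map function evaluates correctly and respects its bounds", {
  expect_equal(haldane(0.0005), (1 - exp(-0.001)) / 2)
  expect_equal(haldane(0.0005), 0.00049975, tolerance = 1e-6)
  expect_equal(haldane(0), 0)
  d <- seq(0, 5, by = 0.1)
  r <- haldane(d)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 0.5))
})

test_that("no mutation means no polymorphism after any number of generations", {
  g <- genome_config(n_chromosomes = 1, n_markers_per_chrom = 20,
                     mutation_rate = 0)
  d <- demography_config(base_size = 20, n_historical = 50,
                         expansion_size = 40, n_sires = 5)
  f <- run_historical(g, d, seed = 3)
  expect_true(all(f$haplotypes == 0))
})

test_that("mutation-drift history reproduces its frozen summary", {
  # reduced-scale regression fixture (the full design is 5 x 2000 markers and
  # is exercised only in full-scale runs): frozen after a single run
  g <- genome_config(n_chromosomes = 2, n_markers_per_chrom = 500,
                     chrom_length = 1)
  d <- demography_config(base_size = 100, n_historical = 1000,
                         expansion_size = 1000)
  f <- run_historical(g, d, seed = 42)
  dos <- ltbayescpi:::cpp_dosage(f$haplotypes)
  mk <- which(g$loci$is_marker)
  p <- colMeans(dos[, mk]) / 2
  maf <- pmin(p, 1 - p)
  expect_identical(sum(maf > 0), 986L)
  expect_equal(mean(maf[maf > 0]), 0.2557404, tolerance = 1e-6)
  # a substantial fraction segregates at intermediate frequency
  expect_gt(mean(maf > 0.05), 0.5)
})

test_that("breeding design produces the stated generation sizes", {
  g <- genome_config(n_chromosomes = 1, n_markers_per_chrom = 20)
  d <- demography_config()  # the full demographic design
  f <- run_historical(g, d, seed = 5)
  # shorten the history for speed: sizes do not depend on it
  f$demography$n_historical <- 0
  pop <- expand_and_breed(f, seed = 6)
  sizes <- table(pop$pedigree$generation)
  expect_equal(unname(sizes[as.character(1:6)]), rep(1000, 6),
               ignore_attr = TRUE)
  expect_equal(unname(sizes["0"]), 100, ignore_attr = TRUE)
})

test_that("transmission is Mendelian-consistent and dosages stay in 0..2", {
  pop <- small_pop()
  Z <- pop$genotypes
  expect_true(all(Z %in% 0:2))
  ped <- pop$pedigree
  off <- ped[ped$generation >= 1, ]
  si <- match(off$sire, ped$id)
  di <- match(off$dam, ped$id)
  Zs <- Z[si, , drop = FALSE]
  Zd <- Z[di, , drop = FALSE]
  Zo <- Z[match(off$id, ped$id), , drop = FALSE]
  lo <- (Zs == 2) + (Zd == 2)
  hi <- 2 - ((Zs == 0) + (Zd == 0))
  expect_true(all(Zo >= lo & Zo <= hi))
})

test_that("zero genetic length makes whole chromosomes co-segregate", {
  # with rec = 0 inside a chromosome a gamete never switches strands, so
  # every transmitted chromosome equals one parental strand exactly
  g <- genome_config(n_chromosomes = 2, n_markers_per_chrom = 30,
                     chrom_length = 0, mutation_rate = 0.01)
  d <- demography_config(base_size = 20, n_historical = 40,
                         expansion_size = 40, n_sires = 5)
  f <- run_historical(g, d, seed = 11)
  H <- f$haplotypes
  np <- ncol(H) / 2
  set.seed(99)
  off <- ltbayescpi:::cpp_breed(H, 0L, as.integer(np - 1), f$genome$rec, 0)
  chrom <- f$genome$loci$chrom
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    expect_true(identical(off[idx, 1], H[idx, 1]) ||
                  identical(off[idx, 1], H[idx, 2]))
    expect_true(identical(off[idx, 2], H[idx, 2 * np - 1]) ||
                  identical(off[idx, 2], H[idx, 2 * np]))
  }
})

test_that("QTL group sizes follow the ratio with largest-remainder rounding", {
  pop <- small_pop()
  a0 <- architecture_config(n_qtl = 60, r_AB = 0)     # forced 0 : 0.5 : 0.5
  q0 <- sample_qtl(pop, a0, seed = 21)
  expect_equal(unname(table(factor(q0$group,
    c("pleiotropic", "A_only", "B_only")))), c(0, 30, 30), ignore_attr = TRUE)

  a5 <- architecture_config(n_qtl = 60, r_AB = 0.5)   # 0.8 : 0.1 : 0.1
  q5 <- sample_qtl(pop, a5, seed = 22)
  expect_equal(unname(table(factor(q5$group,
    c("pleiotropic", "A_only", "B_only")))), c(48, 6, 6), ignore_attr = TRUE)

  # A-only QTL have no effect on B and vice versa
  expect_true(all(q5$a_B[q5$group == "A_only"] == 0))
  expect_true(all(q5$a_A[q5$group == "B_only"] == 0))

  expect_error(sample_qtl(pop, architecture_config(n_qtl = 10000)),
               "segregating")
})

test_that("pleiotropic effect pairs reproduce the target pair correlation", {
  pop <- small_pop()
  a <- architecture_config(n_qtl = 60, r_AB = 0.8,
                           target_correlation = "effect")
  set.seed(33)
  pairs <- do.call(rbind, lapply(1:25, function(i) {
    q <- sample_qtl(pop, a)
    cbind(q$a_A[q$group == "pleiotropic"], q$a_B[q$group == "pleiotropic"])
  }))
  expect_gte(nrow(pairs), 1000)
  expect_equal(cor(pairs[, 1], pairs[, 2]), 0.8, tolerance = 0.04)
})

test_that("rescaling hits the variance targets and the incidence exactly", {
  dat <- small_sim()
  tr <- dat$phenotypes[dat$phenotypes$role == "training", ]
  expect_equal(var(tr$tbv_A), 2.0, tolerance = 1e-9)
  expect_equal(var(tr$tbv_B), 1.0, tolerance = 1e-9)
  # threshold at the empirical quantile: case count exact up to rounding
  expect_lte(abs(sum(tr$pheno_B) - round(nrow(tr) * 0.3)), 1)
  # residual liability variance v_e2 = var_B (1 - h2_B) / h2_B
  expect_equal(dat$v_e2, 1.0 * (1 - 0.3) / 0.3) # h2_B = 0.3 fixture
  pop <- small_pop()
  a9 <- architecture_config(n_qtl = 10, h2_B = 0.1, var_B = 1.0)
  d9 <- rescale_and_phenotype(pop, sample_qtl(pop, a9, seed = 8), a9, seed = 9)
  expect_equal(d9$v_e2, 9.0)
})

test_that("thresholding conserves liability ranks", {
  dat <- small_sim()
  tr <- dat$phenotypes[dat$phenotypes$role == "training", ]
  o1 <- order(tr$liability_B)
  o2 <- order(tr$pheno_B, tr$liability_B)
  expect_identical(o1, o2)
})

test_that("the simulator is deterministic given a seed", {
  g <- genome_config(n_chromosomes = 1, n_markers_per_chrom = 40)
  d <- demography_config(base_size = 20, n_historical = 60,
                         expansion_size = 40, n_sires = 5)
  a <- architecture_config(n_qtl = 5)
  d1 <- simulate_dataset(g, d, a, seed = 77)
  d2 <- simulate_dataset(g, d, a, seed = 77)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$qtl, d2$qtl)
})

test_that("realized genetic correlation targets r_AB across replicates", {
  g <- genome_config(n_chromosomes = 2, n_markers_per_chrom = 150,
                     chrom_length = 0.15)
  d <- demography_config(base_size = 60, n_historical = 500,
                         expansion_size = 600, n_sires = 30)
  a <- architecture_config(n_qtl = 60, r_AB = 0.5)
  rs <- vapply(1:20, function(r) {
    dat <- simulate_dataset(g, d, a, seed = 1000 + r)
    tr <- dat$phenotypes[dat$phenotypes$role == "training", ]
    cor(tr$tbv_A, tr$tbv_B)
  }, 0.0)
  expect_equal(mean(rs), 0.5, tolerance = 0.06)
})

test_that("configuration errors are caught", {
  expect_error(demography_config(base_size = 0), "even")
  expect_error(demography_config(base_size = 15), "even")
  expect_error(genome_config(mutation_rate = -1), "mutation_rate")
  expect_error(architecture_config(group_ratio = c(0.5, 0.5, 0.5)), "sum")
  expect_error(architecture_config(incidence = 0), "incidence")
})
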