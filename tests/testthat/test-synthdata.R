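test_that("simulated trial has the configured dimensions and metadata", {
  cfg <- sim_config(n_families = 49, offspring_per_family = 10,
                    n_markers = 220, n_chromosomes = 11,
                    traits = list(), seed = 11)
  dat <- simulate_genotypes(cfg)
  expect_equal(nrow(dat$geno$codes), 490)
  expect_equal(ncol(dat$geno$codes), 220)
  expect_equal(length(unique(dat$geno$map$chrom)), 11)
  # positions sorted within each chromosome
  for (ch in unique(dat$geno$map$chrom)) {
    expect_false(is.unsorted(dat$geno$map$pos[dat$geno$map$chrom == ch]))
  }
  expect_equal(nrow(dat$ped), 49 + 490)
  expect_true(all(dat$ped$sire == "0"))
  expect_equal(sort(unique(dat$subpop)), c("P1", "P2", "P3"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_markers = 5, n_chromosomes = 11), "n_markers")
  expect_error(trait_arch("x", n_qtl = 2, qtl_variance_fractions = 0.4,
                          polygenic_h2 = 0.2, marker_h2 = 0.1),
               "more than 1")
  dat <- small_trial(seed = 2, n_markers = 50)
  expect_error(simulate_phenotypes(dat$geno, dat$ped,
                                   trait_arch("x", n_qtl = 60,
                                              qtl_variance_fractions = 0.001,
                                              polygenic_h2 = 0, marker_h2 = 0),
                                   dat$blocks),
               "exceeds marker count")
})

test_that("same seed gives bit-identical simulations", {
  cfg <- sim_config(n_families = 10, offspring_per_family = 5, n_markers = 80,
                    n_chromosomes = 4,
                    traits = list(trait_arch("T", n_qtl = 3,
                                             qtl_variance_fractions = 0.05,
                                             polygenic_h2 = 0.2,
                                             marker_h2 = 0.1)),
                    seed = 99)
  expect_identical(sim_trial(cfg), sim_trial(cfg))
})

test_that("no differentiation is simulated when a single panmictic pool is requested", {
  cfg <- sim_config(n_families = 40, offspring_per_family = 2,
                    n_markers = 2000, n_chromosomes = 10, n_subpops = 1,
                    target_fst = 0, traits = list(), seed = 5)
  dat <- simulate_genotypes(cfg)
  # split founders into arbitrary halves: F_ST should vanish
  half <- rep(c("a", "b"), length.out = nrow(dat$founder_geno$codes))
  fst <- pairwise_fst(dat$founder_geno, half)
  expect_lt(abs(fst["a", "b"]), 0.02)
})

test_that("founder divergence reaches the Balding-Nichols target", {
  est <- sapply(1:3, function(s) {
    cfg <- sim_config(n_families = 48, offspring_per_family = 2,
                      n_markers = 2000, n_chromosomes = 10, n_subpops = 3,
                      target_fst = 0.25, traits = list(), seed = 100 + s)
    dat <- simulate_genotypes(cfg)
    fst <- pairwise_fst(dat$founder_geno,
                        dat$subpop[rownames(dat$founder_geno$codes)])
    mean(fst[upper.tri(fst)])
  })
  # oracle: the generating divergence parameter (pairwise expectation 0.25)
  expect_lt(abs(mean(est) - 0.25), 0.05)
})

test_that("offspring are Mendelian-consistent with their dam under selfing", {
  cfg <- sim_config(n_families = 15, offspring_per_family = 6, n_markers = 150,
                    n_chromosomes = 3, selfing_rate = 1, traits = list(),
                    seed = 31)
  dat <- simulate_genotypes(cfg)
  fam <- rep(seq_len(15), each = 6)
  for (i in seq_len(nrow(dat$geno$codes))) {
    dam <- dat$founder_geno$codes[fam[i], ]
    off <- dat$geno$codes[i, ]
    # a selfed offspring cannot carry an allele its dam lacks
    expect_true(all(off[dam == 0] == 0))
    expect_true(all(off[dam == 2] == 2))
  }
})

test_that("a signal-free architecture leaves only block and residual variance", {
  arch <- trait_arch("null", n_qtl = 0, polygenic_h2 = 0, marker_h2 = 0)
  cfg <- sim_config(n_markers = 100, n_chromosomes = 5, n_subpops = 1,
                    target_fst = 0, traits = list(arch),
                    block_variance = 0.3, seed = 8)
  dat <- sim_trial(cfg)
  expect_lt(abs(var(dat$pheno$null) - (0.3 + 1)), 0.1 * 1.3)
  expect_equal(unname(dat$truth$null$realized_h2_components),
               c(0, 0, 0))
})

test_that("ordinal traits land on the declared level sets", {
  arch4 <- trait_arch("STR", n_qtl = 0, polygenic_h2 = 0.2, marker_h2 = 0.1,
                      scale = ordinal_scale(4, start = 0L))
  arch5 <- trait_arch("BHT", n_qtl = 0, polygenic_h2 = 0.2, marker_h2 = 0.1,
                      scale = ordinal_scale(5, start = 1L))
  cfg <- sim_config(n_families = 20, offspring_per_family = 8, n_markers = 100,
                    n_chromosomes = 5, n_subpops = 1, target_fst = 0,
                    traits = list(arch4, arch5), seed = 3)
  dat <- sim_trial(cfg)
  expect_true(all(dat$pheno$STR %in% 0:3))
  expect_true(all(dat$pheno$BHT %in% 1:5))
})

test_that("realized per-QTL variance tracks the architecture target over seeds", {
  arch <- trait_arch("T", n_qtl = 1, qtl_variance_fractions = 0.05,
                     polygenic_h2 = 0.15, marker_h2 = 0.1)
  realized <- sapply(1:10, function(s) {
    dat <- small_trial(seed = 300 + s, n_families = 25, offspring = 8,
                       n_markers = 150, traits = list(arch))
    unname(dat$truth$T$realized_h2_components["qtl"])
  })
  expect_lt(abs(mean(realized) - 0.05) / 0.05, 0.3)
})
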