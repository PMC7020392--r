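test_that("BH + alpha gating matches the hand-computed toy selection", {
  res <- data.frame(marker = paste0("m", 1:5), chrom = "1", pos = 1:5,
                    effect = 0, se = 1,
                    p_value = c(1e-4, 5e-4, 2e-3, 3e-2, 0.5),
                    variance_explained = 0.01)
  sel <- select_mtas(res, alpha = 0.001, fdr_max = 0.10)
  # BH at m = 5: q = (5e-4, 1.25e-3, 3.33e-3, 3.75e-2, 0.5); the p < 0.001
  # gate excludes m3 despite its BH pass
  expect_equal(sel$marker, c("m1", "m2"))
  expect_equal(attr(sel, "all")$q_value,
               c(5e-4, 1.25e-3, 2e-3 * 5 / 3, 3.75e-2, 0.5))

  res$p_value <- rep(1, 5)
  expect_equal(nrow(select_mtas(res)), 0L)

  one <- res[1, ]; one$p_value <- 5e-4
  sel1 <- select_mtas(one)
  expect_equal(nrow(sel1), 1L)
  expect_equal(sel1$q_value, 5e-4)
})

test_that("selection output is a stable subset of its input", {
  set.seed(9)
  res <- data.frame(marker = paste0("m", 1:200), chrom = "1", pos = 1:200,
                    effect = 0, se = 1,
                    p_value = c(runif(5, 0, 5e-4), runif(195)),
                    variance_explained = 0)
  sel <- select_mtas(res)
  expect_true(all(sel$marker %in% res$marker))
  resel <- select_mtas(sel[, names(res)])
  expect_true(all(resel$marker %in% sel$marker))
})

test_that("a strong simulated QTL attains the scan minimum p-value", {
  arch <- trait_arch("T", n_qtl = 1, qtl_variance_fractions = 0.20,
                     polygenic_h2 = 0.1, marker_h2 = 0.05)
  cfg <- sim_config(n_markers = 500, n_chromosomes = 5, n_subpops = 1,
                    target_fst = 0, traits = list(arch), seed = 17)
  dat <- sim_trial(cfg)
  adj <- adjust_phenotypes(dat$pheno, "T")
  scan <- scan_markers(adj, dat$geno, marker_kinship(dat$geno))
  expect_equal(which.min(scan$p_value), dat$truth$T$qtl_marker_indices)
})

test_that("null-trait p-values are uniform and type-I error is nominal", {
  arch <- trait_arch("null", n_qtl = 0, polygenic_h2 = 0, marker_h2 = 0)
  pv <- unlist(lapply(1:5, function(s) {
    cfg <- sim_config(n_markers = 1000, n_chromosomes = 10, n_subpops = 1,
                      target_fst = 0, traits = list(arch), seed = 400 + s)
    dat <- sim_trial(cfg)
    adj <- adjust_phenotypes(dat$pheno, "null")
    scan_markers(adj, dat$geno, marker_kinship(dat$geno))$p_value
  }))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  # mean count of p < 0.001 per 1,000-marker scan stays near its expectation
  expect_lte(sum(pv < 0.001) / 5, 5)
})

test_that("degenerate markers are skipped with a warning", {
  dat <- small_trial(seed = 3, n_markers = 50,
                     traits = list(trait_arch("T", polygenic_h2 = 0.2,
                                              marker_h2 = 0)))
  codes <- dat$geno$codes
  codes[, 1] <- 1L  # constant marker slipped past QC
  g <- toy_geno(codes, chrom = dat$geno$map$chrom, pos = dat$geno$map$pos)
  adj <- adjust_phenotypes(dat$pheno, "T")
  expect_warning(scan <- scan_markers(adj, g, marker_kinship(dat$geno)),
                 "skipped")
  expect_true(is.na(scan$p_value[1]))
})

test_that("single-marker variance explained matches its R-squared meaning", {
  g <- toy_geno(cbind(m1 = c(0L, 1L, 2L, 0L, 1L, 2L),
                      m2 = c(0L, 0L, 1L, 1L, 2L, 2L)))
  y <- c(0, 1, 2, 0, 1, 2); names(y) <- rownames(g$codes)
  expect_equal(variance_explained(y, g, "m1"), 1)
  y2 <- c(1, -1, 0, -1, 1, 0); names(y2) <- rownames(g$codes)
  expect_lt(variance_explained(y2, g, "m1"), 1e-10)

  ve <- sapply(1:20, function(s) {
    arch <- trait_arch("T", n_qtl = 1, qtl_variance_fractions = 0.05,
                       polygenic_h2 = 0.1, marker_h2 = 0.05)
    cfg <- sim_config(n_markers = 60, n_chromosomes = 3, n_subpops = 1,
                      target_fst = 0, traits = list(arch), seed = 900 + s)
    dat <- sim_trial(cfg)
    adj <- adjust_phenotypes(dat$pheno, "T")
    variance_explained(adj$y_star, dat$geno,
                       dat$truth$T$qtl_marker_indices)
  })
  expect_lt(abs(mean(ve) - 0.05), 0.02)
})
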