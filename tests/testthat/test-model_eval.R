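test_that("heritability ratios follow the common-denominator definition", {
  h <- heritabilities(1, 1, 1, 1)
  expect_equal(c(h$h2_a, h$h2_m, h$h2_q), c(0.25, 0.25, 0.25))
  h2 <- heritabilities(2, 1, 1, 4)
  expect_equal(c(h2$h2_a, h2$h2_m, h2$h2_q), c(0.25, 0.125, 0.125))
  hgs <- heritabilities(1, 1, NULL, 2)   # GS: no QTL-genotype term
  expect_equal(c(hgs$h2_a, hgs$h2_m, hgs$h2_q), c(0.25, 0.25, 0))
  expect_error(heritabilities(0, 0, 0, 0), "all-zero")
})

test_that("heritabilities are scale-invariant and per-draw averaged", {
  set.seed(1)
  a <- rgamma(200, 2); m <- rgamma(200, 2); q <- rgamma(200, 2)
  e <- rgamma(200, 2)
  h1 <- heritabilities(a, m, q, e)
  h2 <- heritabilities(7 * a, 7 * m, 7 * q, 7 * e)
  expect_equal(h1$h2_a, h2$h2_a)
  expect_equal(h1$h2_m, mean(m / (a + m + q + e)))  # mean of ratios
})

test_that("DIC arithmetic and invariances hold", {
  d <- dic(c(10, 12), d_at_mean = 9)
  expect_equal(d$d_bar, 11)
  expect_equal(d$p_d, 2)
  expect_equal(d$dic, 13)
  # degenerate posterior: all draws equal the plug-in deviance
  d0 <- dic(c(5, 5, 5), 5)
  expect_equal(d0$p_d, 0)
  expect_equal(d0$dic, 5)
  set.seed(2)
  dd <- rnorm(500, 100, 3)
  expect_equal(dic(dd, 95)$dic, dic(rev(dd), 95)$dic)
  expect_error(dic(c(1, Inf), 1), "non-finite")
  expect_error(dic(3, 1), "at least 2")
})

test_that("pD matches the conjugate normal-mean shrinkage factor", {
  # y_i ~ N(theta, s2) with s2 known, theta ~ N(0, tau2):
  # analytic pD = n * tau2 / (s2 + n tau2)
  set.seed(11)
  n <- 25; s2 <- 2; tau2 <- 0.5
  y <- rnorm(n, 1, sqrt(s2))
  vpost <- 1 / (n / s2 + 1 / tau2)
  mpost <- vpost * sum(y) / s2
  theta <- rnorm(2e5, mpost, sqrt(vpost))
  dev <- sapply(theta, function(t) n * log(2 * pi * s2) + sum((y - t)^2) / s2)
  d_at_mean <- n * log(2 * pi * s2) + sum((y - mpost)^2) / s2
  expect_lt(abs(dic(dev, d_at_mean)$p_d - n * tau2 / (s2 + n * tau2)), 0.1)
})

test_that("delta-DIC verdicts follow the 5/10 decision bands", {
  d1 <- delta_dic(1968.9, 1951.2)
  expect_equal(d1$delta, 17.7)
  expect_equal(d1$verdict, "strong")
  expect_equal(d1$favors, "GSq")

  d2 <- delta_dic(947.7, 947.0)
  expect_equal(d2$delta, 0.7)
  expect_equal(d2$verdict, "not significant")

  d3 <- delta_dic(2042.0, 2070.3)
  expect_equal(d3$delta, -28.3)
  expect_equal(d3$verdict, "strong")
  expect_equal(d3$favors, "GS")

  expect_equal(delta_dic(100, 92)$verdict, "substantial")
})

test_that("predictive ability is the Pearson correlation with guard rails", {
  y <- c(1, 2, 3, 4)
  expect_equal(predictive_ability(y, y), 1)
  expect_equal(predictive_ability(y, -y), -1)
  expect_equal(predictive_ability(y, c(1, 3, 2, 4)), 0.8)  # hand Pearson
  expect_message(pa <- predictive_ability(y, rep(1, 4)), "zero variance")
  expect_true(is.na(pa))
  expect_error(predictive_ability(1:2, 1:2), "length")
})

test_that("cross-validation partitions cleanly and is seed-deterministic", {
  dat <- small_trial(seed = 52, n_families = 12, offspring = 5,
                     n_markers = 60,
                     traits = list(trait_arch("T", n_qtl = 1,
                                              qtl_variance_fractions = 0.15,
                                              polygenic_h2 = 0.2,
                                              marker_h2 = 0.1)))
  adj <- adjust_phenotypes(dat$pheno, "T")
  spec <- model_spec("BRR", "GS", kernels = list(A = offspring_A(dat)),
                     niter = 600, burnin = 150, thin = 3, seed = 5)
  cv <- cross_validate(adj, dat$geno, spec, n_folds = 5, seed = 31)
  expect_equal(as.integer(table(cv$folds)), rep(12L, 5))
  expect_equal(sort(names(cv$folds)), sort(names(adj$y_star)))
  expect_true(all(cv$pa >= -1 & cv$pa <= 1))
  cv2 <- cross_validate(adj, dat$geno, spec, n_folds = 5, seed = 31)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$pa, cv2$pa)
  expect_error(cross_validate(adj, dat$geno, spec, n_folds = 100, seed = 1),
               "folds")
})

test_that("oracle predictions cap predictive ability near the heritability root", {
  # feeding true breeding values as the predictor: corr(y*, g) ~ h
  pa <- sapply(1:5, function(s) {
    arch <- trait_arch("T", n_qtl = 4, qtl_variance_fractions = 0.05,
                       polygenic_h2 = 0.1, marker_h2 = 0.1)  # h2 = 0.4
    cfg <- sim_config(n_markers = 200, n_chromosomes = 5, n_subpops = 1,
                      target_fst = 0, traits = list(arch), seed = 600 + s)
    dat <- sim_trial(cfg)
    adj <- adjust_phenotypes(dat$pheno, "T")
    tbv <- dat$truth$T$true_breeding_values[names(adj$y_star)]
    predictive_ability(adj$y_star, tbv)
  })
  expect_lt(abs(mean(pa) - sqrt(0.4)), 0.1)
})

test_that("with no true QTLs the DIC comparison does not favor the QTL model", {
  outcome <- sapply(1:6, function(s) {
    arch <- trait_arch("null", n_qtl = 0, polygenic_h2 = 0.15,
                       marker_h2 = 0.1)
    cfg <- sim_config(n_markers = 600, n_chromosomes = 6, n_subpops = 1,
                      target_fst = 0, traits = list(arch), seed = 7000 + s)
    dat <- sim_trial(cfg)
    adj <- adjust_phenotypes(dat$pheno, "null")
    sel <- select_mtas(scan_markers(adj, dat$geno, marker_kinship(dat$geno)))
    sig <- match(sel$marker, colnames(dat$geno$codes))
    # an empty MTA set leaves nothing for the QTL model to claim
    if (length(sig) == 0) return("not significant")
    A <- offspring_A(dat)
    fit2 <- function(spec) dic_from_fit(fit_wgr(adj, dat$geno, spec))
    d_gs <- fit2(model_spec("BRR", "GS", kernels = list(A = A),
                            niter = 2000, burnin = 500, thin = 3, seed = s))
    d_gsq <- fit2(model_spec("BRR", "GSq",
                             marker_set = setdiff(seq_len(600), sig),
                             significant_markers = sig,
                             kernels = list(A = A, Q = qtl_Q(dat$geno, sig)),
                             niter = 2000, burnin = 500, thin = 3, seed = s))
    dd <- delta_dic(d_gs, d_gsq)
    if (dd$verdict == "not significant") dd$verdict else dd$favors
  })
  expect_gte(sum(outcome %in% c("not significant", "GS")), 4)
})
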