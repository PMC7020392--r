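ridge_fixture <- function(seed = 42, n = 40, p = 15) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * p, TRUE), n, p,
              dimnames = list(paste0("i", 1:n), paste0("m", 1:p)))
  Xc <- scale(X, scale = FALSE)
  y <- drop(Xc %*% rnorm(p, 0, 0.3)) + rnorm(n)
  y <- y - mean(y)
  names(y) <- rownames(X)
  list(X = X, Xc = Xc, y = y, geno = toy_geno(X))
}

test_that("fixed-variance BRR matches the closed-form ridge solution", {
  fx <- ridge_fixture()
  s2m <- 0.09; s2e <- 1
  spec <- model_spec("BRR", "GS", kernels = list(),
                     niter = 8000, burnin = 1000, thin = 2, seed = 5,
                     hyper = list(fix_sigma_snp = s2m, fix_sigma_e = s2e))
  fit <- fit_wgr(fx$y, fx$geno, spec)
  ridge <- solve(crossprod(fx$Xc) + diag(s2e / s2m, ncol(fx$Xc)),
                 crossprod(fx$Xc, fx$y))
  expect_lt(max(abs(fit$m - drop(ridge))), 0.05)
})

test_that("Bayes C-pi with the spike disabled reduces to BRR", {
  fx <- ridge_fixture(seed = 7)
  sp_c <- model_spec("BayesCpi", "GS", kernels = list(), niter = 8000,
                     burnin = 1000, thin = 2, seed = 5,
                     hyper = list(pi_fixed = 0))
  sp_b <- model_spec("BRR", "GS", kernels = list(), niter = 8000,
                     burnin = 1000, thin = 2, seed = 5)
  expect_lt(max(abs(fit_wgr(fx$y, fx$geno, sp_c)$m -
                      fit_wgr(fx$y, fx$geno, sp_b)$m)), 0.03)
})

test_that("chains are bit-identical under the same seed for every method", {
  fx <- ridge_fixture(seed = 3, n = 30, p = 10)
  for (meth in c("BRR", "BayesA", "BayesB", "BayesCpi")) {
    spec <- model_spec(meth, "GS", kernels = list(A = rel_matrix(
      diag(30) |> `dimnames<-`(list(names(fx$y), names(fx$y))),
      kind = "pedigreeA")), niter = 600, burnin = 100, thin = 2, seed = 77)
    f1 <- fit_wgr(fx$y, fx$geno, spec)
    f2 <- fit_wgr(fx$y, fx$geno, spec)
    expect_identical(f1$draws, f2$draws)
    expect_identical(f1$m, f2$m)
  }
})

test_that("a signal-free fit centers on zero with positive variance draws", {
  y <- setNames(rnorm(50, 0, 0.1) * 0, paste0("i", 1:50))
  g <- toy_geno(matrix(integer(0), 50, 0,
                       dimnames = list(names(y), NULL)))
  A <- rel_matrix(diag(50) |> `dimnames<-`(list(names(y), names(y))),
                  kind = "pedigreeA")
  spec <- model_spec("BRR", "GS", kernels = list(A = A), niter = 2000,
                     burnin = 500, thin = 2, seed = 9)
  fit <- fit_wgr(y, g, spec)
  expect_lt(abs(fit$mu), 0.05)
  expect_true(all(fit$draws$sigma2_e > 0))
  expect_true(all(fit$draws$sigma2_k > 0))
})

test_that("deviance draws are finite and pD is non-negative for all methods", {
  dat <- small_trial(seed = 88, n_families = 12, offspring = 5,
                     n_markers = 80,
                     traits = list(trait_arch("T", n_qtl = 2,
                                              qtl_variance_fractions = 0.1,
                                              polygenic_h2 = 0.2,
                                              marker_h2 = 0.1)))
  adj <- adjust_phenotypes(dat$pheno, "T")
  A <- offspring_A(dat)
  for (meth in c("BRR", "BayesA", "BayesB", "BayesCpi")) {
    spec <- model_spec(meth, "GS", kernels = list(A = A), niter = 1500,
                       burnin = 500, thin = 2, seed = 21)
    fit <- fit_wgr(adj, dat$geno, spec)
    expect_true(all(is.finite(fit$draws$deviance)))
    d <- dic_from_fit(fit)
    expect_gte(d$p_d, 0)
    expect_true(all(fit$draws$pi_zero >= 0 & fit$draws$pi_zero <= 1))
    nret <- (spec$niter - spec$burnin) / spec$thin
    expect_equal(length(fit$draws$deviance), nret)
  }
})

test_that("prior-only runs recover the hyperprior means", {
  y <- setNames(rnorm(40), paste0("i", 1:40))
  g <- toy_geno(matrix(sample(0:2, 40 * 20, TRUE), 40, 20,
                       dimnames = list(names(y), paste0("m", 1:20))))
  spec <- model_spec("BRR", "GS", kernels = list(), niter = 30000,
                     burnin = 2000, thin = 5, seed = 13,
                     hyper = list(prior_only = TRUE))
  fit <- fit_wgr(y, g, spec)
  df <- spec$hyper$df
  S_e <- (1 - spec$hyper$R2) * var(y) * (df - 2) / df
  prior_mean <- S_e * df / (df - 2)
  expect_lt(abs(mean(fit$draws$sigma2_e) - prior_mean) / prior_mean, 0.15)
})

test_that("marker-variance draws follow the allele-frequency weighting", {
  mock <- structure(list(m = c(m1 = 0.1),
                         maf = 0.5,
                         draws = list(snp_var = matrix(1, 1, 1),
                                      sigma2_e = 1),
                         spec = list(method = "BRR")), class = "wgr_fit")
  expect_equal(marker_variance(mock), 2 * 1 * 0.25)

  mock2 <- structure(list(m = c(m1 = 0, m2 = 0),
                          maf = c(0.1, 0.2),
                          draws = list(snp_var = matrix(c(1, 2), 1, 2),
                                       sigma2_e = 1),
                          spec = list(method = "BayesA")), class = "wgr_fit")
  expect_equal(marker_variance(mock2), 2 * (0.09 * 1 + 0.16 * 2))
  expect_equal(marker_variance(mock2), 0.82)
  expect_error(marker_variance(mock2, maf = c(0.6, 0.2)), "maf")

  empty <- structure(list(m = setNames(numeric(0), character(0)),
                          maf = numeric(0),
                          draws = list(snp_var = matrix(0, 3, 1),
                                       sigma2_e = rep(1, 3)),
                          spec = list(method = "BRR")), class = "wgr_fit")
  expect_equal(marker_variance(empty), c(0, 0, 0))
})

test_that("training-individual predictions equal fitted genetic values", {
  dat <- small_trial(seed = 61, n_families = 10, offspring = 5,
                     n_markers = 60,
                     traits = list(trait_arch("T", n_qtl = 1,
                                              qtl_variance_fractions = 0.1,
                                              polygenic_h2 = 0.2,
                                              marker_h2 = 0.1)))
  adj <- adjust_phenotypes(dat$pheno, "T")
  A <- offspring_A(dat)
  spec <- model_spec("BRR", "GS", kernels = list(A = A), niter = 1000,
                     burnin = 200, thin = 2, seed = 4)
  fit <- fit_wgr(adj, dat$geno, spec)
  pred <- predict_ebv(fit, dat$geno, list(A = A))
  expect_equal(pred[fit$ids], fit$fitted_genetic, tolerance = 1e-6)
  expect_error(predict_ebv(fit, dat$geno,
                           list(A = rel_matrix(diag(3) |>
                             `dimnames<-`(list(letters[1:3], letters[1:3])),
                             kind = "pedigreeA"))),
               "absent")
})

test_that("marker heritability is recovered at scale on simulated data", {
  arch <- trait_arch("T", n_qtl = 0, polygenic_h2 = 0, marker_h2 = 0.5)
  cfg <- sim_config(n_markers = 1000, n_chromosomes = 10, n_subpops = 1,
                    target_fst = 0, traits = list(arch), seed = 23)
  dat <- sim_trial(cfg)
  adj <- adjust_phenotypes(dat$pheno, "T")
  spec <- model_spec("BRR", "GS", kernels = list(A = offspring_A(dat)),
                     niter = 8000, burnin = 1500, thin = 5, seed = 6)
  fit <- fit_wgr(adj, dat$geno, spec)
  h <- heritabilities_from_fit(fit)
  expect_lt(abs(h$h2_m - 0.5), 0.1)
})

test_that("pedigree heritability is recovered from an A-structured signal", {
  arch <- trait_arch("T", n_qtl = 0, polygenic_h2 = 0.3, marker_h2 = 0)
  cfg <- sim_config(n_markers = 100, n_chromosomes = 5, n_subpops = 1,
                    target_fst = 0, traits = list(arch), seed = 29)
  dat <- sim_trial(cfg)
  adj <- adjust_phenotypes(dat$pheno, "T")
  # pedigree-only model: no marker term, polygenic kernel only
  spec <- model_spec("BRR", "GS", marker_set = integer(0),
                     kernels = list(A = offspring_A(dat)),
                     niter = 6000, burnin = 1000, thin = 5, seed = 2)
  fit <- fit_wgr(adj, dat$geno, spec)
  h2a <- mean(fit$draws$sigma2_k[, "A"] /
                (fit$draws$sigma2_k[, "A"] + fit$draws$sigma2_e))
  expect_lt(abs(h2a - 0.3), 0.1)
})
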