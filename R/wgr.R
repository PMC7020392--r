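#' Model specification for Bayesian whole-genome regression
#'
#' Describes one fit: the marker prior (`BRR`, `BayesA`, `BayesB`,
#' `BayesCpi`), the approach (`GS` = all markers + pedigree polygenic term;
#' `GSq` = non-significant markers + pedigree term + QTL-genotype term), the
#' marker set, the correlated random-effect kernels, and MCMC settings.
#'
#' Default hyperpriors are scaled-inverse-chi-square with 4.2 degrees of
#' freedom and scales solved so the prior expectation of each variance
#' component splits half the phenotypic variance equally among the genetic
#' terms (markers and kernels), leaving half to the residual. Desk-scale
#' MCMC defaults (30,000 iterations, 5,000 burn-in, thin 10) are deliberate:
#' the chains for these conjugate samplers mix quickly, and the full-length
#' settings used in production runs (1,000,000 / 100,000) are available by
#' configuration.
#'
#' @param method marker prior.
#' @param approach `"GS"` or `"GSq"`.
#' @param marker_set marker indices (or ids) entering the regression term;
#'   `NULL` = all markers. For `GSq` this must exclude every significant
#'   marker.
#' @param significant_markers markers underlying the Q kernel (GSq);
#'   checked for disjointness with `marker_set`.
#' @param kernels named list of [rel_matrix()] objects (e.g. `list(A = A)`
#'   for GS, `list(A = A, Q = Q)` for GSq).
#' @param niter,burnin,thin MCMC settings.
#' @param seed integer seed; same seed gives bit-identical chains.
#' @param hyper optional overrides: `df`, `R2`, `pi_zero` (BayesB spike
#'   probability), `pi_beta` (Beta prior for the sampled Bayes C-pi spike
#'   probability), `fix_sigma_snp`, `fix_sigma_e` (fixed variance values for
#'   oracle checks), `prior_only`.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(method = c("BRR", "BayesA", "BayesB", "BayesCpi"),
                       approach = c("GS", "GSq"),
                       marker_set = NULL, significant_markers = NULL,
                       kernels = list(),
                       niter = 30000, burnin = 5000, thin = 10,
                       seed = 1L, hyper = list()) {
  method <- match.arg(method)
  approach <- match.arg(approach)
  stopifnot(burnin < niter, thin >= 1)
  if (approach == "GSq" && length(significant_markers) &&
      length(intersect(marker_set, significant_markers))) {
    stop("GSq marker_set must be disjoint from the significant set")
  }
  h <- utils::modifyList(list(df = 4.2, R2 = 0.5, pi_zero = 0.95,
                              pi_beta = c(1, 1),
                              fix_sigma_snp = NULL, fix_sigma_e = NULL,
                              prior_only = FALSE), hyper)
  structure(list(method = method, approach = approach,
                 marker_set = marker_set,
                 significant_markers = significant_markers,
                 kernels = kernels, niter = as.integer(niter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), hyper = h),
            class = "model_spec")
}

method_code <- function(method) {
  match(method, c("BRR", "BayesA", "BayesB", "BayesCpi")) - 1L
}

#' Fit a Bayesian whole-genome regression model
#'
#' Single-site Gibbs sampler over the intercept (flat prior), marker effects
#' under the chosen prior, kernel random effects (sampled as independent
#' scalar updates in the eigenbasis of each covariance matrix), and variance
#' components (scaled-inverse-chi-square full conditionals). A Gaussian
#' residual likelihood supplies one deviance draw per retained sample, from
#' which [dic()] is computed.
#'
#' Individuals are aligned by id across `y_star`, `geno` and every kernel;
#' the fit uses their intersection, ordered as in `y_star`. Marker columns
#' are centered internally (the stored column means are reapplied by
#' [predict_ebv()]).
#'
#' @param y_star an [adjust_phenotypes()] result, or a named numeric vector
#'   of pre-corrected records.
#' @param geno a [geno_matrix()] with no missing calls.
#' @param spec a [model_spec()].
#' @return Object of class `wgr_fit`: posterior means/SDs of the intercept,
#'   marker effects and kernel effects; retained draws of all variance
#'   components, the Bayes C-pi spike probability and the deviance;
#'   marker-variance draws; effective sample sizes; the spec and alignment
#'   metadata.
#' @export
fit_wgr <- function(y_star, geno, spec) {
  stopifnot(inherits(spec, "model_spec"))
  y <- if (inherits(y_star, "adjusted_phenotype")) y_star$y_star else y_star
  if (is.null(names(y))) stop("y_star must carry individual ids as names")
  if (anyNA(geno$codes)) stop("fit_wgr requires imputed genotypes (no missing calls)")

  ids <- names(y)
  ids <- ids[ids %in% rownames(geno$codes)]
  for (K in spec$kernels) ids <- ids[ids %in% rownames(K)]
  if (length(ids) < 3) stop("fewer than 3 aligned individuals")
  y <- y[ids]
  n <- length(ids)

  marker_set <- spec$marker_set
  if (is.null(marker_set)) marker_set <- seq_len(ncol(geno$codes))
  if (is.character(marker_set)) marker_set <- match(marker_set, colnames(geno$codes))
  Xraw <- geno$codes[ids, marker_set, drop = FALSE]
  storage.mode(Xraw) <- "double"
  xmeans <- colMeans(Xraw)
  X <- sweep(Xraw, 2, xmeans)
  p <- ncol(X)
  pfreq <- xmeans / 2
  pq <- pfreq * (1 - pfreq)
  sum2pq <- 2 * sum(pq)

  nk <- length(spec$kernels)
  kU <- vector("list", nk); kL <- vector("list", nk)
  knames <- names(spec$kernels)
  if (nk > 0 && is.null(knames)) knames <- paste0("K", seq_len(nk))
  for (k in seq_len(nk)) {
    K <- spec$kernels[[k]]
    Ks <- unclass(K)[ids, ids, drop = FALSE]
    eg <- eigen((Ks + t(Ks)) / 2, symmetric = TRUE)
    if (min(eg$values) < -1e-6) {
      stop(sprintf("kernel '%s' is not PSD (min eigenvalue %.2e)",
                   knames[k], min(eg$values)))
    }
    kU[[k]] <- eg$vectors
    kL[[k]] <- pmax(eg$values, 0)
  }

  # hyperprior scales: split R2 * var(y) equally among genetic terms
  h <- spec$hyper
  df <- h$df
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  n_terms <- (p > 0) + nk
  share <- if (n_terms > 0) h$R2 * vy / n_terms else 0
  S_e <- (1 - h$R2) * vy * (df - 2) / df
  S_snp <- if (p > 0 && sum2pq > 0) share / sum2pq * (df - 2) / df else 1e-4
  if (spec$method == "BayesB") S_snp <- S_snp / (1 - h$pi_zero)
  S_k <- rep(share * (df - 2) / df, nk)
  S_k[S_k <= 0] <- 1e-4
  if (S_snp <= 0) S_snp <- 1e-4
  if (S_e <= 0) S_e <- 1e-4

  fix_snp <- !is.null(h$fix_sigma_snp)
  fix_e <- !is.null(h$fix_sigma_e)
  sample_pi <- spec$method == "BayesCpi" && is.null(h$pi_fixed)
  pi0 <- if (spec$method == "BayesB") h$pi_zero
         else if (!is.null(h$pi_fixed)) h$pi_fixed else 0.5

  set.seed(spec$seed)
  out <- gibbs_wgr(as.numeric(y), X, kU, kL,
                   method_code(spec$method),
                   spec$niter, spec$burnin, spec$thin,
                   df, S_snp, df, S_e,
                   rep(df, nk), S_k,
                   pi0, sample_pi, h$pi_beta[1], h$pi_beta[2],
                   fix_snp, if (fix_snp) h$fix_sigma_snp else 0,
                   fix_e, if (fix_e) h$fix_sigma_e else 0,
                   isTRUE(h$prior_only))

  a_mean <- list()
  for (k in seq_len(nk)) {
    a_mean[[knames[k]]] <- stats::setNames(drop(kU[[k]] %*% out$alpha_mean[[k]]), ids)
  }
  s2k <- out$sigma2_k
  colnames(s2k) <- knames

  # deviance at posterior means of all parameters (for pD)
  ghat <- rep(out$mu_mean, n)
  if (p > 0) ghat <- ghat + drop(X %*% out$m_mean)
  for (k in seq_len(nk)) ghat <- ghat + a_mean[[k]]
  s2e_hat <- mean(out$sigma2_e)
  rss_hat <- sum((y - ghat)^2)
  d_at_mean <- n * log(2 * pi * s2e_hat) + rss_hat / s2e_hat

  draws <- list(sigma2_e = out$sigma2_e, sigma2_k = s2k,
                snp_var = out$snp_var, pi_zero = out$pi_zero,
                deviance = out$deviance, mu = out$mu_draws)
  ess <- c(sigma2_e = ess_draws(out$sigma2_e),
           stats::setNames(apply(s2k, 2, ess_draws),
                           if (nk) paste0("sigma2_", knames) else character(0)))

  structure(list(mu = out$mu_mean,
                 m = stats::setNames(out$m_mean, colnames(Xraw)),
                 m_sd = stats::setNames(out$m_sd, colnames(Xraw)),
                 inclusion = stats::setNames(out$inclusion, colnames(Xraw)),
                 kernel_effects = a_mean,
                 draws = draws, d_at_mean = d_at_mean,
                 ess = ess, ids = ids,
                 marker_set = marker_set, x_means = xmeans,
                 maf = pmin(pfreq, 1 - pfreq), sum2pq = sum2pq,
                 fitted_genetic = stats::setNames(ghat - out$mu_mean, ids),
                 spec = spec),
            class = "wgr_fit")
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("wgr_fit: %s/%s, %d individuals, %d markers, kernels: %s\n",
              x$spec$approach, x$spec$method, length(x$ids),
              length(x$m),
              if (length(x$kernel_effects)) paste(names(x$kernel_effects), collapse = ", ")
              else "none"))
  cat(sprintf("  retained draws: %d; posterior mean sigma2_e = %.4f\n",
              length(x$draws$sigma2_e), mean(x$draws$sigma2_e)))
  invisible(x)
}

# crude initial-sequence effective sample size
ess_draws <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cutoff <- if (length(pos)) pos[1] - 1 else length(ac)
  tau <- 1 + 2 * sum(ac[seq_len(cutoff)])
  max(1, n / max(tau, 1))
}

#' Genomic variance draws from marker-effect variances
#'
#' Converts SNP-effect variance draws into genomic-variance draws using the
#' allele-frequency weighting appropriate to the prior: for common-variance
#' methods (BRR, Bayes C-pi) `sigma2_m = 2 * sigma2_SNP * sum(p_i (1-p_i))`;
#' for per-marker-variance methods (Bayes A, Bayes B)
#' `sigma2_m = 2 * sum(p_i (1-p_i) * sigma2_SNP_i)`, with markers currently
#' at zero (Bayes B) contributing nothing.
#'
#' @param fit a [fit_wgr()] result.
#' @param maf per-marker minor allele frequencies aligned to the fit's
#'   marker set; defaults to the frequencies observed at fit time.
#' @param method marker prior; defaults to the fit's.
#' @return Numeric vector of `sigma2_m` draws (one per retained sample).
#' @export
marker_variance <- function(fit, maf = NULL, method = fit$spec$method) {
  if (is.null(maf)) maf <- fit$maf
  if (length(maf) && (any(maf <= 0) || any(maf > 0.5))) {
    stop("maf must lie in (0, 0.5]")
  }
  if (length(maf) != length(fit$m)) stop("maf not aligned to the fit's marker set")
  if (length(maf) == 0L) return(rep(0, length(fit$draws$sigma2_e)))
  pq <- maf * (1 - maf)
  sv <- fit$draws$snp_var
  if (method %in% c("BRR", "BayesCpi")) {
    2 * sum(pq) * drop(sv[, 1])
  } else {
    2 * drop(sv %*% pq)
  }
}

#' Predict breeding values for (new) individuals
#'
#' `y_hat = X m_hat + sum_k cross-kernel prediction of the kernel effect` —
#' the marker term uses posterior-mean effects on the fit's centered code
#' scale; each kernel effect at new individuals is the joint-normal
#' conditional mean `K[new, train] K[train, train]^{-1} u_hat`. For a
#' training individual the result equals its fitted genetic value.
#'
#' @param fit a [fit_wgr()] result.
#' @param geno_new [geno_matrix()] holding the individuals to predict (must
#'   contain the fit's marker set).
#' @param kernels named list of full [rel_matrix()] objects covering both
#'   training and new individuals; names must match the fit's kernels.
#' @return Named vector of predicted genetic values.
#' @export
predict_ebv <- function(fit, geno_new, kernels = fit$spec$kernels) {
  new_ids <- rownames(geno_new$codes)
  X <- geno_new$codes[, fit$marker_set, drop = FALSE]
  storage.mode(X) <- "double"
  X <- sweep(X, 2, fit$x_means)
  yhat <- if (ncol(X)) drop(X %*% fit$m) else rep(0, length(new_ids))
  names(yhat) <- new_ids
  for (kn in names(fit$kernel_effects)) {
    K <- kernels[[kn]]
    if (is.null(K)) stop(sprintf("kernel '%s' not supplied", kn))
    if (!all(new_ids %in% rownames(K)) || !all(fit$ids %in% rownames(K))) {
      stop(sprintf("individual(s) absent from kernel '%s'", kn))
    }
    Ktt <- unclass(K)[fit$ids, fit$ids, drop = FALSE]
    Knt <- unclass(K)[new_ids, fit$ids, drop = FALSE]
    u <- fit$kernel_effects[[kn]]
    yhat <- yhat + drop(Knt %*% solve(Ktt, u))
  }
  yhat
}
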