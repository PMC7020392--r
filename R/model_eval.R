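#' Partitioned heritability from variance-component draws
#'
#' Computes, per retained MCMC draw, the pedigree (`h2_a`), marker (`h2_m`)
#' and QTL-genotype (`h2_q`) heritabilities as each component over the
#' common denominator `sigma2_a + sigma2_m + sigma2_q + sigma2_e`, then
#' averages the per-draw ratios (the proper posterior of a ratio, rather
#' than a ratio of posterior means). For the traditional model `sigma2_q`
#' is identically zero.
#'
#' @param sigma2_a,sigma2_m,sigma2_e aligned draw vectors.
#' @param sigma2_q draw vector or `NULL`/0 for the GS model.
#' @return List of class `heritability_estimates`: posterior means `h2_a`,
#'   `h2_m`, `h2_q` and the per-draw ratios in `draws`.
#' @export
heritabilities <- function(sigma2_a, sigma2_m, sigma2_q = NULL, sigma2_e) {
  nd <- length(sigma2_e)
  if (is.null(sigma2_q)) sigma2_q <- rep(0, nd)
  if (length(sigma2_q) == 1L) sigma2_q <- rep(sigma2_q, nd)
  if (length(sigma2_a) == 1L) sigma2_a <- rep(sigma2_a, nd)
  stopifnot(length(sigma2_a) == nd, length(sigma2_m) == nd,
            length(sigma2_q) == nd)
  denom <- sigma2_a + sigma2_m + sigma2_q + sigma2_e
  if (any(denom == 0)) stop("all-zero variance draw: heritability undefined")
  draws <- data.frame(h2_a = sigma2_a / denom, h2_m = sigma2_m / denom,
                      h2_q = sigma2_q / denom)
  structure(list(h2_a = mean(draws$h2_a), h2_m = mean(draws$h2_m),
                 h2_q = mean(draws$h2_q), draws = draws),
            class = "heritability_estimates")
}

#' Heritability partition of a fitted model
#'
#' Convenience wrapper assembling the draw vectors from a [fit_wgr()]
#' result: `sigma2_a` from the pedigree kernel, `sigma2_q` from the Q kernel
#' (when present), `sigma2_m` via [marker_variance()].
#'
#' @param fit a [fit_wgr()] result with kernels named `A` (and `Q` for GSq).
#' @return A [heritabilities()] object.
#' @export
heritabilities_from_fit <- function(fit) {
  s2k <- fit$draws$sigma2_k
  nd <- length(fit$draws$sigma2_e)
  s2a <- if ("A" %in% colnames(s2k)) s2k[, "A"] else rep(0, nd)
  s2q <- if ("Q" %in% colnames(s2k)) s2k[, "Q"] else NULL
  heritabilities(s2a, marker_variance(fit), s2q, fit$draws$sigma2_e)
}

#' Deviance information criterion
#'
#' `DIC = D_bar + pD` with `D_bar` the posterior mean deviance and
#' `pD = D_bar - D(theta_bar)` the effective number of parameters
#' (deviance at the posterior means).
#'
#' @param deviance_draws vector of deviance draws (at least 2, finite).
#' @param d_at_mean deviance evaluated at the posterior parameter means.
#' @return List of class `dic_result`: `dic`, `d_bar`, `p_d`, `d_at_mean`.
#' @export
dic <- function(deviance_draws, d_at_mean) {
  if (length(deviance_draws) < 2) stop("need at least 2 deviance draws")
  if (!all(is.finite(deviance_draws)) || !is.finite(d_at_mean)) {
    stop("non-finite deviance")
  }
  d_bar <- mean(deviance_draws)
  p_d <- d_bar - d_at_mean
  structure(list(dic = d_bar + p_d, d_bar = d_bar, p_d = p_d,
                 d_at_mean = d_at_mean),
            class = "dic_result")
}

#' @rdname dic
#' @param fit a [fit_wgr()] result.
#' @export
dic_from_fit <- function(fit) dic(fit$draws$deviance, fit$d_at_mean)

#' DIC difference between the traditional and QTL-informed models
#'
#' `delta = DIC(GS) - DIC(GSq)`: positive values favour the QTL-informed
#' model (lower DIC). Verdict bands: `|delta| > 10` strong support,
#' `5 <= |delta| <= 10` substantial, `|delta| < 5` not significant.
#'
#' @param dic_gs,dic_gsq DIC values (numbers or [dic()] results).
#' @return List: `delta`, `verdict`, `favors` (`"GSq"`, `"GS"` or `"none"`).
#' @export
delta_dic <- function(dic_gs, dic_gsq) {
  if (inherits(dic_gs, "dic_result")) dic_gs <- dic_gs$dic
  if (inherits(dic_gsq, "dic_result")) dic_gsq <- dic_gsq$dic
  if (!is.finite(dic_gs) || !is.finite(dic_gsq)) stop("non-finite DIC")
  delta <- dic_gs - dic_gsq
  verdict <- if (abs(delta) > 10) "strong"
             else if (abs(delta) >= 5) "substantial"
             else "not significant"
  favors <- if (verdict == "not significant") "none"
            else if (delta > 0) "GSq" else "GS"
  list(delta = delta, verdict = verdict, favors = favors)
}

#' Predictive ability
#'
#' Pearson correlation between pre-corrected validation records and
#' predicted breeding values.
#'
#' @param y_star_validation,y_hat_validation equal-length vectors (n >= 3).
#' @return Correlation in `[-1, 1]`, or `NA` when either vector has zero
#'   variance.
#' @export
predictive_ability <- function(y_star_validation, y_hat_validation) {
  stopifnot(length(y_star_validation) == length(y_hat_validation),
            length(y_star_validation) >= 3)
  if (stats::sd(y_star_validation) == 0 || stats::sd(y_hat_validation) == 0) {
    message("zero variance in observed or predicted values: PA undefined")
    return(NA_real_)
  }
  stats::cor(y_star_validation, y_hat_validation)
}

#' k-fold cross-validated predictive ability
#'
#' Individuals are randomly partitioned into `n_folds` near-equal folds.
#' For each fold the model is refit on the remaining individuals (the marker
#' set and kernels of `spec` are held fixed — significant-marker selection is
#' not re-run inside folds) and validation predictions come from
#' [predict_ebv()] using the full kernel matrices; per-fold predictive
#' ability is the Pearson correlation with the held-out records.
#'
#' @param y_star adjusted phenotype (named vector or
#'   [adjust_phenotypes()] result).
#' @param geno [geno_matrix()] with no missing calls.
#' @param spec a [model_spec()] whose kernels cover all individuals.
#' @param n_folds number of folds (default 20).
#' @param seed RNG seed for the fold assignment.
#' @return List of class `cv_result`: `n_folds`, `folds` (named assignment),
#'   `pa` (per-fold), `mean_pa`, `y_hat` (out-of-fold predictions).
#' @export
cross_validate <- function(y_star, geno, spec, n_folds = 20, seed = 1L) {
  y <- if (inherits(y_star, "adjusted_phenotype")) y_star$y_star else y_star
  ids <- names(y)[names(y) %in% rownames(geno$codes)]
  y <- y[ids]
  n <- length(y)
  if (n_folds > n) stop("more folds than individuals")
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  names(folds) <- ids
  if (min(table(folds)) < 3) stop("a fold has fewer than 3 individuals")
  pa <- numeric(n_folds)
  y_hat <- stats::setNames(rep(NA_real_, n), ids)
  for (f in seq_len(n_folds)) {
    val <- ids[folds == f]
    train <- ids[folds != f]
    fit <- fit_wgr(y[train], geno, spec)
    pred <- predict_ebv(fit, geno[val, ], spec$kernels)
    y_hat[val] <- pred
    pa[f] <- predictive_ability(y[val], pred)
  }
  structure(list(n_folds = n_folds, folds = folds, pa = pa,
                 mean_pa = mean(pa, na.rm = TRUE), y_hat = y_hat),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean PA = %.3f (fold range %.3f to %.3f)\n",
              x$n_folds, x$mean_pa, min(x$pa, na.rm = TRUE),
              max(x$pa, na.rm = TRUE)))
  invisible(x)
}
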