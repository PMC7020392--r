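#' Mixed-model association scan
#'
#' Single-marker scan of the pre-corrected phenotype under the mixed model
#' `y* = S a + Q v + Z u + e` with a fixed marker effect, fixed
#' population-structure covariates, a random polygenic effect with covariance
#' proportional to the marker kinship, and homoscedastic residuals. Variance
#' components are estimated once by REML on the null (no-marker) model and
#' reused for every marker — the standard population-parameters-previously-
#' determined (P3D/EMMAX) scheme — and each marker is tested with a Wald test
#' on its generalized-least-squares coefficient.
#'
#' The computation rotates the model into the kinship eigenbasis, where the
#' covariance is diagonal, and profiles the REML likelihood over the
#' variance ratio.
#'
#' @param y_star an [adjust_phenotypes()] result or named numeric vector.
#' @param geno a [geno_matrix()] with no missing calls.
#' @param K full-panel [marker_kinship()] matrix (used directly as the
#'   polygenic covariance; it is on the `2 x` coancestry scale).
#' @param structure_covariates optional matrix of fixed covariates (rows
#'   named by individual id, or aligned with `y_star`).
#' @return data.frame of per-marker association results: `marker`, `chrom`,
#'   `pos`, `effect`, `se`, `p_value`, `variance_explained`, plus the REML
#'   variance components as attributes `sigma2_g`, `sigma2_e`. Markers with
#'   no genotypic variance or a collinear design are skipped (`NA` rows)
#'   with a warning.
#' @export
scan_markers <- function(y_star, geno, K, structure_covariates = NULL) {
  y <- if (inherits(y_star, "adjusted_phenotype")) y_star$y_star else y_star
  ids <- names(y)
  ids <- ids[ids %in% rownames(geno$codes) & ids %in% rownames(K)]
  y <- y[ids]
  n <- length(y)
  X <- geno$codes[ids, , drop = FALSE]
  storage.mode(X) <- "double"

  W <- matrix(1, n, 1)
  if (!is.null(structure_covariates)) {
    sc <- as.matrix(structure_covariates)
    if (!is.null(rownames(sc))) sc <- sc[ids, , drop = FALSE]
    W <- cbind(W, sc)
  }
  q <- ncol(W)

  eg <- eigen(unclass(K)[ids, ids], symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  ty <- drop(Ut %*% y)
  tW <- Ut %*% W

  reml_rss <- function(delta) {
    w <- 1 / (d + delta)
    sw <- sqrt(w)
    fit <- stats::lm.fit(tW * sw, ty * sw)
    sum(fit$residuals^2)
  }
  reml_nll <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    rss <- reml_rss(delta)
    sw <- sqrt(w)
    WtVW <- crossprod(tW * sw)
    0.5 * ((n - q) * log(rss / (n - q)) + sum(log(d + delta)) +
             determinant(WtVW, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml_nll, c(-12, 12))
  delta <- exp(opt$minimum)
  sigma2_g <- reml_rss(delta) / (n - q)
  sigma2_e <- delta * sigma2_g

  w <- 1 / (d + delta)
  sw <- sqrt(w)
  tWs <- tW * sw
  tys <- ty * sw
  tX <- (Ut %*% X) * sw

  eff <- se <- pv <- rep(NA_real_, ncol(X))
  skipped <- 0L
  for (j in seq_len(ncol(X))) {
    xj <- tX[, j]
    M <- cbind(tWs, xj)
    XtX <- crossprod(M)
    ok <- TRUE
    cf <- tryCatch(solve(XtX, crossprod(M, tys)),
                   error = function(e) { ok <<- FALSE; NULL })
    if (!ok || stats::var(X[, j]) == 0) { skipped <- skipped + 1L; next }
    res <- tys - drop(M %*% cf)
    s2 <- sum(res^2) / (n - q - 1)
    vc <- tryCatch(solve(XtX)[q + 1, q + 1] * s2,
                   error = function(e) { ok <<- FALSE; NA_real_ })
    if (!ok || !is.finite(vc) || vc <= 0) { skipped <- skipped + 1L; next }
    eff[j] <- cf[q + 1]
    se[j] <- sqrt(vc)
    pv[j] <- 2 * stats::pnorm(-abs(cf[q + 1] / se[j]))
  }
  if (skipped > 0) {
    warning(sprintf("skipped %d marker(s): zero variance or collinear with covariates",
                    skipped))
  }

  r2 <- vapply(seq_len(ncol(X)), function(j) {
    vx <- stats::var(X[, j])
    if (vx == 0) return(NA_real_)
    stats::cor(y, X[, j])^2
  }, numeric(1))

  out <- data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
                    pos = geno$map$pos, effect = eff, se = se,
                    p_value = pv, variance_explained = r2,
                    stringsAsFactors = FALSE)
  attr(out, "sigma2_g") <- sigma2_g
  attr(out, "sigma2_e") <- sigma2_e
  out
}

#' Select significant marker-trait associations
#'
#' Benjamini–Hochberg q-values are computed over all scanned markers for the
#' trait; a marker is a significant MTA when its raw p-value is strictly
#' below `alpha` and its q-value strictly below `fdr_max`.
#'
#' @param results a [scan_markers()] data.frame.
#' @param alpha genome-wide per-marker significance threshold.
#' @param fdr_max false-discovery-rate ceiling.
#' @return The input with `q_value` and `significant` columns added,
#'   restricted to the significant rows; the full annotated table is
#'   attached as attribute `all`.
#' @export
select_mtas <- function(results, alpha = 0.001, fdr_max = 0.10) {
  if (nrow(results) == 0L) stop("empty scan results")
  results$q_value <- stats::p.adjust(results$p_value, method = "BH")
  results$significant <- !is.na(results$p_value) &
    results$p_value < alpha & results$q_value < fdr_max
  out <- results[results$significant, , drop = FALSE]
  attr(out, "all") <- results
  out
}

#' Phenotypic variance explained by one marker
#'
#' R-squared of the ordinary single-marker regression of the pre-corrected
#' phenotype on allele count.
#'
#' @param y_star adjusted phenotype (named vector or
#'   [adjust_phenotypes()] result).
#' @param geno a [geno_matrix()].
#' @param marker_id marker id or column index.
#' @return Fraction of phenotypic variance in `[0, 1]`.
#' @export
variance_explained <- function(y_star, geno, marker_id) {
  y <- if (inherits(y_star, "adjusted_phenotype")) y_star$y_star else y_star
  if (is.character(marker_id)) marker_id <- match(marker_id, colnames(geno$codes))
  x <- geno$codes[names(y), marker_id]
  if (stats::var(x) == 0) stop("marker is monomorphic")
  stats::cor(y, x)^2
}
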