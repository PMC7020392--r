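#' Relationship matrices
#'
#' Symmetric positive-semi-definite covariance structures over individuals:
#' the pedigree numerator relationship matrix `A`, the realized marker
#' relationship (VanRaden) used both as the GWAS kinship `K` and, on the
#' GWAS-significant subset, as the QTL-genotype covariance `Q`.
#'
#' @param values symmetric numeric matrix with individual ids as dimnames.
#' @param kind one of `"pedigreeA"`, `"kinshipK"`, `"qtlQ"`, `"markerG"`.
#' @param epsilon ridge added to the diagonal for sampler stability.
#' @return Object of class `rel_matrix`: the regularized matrix with
#'   attributes `kind` and `epsilon`.
#' @export
rel_matrix <- function(values, kind = c("markerG", "pedigreeA", "kinshipK", "qtlQ"),
                       epsilon = 1e-6) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (max(abs(values - t(values))) > 1e-10) stop("relationship matrix not symmetric")
  values <- (values + t(values)) / 2 + diag(epsilon, nrow(values))
  structure(values, kind = kind, epsilon = epsilon, class = c("rel_matrix", "matrix"))
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix (%s): %d individuals, mean diag %.3f\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

#' Pedigree numerator relationship matrix
#'
#' Tabular-method additive relationship matrix. For open-pollinated families
#' (dam known, sire unknown) the plain tabular method yields 0.25 between
#' maternal sibs — the pure half-sib assumption; `op_sib_coefficient` lets
#' the analyst raise that block to reflect a selfing / full-sib mixture in
#' the pollen cloud, in the spirit of published open-pollinated relationship
#' adjustments.
#'
#' @param ped data.frame with character columns `id`, `dam`, `sire`
#'   (`"0"` or `NA` = unknown parent). Parents must precede offspring.
#' @param op_sib_coefficient additive relationship assigned between maternal
#'   sibs with unknown sires (default 0.25 = half-sibs).
#' @param epsilon diagonal regularization.
#' @return A [rel_matrix()] of kind `"pedigreeA"`.
#' @export
pedigree_A <- function(ped, op_sib_coefficient = 0.25, epsilon = 1e-6) {
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  dam <- as.character(ped$dam); sire <- as.character(ped$sire)
  dam[is.na(dam) | dam == "0" | dam == ""] <- NA
  sire[is.na(sire) | sire == "0" | sire == ""] <- NA
  n <- length(ids)
  di <- match(dam, ids); si <- match(sire, ids)
  if (any(!is.na(dam) & is.na(di)) || any(!is.na(sire) & is.na(si))) {
    stop("pedigree parent not found among ids (is the pedigree sorted parents-first?)")
  }
  if (any(stats::na.omit(di) >= seq_len(n)[!is.na(di)]) ||
      any(stats::na.omit(si) >= seq_len(n)[!is.na(si)])) {
    stop("cyclic or unsorted pedigree: parents must precede offspring")
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- di[i]; s <- si[i]
    A[i, i] <- 1 + if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
    if (i > 1) {
      js <- seq_len(i - 1)
      ad <- if (!is.na(d)) A[js, d] else rep(0, i - 1)
      as_ <- if (!is.na(s)) A[js, s] else rep(0, i - 1)
      A[i, js] <- A[js, i] <- 0.5 * (ad + as_)
    }
  }
  if (op_sib_coefficient != 0.25) {
    # raise maternal-sib blocks where both sires are unknown
    for (d in unique(stats::na.omit(di[is.na(si)]))) {
      sibs <- which(di == d & is.na(si))
      if (length(sibs) > 1) {
        for (i in sibs) for (j in sibs) if (i != j) A[i, j] <- op_sib_coefficient
      }
    }
  }
  rel_matrix(A, kind = "pedigreeA", epsilon = epsilon)
}

#' Realized marker relationship matrix (VanRaden)
#'
#' `G = W W' / (2 * sum(p_i (1 - p_i)))` with `W` the column-centered allele
#' count matrix and `p_i` the observed allele frequencies. The full-panel
#' matrix serves as the GWAS kinship (it is on the `2K` scale: diagonal
#' `~ 1 + f`); a subset restricted to significant markers is the QTL-genotype
#' covariance `Q`.
#'
#' @param geno a [geno_matrix()] without missing calls.
#' @param marker_subset optional marker column indices (or marker ids).
#' @param kind recorded matrix kind.
#' @param epsilon diagonal regularization.
#' @return A [rel_matrix()].
#' @export
marker_kinship <- function(geno, marker_subset = NULL,
                           kind = if (is.null(marker_subset)) "kinshipK" else "qtlQ",
                           epsilon = 1e-6) {
  codes <- geno$codes
  if (anyNA(codes)) stop("marker_kinship requires a fully imputed genotype matrix")
  if (!is.null(marker_subset)) {
    if (is.character(marker_subset)) marker_subset <- match(marker_subset, colnames(codes))
    codes <- codes[, marker_subset, drop = FALSE]
  }
  p <- colMeans(codes) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warning(sprintf("dropped %d monomorphic marker(s) from kinship", sum(!poly)))
    codes <- codes[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (ncol(codes) == 0L) stop("no polymorphic markers left for kinship")
  W <- sweep(codes, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  rel_matrix(G, kind = kind, epsilon = epsilon)
}

#' QTL-genotype covariance from significant markers
#'
#' Realized relationship over the GWAS-significant marker subset — the
#' covariance of the QTL-genotype random effect in the two-stage model. An
#' empty subset is an error: with no significant associations the traditional
#' model (no QTL term) is the one to fit.
#'
#' @param geno a [geno_matrix()] without missing calls.
#' @param significant_markers marker indices or ids flagged by the scan.
#' @param epsilon diagonal regularization.
#' @return A [rel_matrix()] of kind `"qtlQ"`.
#' @export
qtl_Q <- function(geno, significant_markers, epsilon = 1e-6) {
  if (length(significant_markers) == 0L) {
    stop("no significant markers: fit the traditional GS model instead")
  }
  marker_kinship(geno, marker_subset = significant_markers,
                 kind = "qtlQ", epsilon = epsilon)
}
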