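#' Observed and expected heterozygosity
#'
#' Per marker, observed heterozygosity is the fraction of heterozygous
#' (code 1) individuals and expected heterozygosity is `2p(1-p)` from the
#' allele frequency; panel values are unweighted means over markers.
#' Missing calls are excluded per marker.
#'
#' @param geno a [geno_matrix()].
#' @return List of class `diversity_summary` with `per_marker`
#'   (data.frame `marker`, `ho`, `he`) and panel means `ho`, `he`.
#' @export
heterozygosity <- function(geno) {
  if (ncol(geno$codes) == 0L || nrow(geno$codes) == 0L) stop("empty genotype matrix")
  ho <- colMeans(geno$codes == 1L, na.rm = TRUE)
  p <- allele_freq(geno)
  he <- 2 * p * (1 - p)
  structure(list(per_marker = data.frame(marker = geno$map$marker, ho = ho, he = he,
                                         row.names = NULL),
                 ho = mean(ho), he = mean(he)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("diversity over %d markers: Ho = %.3f, He = %.3f\n",
              nrow(x$per_marker), x$ho, x$he))
  invisible(x)
}

# Weir & Cockerham (1984) theta for one pair of groups, combined over markers
# as ratio of summed variance components a / (a + b + c).
wc_theta_pair <- function(codes1, codes2) {
  r <- 2
  a_sum <- 0; abc_sum <- 0
  for (j in seq_len(ncol(codes1))) {
    g1 <- codes1[, j]; g2 <- codes2[, j]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    if (pbar <= 0 || pbar >= 1) next
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  if (abc_sum == 0) return(NA_real_)
  a_sum / abc_sum
}

#' Pairwise F_ST between groups (Weir–Cockerham)
#'
#' Multi-marker Weir & Cockerham (1984) estimator, combining variance
#' components over markers as a ratio of sums, for every pair of groups.
#'
#' @param geno a [geno_matrix()].
#' @param group_labels group assignment per individual (length = rows of
#'   `geno`); at least two groups with two or more individuals each.
#' @return Symmetric matrix of pairwise F_ST with zero diagonal, dimnames =
#'   group names.
#' @export
pairwise_fst <- function(geno, group_labels) {
  group_labels <- as.character(group_labels)
  stopifnot(length(group_labels) == nrow(geno$codes))
  groups <- sort(unique(group_labels))
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- table(group_labels)
  if (any(sizes < 2)) stop("every group needs at least two individuals")
  k <- length(groups)
  out <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      th <- wc_theta_pair(geno$codes[group_labels == groups[i], , drop = FALSE],
                          geno$codes[group_labels == groups[j], , drop = FALSE])
      out[i, j] <- out[j, i] <- th
    }
  }
  out
}

#' Composite LD between marker pairs
#'
#' Squared Pearson correlation of genotype codes (composite, genotypic LD —
#' appropriate for unphased data). Pairs must lie on a single chromosome;
#' a pair involving a monomorphic marker is undefined and reported `NA`.
#'
#' @param geno a [geno_matrix()].
#' @param marker_pairs two-column matrix (or list of length-2 vectors) of
#'   marker column indices.
#' @return data.frame with columns `marker1`, `marker2`, `chrom`, `dist_bp`,
#'   `r2`.
#' @export
ld_r2 <- function(geno, marker_pairs) {
  if (is.list(marker_pairs)) marker_pairs <- do.call(rbind, marker_pairs)
  marker_pairs <- matrix(as.integer(marker_pairs), ncol = 2)
  out <- data.frame(marker1 = geno$map$marker[marker_pairs[, 1]],
                    marker2 = geno$map$marker[marker_pairs[, 2]],
                    chrom = geno$map$chrom[marker_pairs[, 1]],
                    dist_bp = abs(geno$map$pos[marker_pairs[, 1]] -
                                    geno$map$pos[marker_pairs[, 2]]),
                    r2 = NA_real_)
  for (k in seq_len(nrow(marker_pairs))) {
    i <- marker_pairs[k, 1]; j <- marker_pairs[k, 2]
    if (geno$map$chrom[i] != geno$map$chrom[j]) {
      stop("ld_r2 pairs must lie on the same chromosome")
    }
    x <- geno$codes[, i]; y <- geno$codes[, j]
    ok <- !is.na(x) & !is.na(y)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next  # monomorphic -> NA
    out$r2[k] <- stats::cor(x[ok], y[ok])^2
  }
  out
}
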