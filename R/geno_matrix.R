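#' SNP genotype matrix
#'
#' Container for biallelic SNP genotypes coded by minor/alternate allele count
#' (AA = 0, AB = 1, BB = 2; `NA` = missing call), together with marker map
#' metadata. Rows are individuals, columns are markers.
#'
#' @param codes integer matrix of allele counts in `{0, 1, 2, NA}`;
#'   dimnames supply individual and marker ids when present.
#' @param chrom chromosome label per marker (coerced to character).
#' @param pos physical position (bp) per marker; non-negative, sorted within
#'   chromosome.
#' @param individual_ids,marker_ids optional explicit ids; default to the
#'   dimnames of `codes` or generated labels.
#'
#' @return An object of class `geno_matrix`: a list with elements `codes`
#'   (integer matrix with dimnames) and `map` (data.frame with columns
#'   `marker`, `chrom`, `pos`).
#' @export
geno_matrix <- function(codes, chrom = NULL, pos = NULL,
                        individual_ids = NULL, marker_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  n <- nrow(codes)
  p <- ncol(codes)
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(individual_ids)) {
    individual_ids <- rownames(codes)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n), recycle0 = TRUE)
  }
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (is.null(marker_ids)) {
    marker_ids <- colnames(codes)
    if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(p), recycle0 = TRUE)
  }
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos)) pos <- seq_len(p)
  if (length(chrom) != p || length(pos) != p) {
    stop("chrom and pos must have one entry per marker")
  }
  if (any(pos < 0)) stop("positions must be non-negative")
  dimnames(codes) <- list(individual_ids, marker_ids)
  map <- data.frame(marker = as.character(marker_ids),
                    chrom = as.character(chrom),
                    pos = as.numeric(pos),
                    stringsAsFactors = FALSE)
  structure(list(codes = codes, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers on %d chromosome(s); %.1f%% missing\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom)),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i individual index (row) selector.
#' @param j marker index (column) selector.
#' @param ... unused.
#' @return A `geno_matrix` restricted to the selected individuals/markers.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$codes))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  codes <- x$codes[i, j, drop = FALSE]
  jj <- seq_len(ncol(x$codes))
  names(jj) <- colnames(x$codes)
  jidx <- jj[j]
  geno_matrix(codes, chrom = x$map$chrom[jidx], pos = x$map$pos[jidx])
}

# Per-marker alternate-allele frequency computed on non-missing calls.
allele_freq <- function(geno) {
  colMeans(geno$codes, na.rm = TRUE) / 2
}

# Per-marker minor allele frequency.
minor_allele_freq <- function(geno) {
  p <- allele_freq(geno)
  pmin(p, 1 - p)
}
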