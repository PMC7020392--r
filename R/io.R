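#' Read genotypes from VCF or 0/1/2 CSV
#'
#' VCF input is parsed with \pkg{vcfR}; only biallelic records are kept
#' (multi-allelic records are skipped with a warning) and only the GT field is
#' used. CSV input expects a header row of marker ids, a first column of
#' individual ids, and cells in `{0, 1, 2, NA}`.
#'
#' @param path file path.
#' @param format `"vcf"` or `"csv012"`; guessed from the file extension when
#'   omitted.
#' @return A [geno_matrix()]. Missing calls are preserved as `NA`; marker
#'   order follows the file.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "csv012")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv012"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_csv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt)
  if (any(!biallelic)) {
    warning(sprintf("skipped %d multi-allelic VCF record(s)", sum(!biallelic)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # allele-count code from the GT string; any missing allele gives NA
  code1 <- gsub("\\|", "/", gt)
  codes <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  codes[] <- unname(known[code1])
  geno_matrix(t(codes),
              chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
              individual_ids = colnames(gt),
              marker_ids = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                  paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                  fix[, "ID"]))
}

read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  codes <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(codes) <- "integer"
  rownames(codes) <- ids
  geno_matrix(codes)
}

#' Write genotypes
#'
#' `csv012` writes the allele-count matrix with an `id` index column; `vcf`
#' writes a minimal VCF v4.2 with GT-only genotype columns (alleles A/B as
#' REF/ALT placeholders, unphased).
#'
#' @param geno a [geno_matrix()].
#' @param path output path.
#' @param format `"csv012"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("csv012", "vcf")) {
  format <- match.arg(format)
  if (format == "csv012") {
    d <- data.frame(id = rownames(geno$codes), geno$codes,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(geno$codes)),
                       collapse = "\t")), con)
    gt_str <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(geno$codes))) {
      g <- geno$codes[, j]
      cells <- ifelse(is.na(g), "./.", gt_str[g + 1L])
      writeLines(paste(c(geno$map$chrom[j], format(geno$map$pos[j], scientific = FALSE),
                         geno$map$marker[j], "A", "B", ".", "PASS", ".", "GT", cells),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read/write a 3-column pedigree CSV (id, dam, sire; "0" = unknown)
#'
#' @param path file path.
#' @return A data.frame with character columns `id`, `dam`, `sire`, where
#'   `"0"` denotes an unknown parent.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  names(d)[1:3] <- c("id", "dam", "sire")
  d
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped[, c("id", "dam", "sire")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a phenotype table (id, block, trait columns)
#'
#' @param path file path.
#' @return data.frame with `id`, `block` and one column per trait.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$id <- as.character(d$id)
  d
}

#' @rdname read_phenotypes
#' @param pheno phenotype data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Marker quality control
#'
#' Retains markers whose call rate is strictly greater than `call_rate_min`
#' and whose minor allele frequency (computed on non-missing calls) is
#' strictly greater than `maf_min` — the standard pre-imputation screen for
#' low-density SNP panels.
#'
#' @param geno a [geno_matrix()].
#' @param call_rate_min minimum fraction of non-missing calls (exclusive).
#' @param maf_min minimum minor allele frequency (exclusive).
#' @return The filtered `geno_matrix`, with an attribute `qc` recording the
#'   number of markers removed by each criterion.
#' @export
filter_markers <- function(geno, call_rate_min = 0.7, maf_min = 0.05) {
  if (ncol(geno$codes) == 0L) stop("empty genotype matrix")
  call_rate <- colMeans(!is.na(geno$codes))
  maf <- minor_allele_freq(geno)
  maf[is.nan(maf)] <- 0
  keep_cr <- call_rate > call_rate_min
  keep_maf <- maf > maf_min
  keep <- keep_cr & keep_maf
  if (!any(keep)) warning("all markers removed by QC: empty panel")
  out <- geno[, keep]
  attr(out, "qc") <- list(removed_call_rate = sum(!keep_cr),
                          removed_maf = sum(keep_cr & !keep_maf),
                          retained = sum(keep))
  out
}

#' LD-kNN genotype imputation
#'
#' Fills each missing call using the k nearest individuals, with distances
#' computed over the `l_sites` markers most correlated with the target marker
#' (LD-informed site restriction). Votes for codes 0/1/2 are weighted by
#' inverse distance; ties resolve to the lower code. Observed calls are never
#' altered. A marker missing in every individual is filled with the rounded
#' panel mean code and a message is logged.
#'
#' @param geno a [geno_matrix()].
#' @param k_neighbors number of neighbours voting per missing call.
#' @param l_sites number of LD-correlated markers used for the distance.
#' @return A `geno_matrix` with no missing calls.
#' @export
impute_knn <- function(geno, k_neighbors = 5, l_sites = 30) {
  codes <- geno$codes
  n <- nrow(codes)
  if (n < k_neighbors + 1) stop("need at least k_neighbors + 1 individuals")
  miss <- which(is.na(codes), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(geno)
  # |r| between markers, on the observed calls; NA-safe
  suppressWarnings(cr <- abs(stats::cor(codes, use = "pairwise.complete.obs")))
  cr[!is.finite(cr)] <- 0
  for (j in unique(miss[, 2])) {
    target_rows <- miss[miss[, 2] == j, 1]
    obs_rows <- which(!is.na(codes[, j]))
    if (length(obs_rows) == 0L) {
      fill <- round(mean(codes, na.rm = TRUE))
      codes[target_rows, j] <- as.integer(fill)
      message(sprintf("marker %s missing in all individuals; filled with panel mean %d",
                      colnames(codes)[j], as.integer(fill)))
      next
    }
    ord <- order(cr[, j], decreasing = TRUE)
    sites <- setdiff(ord, j)[seq_len(min(l_sites, ncol(codes) - 1L))]
    for (i in target_rows) {
      # distance to candidate neighbours over shared non-missing LD sites
      d <- vapply(obs_rows, function(r) {
        ok <- !is.na(codes[i, sites]) & !is.na(codes[r, sites])
        if (!any(ok)) return(NA_real_)
        mean(abs(codes[i, sites][ok] - codes[r, sites][ok])) / 2
      }, numeric(1))
      cand <- obs_rows[order(d, na.last = TRUE)]
      nb <- cand[seq_len(min(k_neighbors, length(cand)))]
      w <- 1 / pmax(d[match(nb, obs_rows)], 1e-8)
      w[is.na(w)] <- 1e-8
      votes <- vapply(0:2, function(g) sum(w[codes[nb, j] == g]), numeric(1))
      codes[i, j] <- as.integer(which.max(votes) - 1L)  # which.max -> lower code on ties
    }
  }
  geno_matrix(codes, chrom = geno$map$chrom, pos = geno$map$pos)
}

#' Pre-correct phenotypes for design and structure effects
#'
#' Fits an ordinary linear model of the trait on block indicators (and
#' population-structure covariates when supplied) and returns the residuals
#' `y*` — the adjusted records that downstream association and prediction
#' models work with. Ordinal traits are treated on their numeric scale. A
#' rank-deficient design (confounded covariates) is handled by R's
#' pivoting least squares fit with a warning.
#'
#' @param pheno phenotype data.frame with columns `id`, `block` and the trait.
#' @param trait trait column name.
#' @param structure_covariates optional numeric matrix/data.frame of per-
#'   individual covariates (rows aligned with `pheno`).
#' @return A list of class `adjusted_phenotype`: `y_star` (named residual
#'   vector), `trait`, and `fit` (the `lm` object holding the correction
#'   terms).
#' @export
adjust_phenotypes <- function(pheno, trait, structure_covariates = NULL) {
  if (!trait %in% names(pheno)) stop(sprintf("trait '%s' not in phenotype table", trait))
  y <- as.numeric(pheno[[trait]])
  keep <- !is.na(y)
  dat <- data.frame(y = y[keep], block = factor(pheno$block[keep]))
  # a single-block design reduces to intercept-only correction
  form <- if (nlevels(dat$block) > 1) y ~ block else y ~ 1
  if (!is.null(structure_covariates)) {
    sc <- as.matrix(structure_covariates)[keep, , drop = FALSE]
    colnames(sc) <- paste0("q", seq_len(ncol(sc)))
    dat <- cbind(dat, sc)
    base <- if (nlevels(dat$block) > 1) "y ~ block +" else "y ~"
    form <- stats::as.formula(paste(base, paste(colnames(sc), collapse = " + ")))
  }
  fit <- stats::lm(form, data = dat)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    warning("rank-deficient correction design; confounded covariates dropped")
  }
  y_star <- stats::residuals(fit)
  names(y_star) <- as.character(pheno$id[keep])
  structure(list(y_star = y_star, trait = trait, fit = fit),
            class = "adjusted_phenotype")
}
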