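#' Simulation configuration for an open-pollinated progeny trial
#'
#' The defaults emulate the study system the package targets: 49
#' open-pollinated families (~10 genotyped offspring each, 490 trees), a
#' low-density panel of ~3,879 informative SNPs spread over 11 chromosomes,
#' three diverged subpopulations, and a randomized complete block design
#' with 30 blocks.
#'
#' `target_fst` gives the Balding–Nichols divergence of each subpopulation
#' from the ancestral pool; the expected pairwise Weir–Cockerham F_ST between
#' subpopulations i and j is approximately `(F_i + F_j)/2`. The default
#' vector `c(0.056, 0.116, 0.444)` yields pairwise values near 0.086, 0.25
#' and 0.28 — the differentiation reported for the target population.
#'
#' @param n_families number of open-pollinated (maternal) families.
#' @param offspring_per_family genotyped offspring per family.
#' @param n_markers SNP panel size.
#' @param n_chromosomes chromosomes the panel is spread over.
#' @param chromosome_length_bp physical length per chromosome.
#' @param n_subpops number of founder subpopulations.
#' @param target_fst per-subpopulation Balding–Nichols divergence; scalar
#'   recycled to `n_subpops`.
#' @param maf_range ancestral minor-allele-frequency range; the default
#'   minimum 0.1 keeps most simulated markers above the 0.05 QC threshold.
#' @param selfing_rate probability an offspring is selfed rather than sired
#'   by the open pollen pool.
#' @param traits list of [trait_arch()] objects.
#' @param n_blocks randomized-complete-block count.
#' @param block_variance variance of block effects (phenotypes are simulated
#'   with unit non-block variance, so this is relative to the trait scale).
#' @param seed integer RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_families = 49, offspring_per_family = 10,
                       n_markers = 3879, n_chromosomes = 11,
                       chromosome_length_bp = 5e7,
                       n_subpops = 3, target_fst = c(0.056, 0.116, 0.444),
                       maf_range = c(0.1, 0.5), selfing_rate = 0,
                       traits = default_traits(), n_blocks = 30,
                       block_variance = 0.2, seed = 1L) {
  if (length(target_fst) == 1L) target_fst <- rep(target_fst, n_subpops)
  stopifnot(n_families >= 1, offspring_per_family >= 1, n_markers >= 1,
            n_chromosomes >= 1, n_subpops >= 1,
            length(target_fst) == n_subpops,
            all(target_fst >= 0), all(target_fst < 1),
            length(maf_range) == 2, maf_range[1] >= 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            selfing_rate >= 0, selfing_rate <= 1,
            n_blocks >= 1, block_variance >= 0)
  if (n_markers < n_chromosomes) stop("invalid config: n_markers < n_chromosomes")
  structure(list(n_families = n_families,
                 offspring_per_family = offspring_per_family,
                 n_markers = n_markers, n_chromosomes = n_chromosomes,
                 chromosome_length_bp = chromosome_length_bp,
                 n_subpops = n_subpops, target_fst = target_fst,
                 maf_range = maf_range, selfing_rate = selfing_rate,
                 traits = traits, n_blocks = n_blocks,
                 block_variance = block_variance, seed = as.integer(seed)),
            class = "sim_config")
}

#' Trait architecture
#'
#' Describes one simulated trait as a mixture of a few moderate-effect QTLs,
#' an A-structured polygenic background, a diffuse marker background and
#' residual noise, on a unit non-block phenotypic variance scale.
#'
#' @param name trait label.
#' @param n_qtl number of QTLs (markers with fixed effects).
#' @param qtl_variance_fractions per-QTL share of phenotypic variance;
#'   scalar recycled to `n_qtl`.
#' @param polygenic_h2 fraction of variance from the pedigree polygenic term.
#' @param marker_h2 fraction of variance from the diffuse marker background.
#' @param scale `"continuous"`, or `ordinal_scale()` for rated traits.
#' @return List of class `trait_arch`.
#' @export
trait_arch <- function(name, n_qtl = 0, qtl_variance_fractions = numeric(0),
                       polygenic_h2 = 0.2, marker_h2 = 0.1,
                       scale = "continuous") {
  if (n_qtl > 0 && length(qtl_variance_fractions) == 1L) {
    qtl_variance_fractions <- rep(qtl_variance_fractions, n_qtl)
  }
  stopifnot(n_qtl >= 0, length(qtl_variance_fractions) == n_qtl,
            all(qtl_variance_fractions >= 0),
            polygenic_h2 >= 0, marker_h2 >= 0)
  tot <- sum(qtl_variance_fractions) + polygenic_h2 + marker_h2
  if (tot > 1) stop("variance fractions sum to more than 1")
  if (is.list(scale) && !is.null(scale$thresholds) &&
      is.unsorted(scale$thresholds, strictly = TRUE)) {
    stop("ordinal thresholds must be strictly increasing")
  }
  structure(list(name = name, n_qtl = n_qtl,
                 qtl_variance_fractions = qtl_variance_fractions,
                 polygenic_h2 = polygenic_h2, marker_h2 = marker_h2,
                 residual = 1 - tot, scale = scale),
            class = "trait_arch")
}

#' @rdname trait_arch
#' @param levels number of ordinal categories.
#' @param start lowest category value (0 for 0-based ratings, 1 for 1-based).
#' @param thresholds optional explicit latent thresholds (length `levels-1`,
#'   strictly increasing); default = equiprobable quantiles of the latent
#'   trait.
#' @export
ordinal_scale <- function(levels, start = 0L, thresholds = NULL) {
  list(type = "ordinal", levels = as.integer(levels), start = as.integer(start),
       thresholds = thresholds)
}

#' Default seven-trait architecture set
#'
#' Growth (HT, DBH), form (SLD, BHT, STR), wood density (WD) and flowering
#' intensity (FI), with pedigree heritabilities in the low-to-moderate range
#' typical of eucalypt progeny trials (0.08–0.34) and a handful of QTLs each
#' explaining 2–10% of phenotypic variance. STR and FI are rated on 0–3
#' scales and BHT on a 1–5 scale.
#'
#' @return List of [trait_arch()] objects.
#' @export
default_traits <- function() {
  list(
    trait_arch("HT",  n_qtl = 10, qtl_variance_fractions = 0.03,
               polygenic_h2 = 0.20, marker_h2 = 0.10),
    trait_arch("DBH", n_qtl = 12, qtl_variance_fractions = 0.03,
               polygenic_h2 = 0.15, marker_h2 = 0.10),
    trait_arch("SLD", n_qtl = 14, qtl_variance_fractions = 0.025,
               polygenic_h2 = 0.10, marker_h2 = 0.08),
    trait_arch("WD",  n_qtl = 10, qtl_variance_fractions = 0.03,
               polygenic_h2 = 0.17, marker_h2 = 0.12,
               scale = "continuous"),
    trait_arch("STR", n_qtl = 4, qtl_variance_fractions = 0.035,
               polygenic_h2 = 0.20, marker_h2 = 0.15,
               scale = ordinal_scale(4, start = 0L)),
    trait_arch("FI",  n_qtl = 4, qtl_variance_fractions = 0.04,
               polygenic_h2 = 0.30, marker_h2 = 0.08,
               scale = ordinal_scale(4, start = 0L)),
    trait_arch("BHT", n_qtl = 12, qtl_variance_fractions = 0.035,
               polygenic_h2 = 0.08, marker_h2 = 0.06,
               scale = ordinal_scale(5, start = 1L))
  )
}

#' Simulate genotypes for an open-pollinated progeny trial
#'
#' Founder (dam) allele frequencies are drawn per subpopulation from a
#' Balding–Nichols beta model around ancestral frequencies sampled in
#' `maf_range`. Each family has one dam; each offspring receives one
#' Mendelian allele from the dam and one from either the dam again (selfing,
#' probability `selfing_rate`) or an unknown pollen parent drawn from the
#' dam's subpopulation allele frequencies. Markers are assigned evenly to
#' chromosomes with sorted uniform positions. Only offspring are "genotyped"
#' (returned in `geno`); dams are returned separately for founder-level
#' statistics.
#'
#' @param config a [sim_config()].
#' @return List with elements `geno` (offspring [geno_matrix()]), `ped`
#'   (pedigree data.frame `id`, `dam`, `sire`; sires unknown), `subpop`
#'   (named subpopulation label per individual), `founder_geno`
#'   ([geno_matrix()] of dams), `blocks` (named block assignment per
#'   offspring), `selfed` (named logical per offspring) and `allele_freq`
#'   (subpop x marker matrix of generating frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_markers
  # marker map: even split over chromosomes, sorted positions
  chrom <- rep(seq_len(config$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(table(chrom), function(k) {
    sort(sample.int(config$chromosome_length_bp, k))
  }), use.names = FALSE)
  marker_ids <- paste0("snp", seq_len(m))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  p0 <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)  # random minor allele
  pf <- matrix(NA_real_, config$n_subpops, m)
  for (s in seq_len(config$n_subpops)) {
    f <- config$target_fst[s]
    pf[s, ] <- if (f <= 0) p0 else {
      stats::rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
  }
  # keep frequencies away from fixation so panels stay informative
  pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)

  nf <- config$n_families
  fam_subpop <- rep(seq_len(config$n_subpops), length.out = nf)
  dam_ids <- sprintf("dam%02d", seq_len(nf))
  # dam haplotypes: 2 x markers per dam
  dam_h1 <- matrix(0L, nf, m); dam_h2 <- matrix(0L, nf, m)
  for (fam in seq_len(nf)) {
    ps <- pf[fam_subpop[fam], ]
    dam_h1[fam, ] <- as.integer(stats::runif(m) < ps)
    dam_h2[fam, ] <- as.integer(stats::runif(m) < ps)
  }
  founder_codes <- dam_h1 + dam_h2
  rownames(founder_codes) <- dam_ids

  k <- config$offspring_per_family
  n <- nf * k
  off_codes <- matrix(0L, n, m)
  off_ids <- character(n)
  off_fam <- rep(seq_len(nf), each = k)
  selfed <- stats::runif(n) < config$selfing_rate
  for (i in seq_len(n)) {
    fam <- off_fam[i]
    off_ids[i] <- sprintf("off%02d_%02d", fam, (i - 1L) %% k + 1L)
    pick <- stats::runif(m) < 0.5
    maternal <- ifelse(pick, dam_h1[fam, ], dam_h2[fam, ])
    paternal <- if (selfed[i]) {
      pick2 <- stats::runif(m) < 0.5
      ifelse(pick2, dam_h1[fam, ], dam_h2[fam, ])
    } else {
      as.integer(stats::runif(m) < pf[fam_subpop[fam], ])
    }
    off_codes[i, ] <- maternal + paternal
  }
  rownames(off_codes) <- off_ids
  names(selfed) <- off_ids

  ped <- data.frame(id = c(dam_ids, off_ids),
                    dam = c(rep("0", nf), dam_ids[off_fam]),
                    sire = "0", stringsAsFactors = FALSE)
  subpop <- c(stats::setNames(paste0("P", fam_subpop), dam_ids),
              stats::setNames(paste0("P", fam_subpop[off_fam]), off_ids))

  # RCBD with single-tree plots: each genotyped offspring sits in a distinct
  # block within its family (sampled without replacement when possible)
  blocks <- integer(n)
  for (fam in seq_len(nf)) {
    idx <- which(off_fam == fam)
    blocks[idx] <- if (k <= config$n_blocks) {
      sample.int(config$n_blocks, k)
    } else sample.int(config$n_blocks, k, replace = TRUE)
  }
  names(blocks) <- off_ids

  list(geno = geno_matrix(off_codes, chrom = chrom, pos = pos,
                          marker_ids = marker_ids),
       ped = ped, subpop = subpop,
       founder_geno = geno_matrix(founder_codes, chrom = chrom, pos = pos,
                                  marker_ids = marker_ids),
       blocks = blocks, selfed = selfed, allele_freq = pf)
}

#' Simulate phenotypes for one trait
#'
#' Builds `y = block + sum(QTL) + polygenic + marker background + residual`
#' on the offspring: QTL effects are scaled against the realized genotypic
#' variance of their marker so each explains its stated fraction of the
#' (non-block) phenotypic variance in expectation; the polygenic value is
#' drawn from `N(0, h2_a * A)` over the full pedigree; the marker background
#' sums small normal effects over all non-QTL markers. Ordinal traits are
#' produced by thresholding the latent value (equiprobable categories by
#' default).
#'
#' @param geno offspring [geno_matrix()] (no missing calls).
#' @param ped pedigree data.frame as from [simulate_genotypes()].
#' @param arch a [trait_arch()].
#' @param blocks named block assignment per offspring.
#' @param block_variance variance of the block effects.
#' @param seed integer RNG seed.
#' @return List with `pheno` (data.frame `id`, `block`, `<trait>`) and
#'   `truth` (list: `qtl_marker_indices`, `qtl_effects`,
#'   `true_breeding_values`, `realized_h2_components`, `components`).
#' @export
simulate_phenotypes <- function(geno, ped, arch, blocks, block_variance = 0.2,
                                seed = 1L) {
  stopifnot(inherits(arch, "trait_arch"))
  n <- nrow(geno$codes)
  m <- ncol(geno$codes)
  if (arch$n_qtl > m) stop("QTL count exceeds marker count")
  set.seed(as.integer(seed))
  ids <- rownames(geno$codes)
  blocks <- blocks[ids]

  qtl_idx <- integer(0); beta <- numeric(0)
  g_qtl <- rep(0, n)
  if (arch$n_qtl > 0) {
    vx <- apply(geno$codes, 2, stats::var)
    eligible <- which(vx > 0.09)  # avoid near-monomorphic QTLs
    if (length(eligible) < arch$n_qtl) eligible <- which(vx > 0)
    qtl_idx <- sort(unname(sample(eligible, arch$n_qtl)))
    beta <- sqrt(arch$qtl_variance_fractions / vx[qtl_idx]) *
      sample(c(-1, 1), arch$n_qtl, replace = TRUE)
    g_qtl <- drop(geno$codes[, qtl_idx, drop = FALSE] %*% beta)
  }

  a_off <- rep(0, n)
  if (arch$polygenic_h2 > 0) {
    A <- pedigree_A(ped)
    L <- t(chol(A))
    a_all <- sqrt(arch$polygenic_h2) * drop(L %*% stats::rnorm(nrow(A)))
    names(a_all) <- rownames(A)
    a_off <- a_all[ids]
  }

  g_bg <- rep(0, n)
  bg_idx <- setdiff(seq_len(m), qtl_idx)
  if (arch$marker_h2 > 0 && length(bg_idx) > 0) {
    vsum <- sum(apply(geno$codes[, bg_idx, drop = FALSE], 2, stats::var))
    w <- stats::rnorm(length(bg_idx), 0, sqrt(arch$marker_h2 / vsum))
    g_bg <- drop(geno$codes[, bg_idx, drop = FALSE] %*% w)
  }

  e <- stats::rnorm(n, 0, sqrt(max(arch$residual, 0)))
  b_eff <- stats::rnorm(max(blocks), 0, sqrt(block_variance))
  latent <- b_eff[blocks] + g_qtl + a_off + g_bg + e

  y <- latent
  if (is.list(arch$scale) && identical(arch$scale$type, "ordinal")) {
    L <- arch$scale$levels
    thr <- arch$scale$thresholds
    if (is.null(thr)) thr <- stats::quantile(latent, probs = seq_len(L - 1) / L)
    y <- arch$scale$start + findInterval(latent, thr)
  }

  vP <- stats::var(latent - b_eff[blocks])
  truth <- list(
    qtl_marker_indices = qtl_idx,
    qtl_effects = stats::setNames(beta, colnames(geno$codes)[qtl_idx]),
    true_breeding_values = stats::setNames(g_qtl + a_off + g_bg, ids),
    realized_h2_components = c(qtl = if (arch$n_qtl) stats::var(g_qtl) / vP else 0,
                               polygenic = stats::var(a_off) / vP,
                               marker = stats::var(g_bg) / vP),
    components = list(block = b_eff[blocks], qtl = g_qtl, polygenic = a_off,
                      marker_bg = g_bg, residual = e, latent = latent)
  )
  pheno <- data.frame(id = ids, block = as.integer(blocks), y,
                      stringsAsFactors = FALSE)
  names(pheno)[3] <- arch$name
  list(pheno = pheno, truth = truth)
}

#' Simulate a full progeny-trial dataset
#'
#' Runs [simulate_genotypes()] once and [simulate_phenotypes()] for every
#' trait in the configuration, merging the per-trait columns into one
#' phenotype table.
#'
#' @param config a [sim_config()].
#' @return List: `geno`, `ped`, `subpop`, `founder_geno`, `blocks`, `selfed`,
#'   `pheno` (id, block, one column per trait), `truth` (per-trait list).
#' @export
sim_trial <- function(config) {
  gen <- simulate_genotypes(config)
  pheno <- data.frame(id = rownames(gen$geno$codes),
                      block = as.integer(gen$blocks[rownames(gen$geno$codes)]),
                      stringsAsFactors = FALSE)
  truth <- list()
  for (i in seq_along(config$traits)) {
    arch <- config$traits[[i]]
    sim <- simulate_phenotypes(gen$geno, gen$ped, arch, gen$blocks,
                               block_variance = config$block_variance,
                               seed = config$seed + 1000L + i)
    pheno[[arch$name]] <- sim$pheno[[arch$name]]
    truth[[arch$name]] <- sim$truth
  }
  c(gen, list(pheno = pheno, truth = truth))
}
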