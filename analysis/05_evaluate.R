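#!/usr/bin/env Rscript

# Stage 5: cross-validated predictive ability and truth-vs-estimate
# recovery. PA is the Pearson correlation between held-out pre-corrected
# records and predicted breeding values; folds are refit with the stage-3
# marker split held fixed. BRR is used for the CV sweep (the priors rank
# traits almost identically; the stage-4 DIC grid covers all four), with
# 5 folds and 2,500-iteration chains per refit to keep the sweep in
# minutes. The truth record from stage 1 grades QTL detection and the
# realized variance components.

library(gsqpred)

raw <- "scratch/trial_data"
out <- "results/analysis"

codes <- read_genotypes(file.path(raw, "genotypes_qc.csv"), "csv012")$codes
map <- read.delim(file.path(raw, "map_qc.tsv"), stringsAsFactors = FALSE)
geno <- geno_matrix(codes, chrom = map$chrom, pos = map$pos)
pheno <- read_phenotypes(file.path(raw, "phenotypes.csv"))
ped <- read_pedigree(file.path(raw, "pedigree.csv"))
sub <- read.csv(file.path(raw, "subpop.csv"), stringsAsFactors = FALSE)
subpop <- setNames(sub$subpop, sub$id)[as.character(pheno$id)]
struct <- stats::model.matrix(~ factor(subpop))[, -1, drop = FALSE]
rownames(struct) <- pheno$id
truth <- jsonlite::read_json(file.path(raw, "truth.json"),
                             simplifyVector = TRUE)

ids <- rownames(geno$codes)
A <- rel_matrix(unclass(pedigree_A(ped))[ids, ids], kind = "pedigreeA")

rows <- list()
for (tr in c("HT", "DBH")) {
  adj <- adjust_phenotypes(pheno, tr, structure_covariates = struct)
  mta <- read.delim(file.path(out, sprintf("mta_%s.tsv", tr)))
  sig <- match(mta$marker, colnames(geno$codes))
  spec_gs <- model_spec("BRR", "GS", kernels = list(A = A),
                        niter = 2500, burnin = 500, thin = 4, seed = 31L)
  pa_gs <- cross_validate(adj, geno, spec_gs, n_folds = 5, seed = 11L)$mean_pa
  pa_gsq <- NA_real_
  if (length(sig)) {
    spec_gsq <- model_spec("BRR", "GSq",
                           marker_set = setdiff(seq_len(ncol(geno$codes)), sig),
                           significant_markers = sig,
                           kernels = list(A = A, Q = qtl_Q(geno, sig)),
                           niter = 2500, burnin = 500, thin = 4, seed = 31L)
    pa_gsq <- cross_validate(adj, geno, spec_gsq, n_folds = 5,
                             seed = 11L)$mean_pa
  }
  planted <- length(truth[[tr]]$qtl_marker_indices)
  detected <- sum(mta$marker %in%
                    names(truth[[tr]]$qtl_effects))
  rows[[tr]] <- data.frame(trait = tr, n_mta = length(sig),
                           qtl_planted = planted, qtl_detected = detected,
                           pa_gs = round(pa_gs, 3),
                           pa_gsq = round(pa_gsq, 3))
  cat(sprintf("%s: PA(GS) = %.3f, PA(GSq) = %.3f (%d/%d planted QTLs detected)\n",
              tr, pa_gs, pa_gsq, detected, planted))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "cv_predictive_ability.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

recov <- do.call(rbind, lapply(names(truth), function(tr) {
  data.frame(trait = tr,
             realized_qtl = round(truth[[tr]]$realized_h2_components[["qtl"]], 3),
             realized_polygenic = round(truth[[tr]]$realized_h2_components[["polygenic"]], 3),
             realized_marker = round(truth[[tr]]$realized_h2_components[["marker"]], 3))
}))
write.table(recov, file.path(out, "truth_realized_h2.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote CV and truth-recovery tables to", out, "\n")
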