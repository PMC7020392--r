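#!/usr/bin/env Rscript

# Stage 2: SNP quality control (call rate > 0.7, MAF > 0.05), LD-kNN
# imputation, and descriptive population genetics — panel density,
# observed/expected heterozygosity, pairwise Weir-Cockerham F_ST between
# the founder subpopulations. Writes summary tables under results/analysis.

library(gsqpred)

raw <- "scratch/trial_data"
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# the VCF carries the marker map (the 0/1/2 CSV does not)
geno <- read_genotypes(file.path(raw, "genotypes.vcf"), "vcf")
sub <- read.csv(file.path(raw, "subpop.csv"), stringsAsFactors = FALSE)
subpop <- setNames(sub$subpop, sub$id)

geno <- filter_markers(geno)
qc <- attr(geno, "qc")
geno <- impute_knn(geno)
write_genotypes(geno, file.path(raw, "genotypes_qc.csv"), "csv012")
write.table(geno$map, file.path(raw, "map_qc.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

div <- heterozygosity(geno)
fst <- pairwise_fst(geno, subpop[rownames(geno$codes)])

panel <- data.frame(
  n_individuals = nrow(geno$codes),
  n_markers = ncol(geno$codes),
  removed_call_rate = qc$removed_call_rate,
  removed_maf = qc$removed_maf,
  markers_per_chromosome = ncol(geno$codes) / length(unique(geno$map$chrom)),
  ho = div$ho, he = div$he)
write.table(panel, file.path(out, "panel_summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.csv(round(fst, 4), file.path(out, "fst_pairwise.csv"), quote = FALSE)

cat(sprintf("QC: %d markers retained (%d removed by call rate, %d by MAF)\n",
            qc$retained, qc$removed_call_rate, qc$removed_maf))
cat(sprintf("diversity: Ho = %.3f, He = %.3f\n", div$ho, div$he))
cat("pairwise F_ST:\n"); print(round(fst, 3))
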