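#!/usr/bin/env Rscript

# Stage 1: generate the synthetic open-pollinated progeny trial under the
# study conditions the package emulates — 49 maternal families x 10
# genotyped offspring (490 trees), 3,879 SNPs on 11 chromosomes, three
# founder subpopulations with pairwise F_ST near 0.086/0.25/0.28, seven
# traits (growth, form, wood density, flowering) in 30 blocks — and write
# the raw trial files. Bulky raw data go to scratch/ (intermediates); the
# truth record needed by later stages goes with them.

library(gsqpred)

out <- "scratch/trial_data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 2026L)
dat <- sim_trial(cfg)

write_genotypes(dat$geno, file.path(out, "genotypes.csv"), "csv012")
write_genotypes(dat$geno, file.path(out, "genotypes.vcf"), "vcf")
write_pedigree(dat$ped, file.path(out, "pedigree.csv"))
write_phenotypes(dat$pheno, file.path(out, "phenotypes.csv"))
write.csv(data.frame(id = names(dat$subpop), subpop = dat$subpop),
          file.path(out, "subpop.csv"), row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  lapply(dat$truth, function(tr) {
    tr$components <- NULL  # per-individual draws stay in memory only
    # named vectors must become lists to keep their names in JSON
    tr$qtl_effects <- as.list(tr$qtl_effects)
    tr$true_breeding_values <- as.list(tr$true_breeding_values)
    tr$realized_h2_components <- as.list(tr$realized_h2_components)
    tr
  }),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = 10)

cat(sprintf("simulated %d offspring x %d markers, %d traits -> %s\n",
            nrow(dat$geno$codes), ncol(dat$geno$codes),
            length(cfg$traits), out))
cat("per-trait planted QTLs:",
    paste(sprintf("%s=%d", names(dat$truth),
                  sapply(dat$truth, function(t) length(t$qtl_marker_indices))),
          collapse = ", "), "\n")
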