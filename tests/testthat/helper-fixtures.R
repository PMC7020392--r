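# Shared fixture builders; everything is generated in code.

toy_geno <- function(codes, chrom = NULL, pos = NULL) {
  geno_matrix(as.matrix(codes), chrom = chrom, pos = pos)
}

# small panmictic trial used by several statistical tests
small_trial <- function(seed = 1, n_families = 20, offspring = 8,
                        n_markers = 300, traits = list(), n_subpops = 1,
                        target_fst = 0, ...) {
  sim_trial(sim_config(n_families = n_families,
                       offspring_per_family = offspring,
                       n_markers = n_markers, n_chromosomes = 5,
                       n_subpops = n_subpops, target_fst = target_fst,
                       traits = traits, seed = seed, ...))
}

# Wright's path-counting coefficients for a 5-individual pedigree used as an
# independent oracle for the tabular method:
#   F1, F2 founders; O1 = F1 x F2; G1 = O1 x F2; U unrelated founder.
# a(F1,O1) = (1/2)^1 ... a(G1,G1) = 1 + (1/2) a(O1,F2).
wright_pedigree <- function() {
  data.frame(id = c("F1", "F2", "O1", "G1", "U"),
             dam = c("0", "0", "F1", "O1", "0"),
             sire = c("0", "0", "F2", "F2", "0"),
             stringsAsFactors = FALSE)
}

wright_expected <- function() {
  A <- matrix(0, 5, 5, dimnames = list(c("F1","F2","O1","G1","U"),
                                       c("F1","F2","O1","G1","U")))
  diag(A) <- 1
  A["G1","G1"] <- 1.25          # parents O1 and F2 share a = 0.5
  A["F1","O1"] <- A["O1","F1"] <- 0.5
  A["F2","O1"] <- A["O1","F2"] <- 0.5
  A["F1","G1"] <- A["G1","F1"] <- 0.25
  A["F2","G1"] <- A["G1","F2"] <- 0.75
  A["O1","G1"] <- A["G1","O1"] <- 0.75
  A
}

# pedigree A restricted to the genotyped offspring of a simulated trial
offspring_A <- function(dat, ...) {
  ids <- rownames(dat$geno$codes)
  rel_matrix(unclass(pedigree_A(dat$ped, ...))[ids, ids], kind = "pedigreeA")
}
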