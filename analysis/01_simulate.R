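#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic paired study.
#
# Emulates six colorectal tumor/normal pairs profiled by MeDIP-seq (5mC)
# and hMeDIP-seq (5hmC) over a 2 x 1 Mb genome, with an RNA-seq count
# matrix.  Planted truth: promoter hyper-5mC regions (half coupled to
# promoter hypo-5hmC and down-regulation), random differential regions,
# extra DEGs, and a global tumor 5hmC signal depletion (factor 0.7).

source(file.path("analysis", "config.R"))

cfg <- study_config()
print(cfg)
sim <- simulate_all(cfg, fragments = FALSE)
cat("\nGenome:", length(sim$annotation$chromosomes), "chromosomes,",
    format(sum(sim$annotation$chromosomes), big.mark = ","), "bp;",
    sum(lengths(sim$annotation$cpg_sites)), "CpG sites;",
    nrow(sim$annotation$genes), "genes\n")
print(sim$tracks$truth)

truth <- sim$tracks$truth
write_table(truth$planted_regions, "01_planted_regions.tsv")
write_table(truth$planted_degs, "01_planted_degs.tsv")
write_table(truth$couplings, "01_coupled_genes.tsv")
write_table(chromosome_features(sim$annotation), "01_chromosome_features.tsv")

cat("\nThe planted truth above is what stages 3-6 must recover.\n")
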