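#!/usr/bin/env Rscript
# Stage 5 -- genome-scale patterns.
#
# (a) PCA of samples over window RPM with silhouette-scored tumor/normal
#     separation, per assay;
# (b) the binned (20 rank classes) 5mC-vs-5hmC regression with
#     tumor/normal slope comparison;
# (c) tumor-vs-normal variability of the TSS metaprofile;
# (d) chromosome feature / depth correlations on an 8-chromosome design.

source(file.path("analysis", "config.R"))

cfg <- study_config()
sim <- simulate_all(cfg, fragments = FALSE)
mc <- sim_track_matrix(sim$tracks, "5mC")
hmc <- sim_track_matrix(sim$tracks, "5hmC")

p_mc <- pca_separation(mc)
p_hmc <- pca_separation(hmc)
cat(sprintf("Silhouette (first two PCs): 5mC %.3f, 5hmC %.3f\n",
            p_mc$silhouette, p_hmc$silhouette))

sl <- mc_hmc_regression(mc, hmc)
cat(sprintf("Binned 5hmC~5mC: normal slope %.3f (r %.3f), tumor slope %.3f (r %.3f)\n",
            sl$normal$slope, sl$normal$r, sl$tumor$slope, sl$tumor$r))
cat("The tumor slope sits below the normal slope: the flattened gradient\n",
    "of hydroxymethylation against methylation that marks global 5hmC loss.\n")

ann <- sim$annotation
tss <- ifelse(ann$genes$strand == "+", ann$genes$start, ann$genes$end)
anchors <- GenomicRanges::GRanges(ann$genes$chrom,
                                  IRanges::IRanges(tss + 1L, tss + 1L),
                                  strand = ann$genes$strand)
mp <- metaprofile(hmc, anchors)
vc <- variability_compare(mp$group_sd[, "tumor"], mp$group_sd[, "normal"])
cat(sprintf("Profile SD, tumor vs normal: %.3f vs %.3f (paired p = %.3g)\n",
            vc$mean_sd_tumor, vc$mean_sd_normal, vc$p))

write_table(data.frame(
  metric = c("silhouette_5mC", "silhouette_5hmC", "slope_normal",
             "slope_tumor", "r_normal", "r_tumor", "sd_profile_p"),
  value = c(p_mc$silhouette, p_hmc$silhouette, sl$normal$slope,
            sl$tumor$slope, sl$normal$r, sl$tumor$r, vc$p)),
  "05_global_patterns.tsv")
write_table(cbind(group = "normal", sl$normal$class_means),
            "05_slope_classes_normal.tsv")
write_table(cbind(group = "tumor", sl$tumor$class_means),
            "05_slope_classes_tumor.tsv")

# chromosome-feature correlations need >= 3 chromosomes: use a wider
# 8 x 250 kb design of the same generative model
cfg8 <- sim_config(seed = ANALYSIS_SEED + 1L, n_chromosomes = 8L,
                   chrom_length = 2.5e5, n_genes = 150L)
sim8 <- simulate_all(cfg8, fragments = FALSE)
feats <- chromosome_features(sim8$annotation)
tr8 <- lapply(c(`5mC` = "5mC", `5hmC` = "5hmC"), function(a)
  sim_track_matrix(sim8$tracks, a))
chrom <- as.character(GenomicRanges::seqnames(tr8[["5mC"]]$windows))
depths <- do.call(cbind, lapply(tr8, function(t)
  apply(t$rpm, 2, function(v) tapply(v, chrom, mean))))
samples <- rbind(tr8[["5mC"]]$samples, tr8[["5hmC"]]$samples)
fc <- feature_correlations(feats, depths[feats$chrom, ], samples)
cat("\nChromosome feature correlations (8-chromosome design):\n")
print(fc[order(fc$feature), c("feature", "assay", "group", "r", "p")],
      digits = 2)
write_table(fc, "05_feature_correlations.tsv")
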