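# Generator: determinism, degenerate configs, Poisson CpG placement,
# planted-effect magnitudes and the analytic generative-model means.

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_pairs = 1), "pairs")
  expect_error(sim_config(hmc_global_factor = 0), "hmc_global_factor")
  expect_error(sim_config(hmc_global_factor = 1.2), "hmc_global_factor")
  expect_error(sim_config(element_fractions = c(CGI = 0.5, SINE = 0.6)),
               "capacity")
  expect_error(sim_config(element_fractions = c(CGI = -0.1)), "fractions")
  expect_error(sim_config(window_size = 0), "window_size")
})

test_that("annotation is deterministic and honours empty gene lists", {
  cfg <- sim_config(seed = 5, n_genes = 0L, chrom_length = 2e5)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$genes), 0L)
  # elements still placed
  expect_gt(sum(lengths(a1$elements)), 0L)
})

test_that("CpG placement follows the stated Poisson rate", {
  # no CGIs -> pure background process at cpg_density per kb
  cfg <- sim_config(seed = 2, n_chromosomes = 1L, chrom_length = 1e6,
                    cpg_density = 10, n_genes = 0L,
                    element_fractions = c(CGI = 0, SINE = 0.1, LINE = 0.1,
                                          LTR = 0.02, enhancer = 0.01))
  ann <- generate_annotation(cfg)
  n <- length(ann$cpg_sites$chr1)
  lambda <- 1e6 * 10 / 1000
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  expect_true(all(diff(ann$cpg_sites$chr1) > 0))
})

test_that("track simulation is deterministic and counts are independent of fragment materialization", {
  cfg <- sim_config(seed = 9, chrom_length = 1e5, n_genes = 20L,
                    n_planted_dmr = 4L, n_planted_dhmr = 4L,
                    n_planted_deg = 6L)
  ann <- generate_annotation(cfg)
  s1 <- simulate_tracks(ann, cfg, fragments = TRUE)
  s2 <- simulate_tracks(ann, cfg, fragments = TRUE)
  s3 <- simulate_tracks(ann, cfg, fragments = FALSE)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(s1$counts, s3$counts)
  expect_null(s3$fragments)
})

test_that("null configuration plants nothing and groups differ only by noise", {
  cfg <- sim_config(seed = 4, chrom_length = 2e5, n_genes = 10L,
                    n_planted_dmr = 0L, n_planted_dhmr = 0L,
                    n_planted_deg = 0L, hmc_global_factor = 1)
  sim <- simulate_all(cfg, fragments = FALSE)
  expect_equal(nrow(sim$tracks$truth$planted_regions), 0L)
  expect_equal(nrow(sim$tracks$truth$planted_degs), 0L)
  mc <- sim_track_matrix(sim$tracks, "5mC")
  gt <- mean(mc$rpm[, mc$samples$group == "tumor"])
  gn <- mean(mc$rpm[, mc$samples$group == "normal"])
  expect_lt(abs(gt / gn - 1), 0.02)
})

test_that("planted hyper regions carry the configured fold in expectation", {
  # oracle: mean of NB draws over seeded replicates approaches
  # 2^effect_log2 x the normal-group mean
  base_cfg <- function(seed) sim_config(
    seed = seed, n_chromosomes = 1L, chrom_length = 1e5, n_genes = 10L,
    n_planted_dmr = 2L, n_planted_dhmr = 0L, n_planted_deg = 0L,
    coupled_fraction = 0, effect_log2 = 2)
  ann <- generate_annotation(base_cfg(1))
  windows <- tile_genome(ann, 500L)
  ratios <- sapply(2001:2060, function(s) {
    cfg <- base_cfg(s)
    sim <- simulate_tracks(ann, cfg, fragments = FALSE)
    pr <- sim$truth$planted_regions
    hyper <- pr[pr$direction == "hyper", ]
    wix <- which(IRanges::overlapsAny(windows, gr0(hyper$chrom, hyper$start,
                                                   hyper$end)))
    tum <- sim$samples$assay == "5mC" & sim$samples$group == "tumor"
    nor <- sim$samples$assay == "5mC" & sim$samples$group == "normal"
    mean(sim$counts[wix, tum]) / mean(sim$counts[wix, nor])
  })
  expect_lt(abs(mean(ratios) - 4), 0.25)
})

test_that("global 5hmC depletion matches the analytic generative mean", {
  cfg <- sim_config(seed = 6, chrom_length = 2e5, n_genes = 20L,
                    n_planted_dmr = 0L, n_planted_dhmr = 0L,
                    n_planted_deg = 0L, hmc_global_factor = 0.7)
  ann <- generate_annotation(cfg)
  am <- analytic_window_means(ann, cfg)
  expected_ratio <- sum(am$hmc_tumor) / sum(am$hmc_normal)
  expect_lt(expected_ratio, 1)  # depletion present in expected counts
  reps <- sapply(1:40, function(k) {
    cfg2 <- cfg; cfg2$seed <- 1000L + k
    sim <- simulate_tracks(ann, cfg2, fragments = FALSE)
    tum <- sim$samples$assay == "5hmC" & sim$samples$group == "tumor"
    nor <- sim$samples$assay == "5hmC" & sim$samples$group == "normal"
    sum(sim$counts[, tum]) / sum(sim$counts[, nor])
  })
  expect_lt(abs(mean(reps) - expected_ratio), 0.02)
})

test_that("planted truth satisfies its structural invariants", {
  sim <- small_sim(seed = 13, n_planted_dmr = 20L, n_planted_dhmr = 20L,
                   n_planted_deg = 25L, coupled_fraction = 0.6)
  truth <- sim$tracks$truth
  windows <- sim$tracks$windows
  pr <- truth$planted_regions
  for (assay in c("5mC", "5hmC")) {
    sub <- pr[pr$assay == assay, ]
    gr <- gr0(sub$chrom, sub$start, sub$end)
    hits <- GenomicRanges::findOverlaps(gr, gr)
    expect_equal(length(hits), length(gr))  # only self-overlaps
  }
  # every planted region lies in CpG-eligible windows
  gr <- gr0(pr$chrom, pr$start, pr$end)
  hit_windows <- unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(gr, windows)))
  expect_true(all(S4Vectors::mcols(windows)$n_cpg[hit_windows] >= 5))
  # every coupled gene appears among planted DEGs, direction down
  expect_true(all(truth$couplings$gene_id %in% truth$planted_degs$gene_id))
  cp <- truth$planted_degs[truth$planted_degs$gene_id %in%
                             truth$couplings$gene_id, ]
  expect_true(all(cp$direction == "down"))
})

test_that("expression simulation reproduces planted folds and is deterministic", {
  cfg <- sim_config(seed = 21, chrom_length = 3e5, n_genes = 60L,
                    n_planted_dmr = 10L, n_planted_dhmr = 10L,
                    n_planted_deg = 12L, deg_fold = 2,
                    coupled_fraction = 0.5)
  ann <- generate_annotation(cfg)
  tr <- simulate_tracks(ann, cfg, fragments = FALSE)
  e1 <- simulate_expression(ann, tr$truth, cfg)
  e2 <- simulate_expression(ann, tr$truth, cfg)
  expect_identical(e1$counts, e2$counts)
  # replicate oracle for the tumor/normal RPKM ratio of planted down genes
  down <- tr$truth$planted_degs$gene_id[tr$truth$planted_degs$direction ==
                                          "down"]
  ratios <- sapply(1:30, function(k) {
    cfg2 <- cfg; cfg2$seed <- 5000L + k
    ex <- simulate_expression(ann, tr$truth, cfg2)
    lib <- colSums(ex$counts)
    rpkm <- sweep(sweep(ex$counts, 2, lib, "/"), 1,
                  ex$gene_length[rownames(ex$counts)], "/") * 1e9
    tum <- ex$samples$group == "tumor"
    mean(rowMeans(rpkm[down, tum, drop = FALSE]) /
           rowMeans(rpkm[down, !tum, drop = FALSE]))
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
  # truth referencing unknown genes errors
  bad <- tr$truth
  bad$planted_degs <- rbind(bad$planted_degs,
                            data.frame(gene_id = "NOPE", direction = "down",
                                       fold = 2, coupled = FALSE))
  expect_error(simulate_expression(ann, bad, cfg), "absent")
})
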