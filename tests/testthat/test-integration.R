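# Promoter mapping, modification/expression correlation, the directional
# candidate screen, and over-representation testing.

two_gene_annotation <- function() {
  genes <- data.frame(
    gene_id = c("Gplus", "Gminus"),
    chrom = "chrA", strand = c("+", "-"),
    start = c(5000L, 8000L), end = c(7000L, 10000L),
    exons = c("5000-7000", "8000-10000"), stringsAsFactors = FALSE)
  gene_annotation(c(chrA = 20000), genes)
}

region_df <- function(start, end, direction, assay = "5mC", p = 0.01) {
  data.frame(assay = assay, chrom = "chrA", start = start, end = end,
             direction = direction, p = p, mean_tumor_rpm = 1,
             mean_normal_rpm = 1, n_windows = 1L, n_cpg = 6L,
             stringsAsFactors = FALSE)
}

test_that("promoter mapping is strand-aware with half-open bounds", {
  ann <- two_gene_annotation()
  # promoter of Gplus: [4500, 5500); of Gminus (TSS = end): [9500, 10500)
  hits <- map_promoter_regions(region_df(5100, 5200, "hyper"), ann)
  expect_equal(hits$gene_id, "Gplus")
  # region at TSS + 600 with zero overlap -> no hit
  expect_equal(nrow(map_promoter_regions(region_df(5600, 5800, "hyper"),
                                         ann)), 0L)
  hits_m <- map_promoter_regions(region_df(9600, 9700, "hypo"), ann)
  expect_equal(hits_m$gene_id, "Gminus")
  # book-ended region just before the promoter start does not hit
  expect_equal(nrow(map_promoter_regions(region_df(4400, 4500, "hyper"),
                                         ann)), 0L)
  # one bp of overlap hits
  expect_equal(nrow(map_promoter_regions(region_df(4400, 4501, "hyper"),
                                         ann)), 1L)
})

test_that("mixed-direction promoter evidence is flagged ambiguous", {
  ann <- two_gene_annotation()
  regs <- rbind(region_df(4600, 4800, "hyper"), region_df(5100, 5300, "hypo"))
  hits <- map_promoter_regions(regs, ann)
  expect_true(hits$ambiguous[hits$gene_id == "Gplus"])
  expect_true(is.na(hits$direction[hits$gene_id == "Gplus"]))
})

test_that("the screen keeps only direction-coherent three-way candidates", {
  mk_hits <- function(gene, dir, assay) {
    data.frame(gene_id = gene, assay = assay, direction = dir,
               n_regions = 1L, min_p = 0.01, ambiguous = FALSE,
               stringsAsFactors = FALSE)
  }
  degs <- data.frame(gene_id = c("A", "B", "C", "D"),
                     deg = c(TRUE, TRUE, TRUE, FALSE),
                     direction = c("down", "up", "down", NA),
                     n_up = 0L, n_down = 4L, q_median = c(0.01, 0.02, 0.03,
                                                          0.9),
                     mean_log2_ratio = -1, stringsAsFactors = FALSE)
  hits_mc <- rbind(mk_hits("A", "hyper", "5mC"),  # coherent repressed
                   mk_hits("B", "hyper", "5mC"),  # DEG up: incoherent
                   mk_hits("D", "hyper", "5mC"))  # not a DEG
  hits_hmc <- rbind(mk_hits("A", "hypo", "5hmC"),
                    mk_hits("B", "hypo", "5hmC"),
                    mk_hits("D", "hypo", "5hmC"))
  sc <- screen_candidates(hits_mc, hits_hmc, degs)
  expect_equal(sc$candidates$gene_id, "A")
  expect_equal(sc$candidates$class, "repressed")
  # two-way intersections reported for transparency
  expect_setequal(sc$intersections$dmr_dhmr, c("A", "B", "D"))
  expect_setequal(sc$intersections$dmr_deg, c("A", "B"))
  # gene with only one mark is never a candidate
  sc2 <- screen_candidates(mk_hits("C", "hyper", "5mC"),
                           hits_hmc[0, ], degs)
  expect_equal(nrow(sc2$candidates), 0L)
  # empty inputs -> empty candidate list
  sc0 <- screen_candidates(hits_mc[0, ], hits_hmc[0, ], degs[0, ])
  expect_equal(nrow(sc0$candidates), 0L)
})

test_that("activated mirror-image candidates are classified", {
  hits_mc <- data.frame(gene_id = "E", assay = "5mC", direction = "hypo",
                        n_regions = 1L, min_p = 0.01, ambiguous = FALSE)
  hits_hmc <- data.frame(gene_id = "E", assay = "5hmC", direction = "hyper",
                         n_regions = 1L, min_p = 0.01, ambiguous = FALSE)
  degs <- data.frame(gene_id = "E", deg = TRUE, direction = "up",
                     n_up = 5L, n_down = 0L, q_median = 0.001,
                     mean_log2_ratio = 1.2)
  sc <- screen_candidates(hits_mc, hits_hmc, degs)
  expect_equal(sc$candidates$class, "activated")
})

test_that("screen recovery is exact on fully coupled, low-noise data", {
  cfg <- sim_config(seed = 51, chrom_length = 5e5, n_genes = 80L,
                    n_planted_dmr = 12L, n_planted_dhmr = 6L,
                    coupled_fraction = 1, n_planted_deg = 6L,
                    nb_dispersion = 0.005, expr_dispersion = 0.01,
                    effect_log2 = 2, deg_fold = 3)
  sim <- simulate_all(cfg, fragments = FALSE)
  truth <- sim$tracks$truth
  regions <- lapply(c(`5mC` = "5mC", `5hmC` = "5hmC"), function(a)
    merge_to_regions(test_windows(sim_track_matrix(sim$tracks, a))))
  ex <- sim$expression
  degs <- call_degs(pairwise_expression_tests(ex$counts, ex$samples,
                                              ex$gene_length))
  sc <- screen_candidates(map_promoter_regions(regions[["5mC"]],
                                               sim$annotation),
                          map_promoter_regions(regions[["5hmC"]],
                                               sim$annotation), degs)
  expect_setequal(sc$candidates$gene_id, truth$couplings$gene_id)
  expect_true(all(sc$candidates$class == "repressed"))
})

test_that("tightening thresholds never adds candidates", {
  sim <- small_sim(seed = 57, n_planted_dmr = 12L, n_planted_dhmr = 8L,
                   coupled_fraction = 1, n_planted_deg = 10L)
  wts <- lapply(c(`5mC` = "5mC", `5hmC` = "5hmC"), function(a)
    test_windows(sim_track_matrix(sim$tracks, a)))
  ex <- sim$expression
  tbl <- pairwise_expression_tests(ex$counts, ex$samples, ex$gene_length)
  cand <- function(alpha, min_abs_log2) {
    regs <- lapply(wts, merge_to_regions, alpha = alpha)
    degs <- call_degs(tbl, min_abs_log2 = min_abs_log2)
    screen_candidates(map_promoter_regions(regs[["5mC"]], sim$annotation),
                      map_promoter_regions(regs[["5hmC"]], sim$annotation),
                      degs)$candidates$gene_id
  }
  loose <- cand(0.05, 0.585)
  expect_true(all(cand(0.01, 0.585) %in% loose))
  expect_true(all(cand(0.05, 1.2) %in% loose))
  expect_true(all(cand(0.001, 1.5) %in% cand(0.01, 1.2)))
})

test_that("expression/modification correlations recover generative signs", {
  set.seed(61)
  n <- 60L
  genes <- data.frame(
    gene_id = sprintf("G%02d", 1:n), chrom = "chrA", strand = "+",
    start = seq(5000L, by = 6000L, length.out = n),
    end = seq(5000L, by = 6000L, length.out = n) + 3000L,
    stringsAsFactors = FALSE)
  genes$exons <- sprintf("%d-%d", genes$start, genes$end)
  ann <- gene_annotation(c(chrA = 6000 * n + 10000), genes)
  win <- tile_genome(ann, 500L)
  sheet_mc <- paired_sheet(2, "5mC"); sheet_hmc <- paired_sheet(2, "5hmC")
  prom_mc <- runif(n, 1, 9)
  rpm_mc <- matrix(1, length(win), 4, dimnames = list(NULL, sheet_mc$sample))
  prom_win <- match(genes$start %/% 500L, bed_frame(win)$start %/% 500L)
  rpm_mc[prom_win, ] <- prom_mc
  t_mc <- manual_track(rpm_mc, win, sheet_mc)
  t_hmc <- manual_track(matrix(2, length(win), 4,
                               dimnames = list(NULL, sheet_hmc$sample)),
                        win, sheet_hmc)
  # expression constructed as a decreasing function of promoter 5mC
  counts <- matrix(rep(round(2000 / prom_mc), 4), n, 4,
                   dimnames = list(genes$gene_id,
                                   paired_sheet(2, "rna")$sample))
  ex <- pairwise_expression_tests(counts, paired_sheet(2, "rna"),
                                  setNames(rep(3000L, n), genes$gene_id))
  mec <- modification_expression_correlation(t_mc, t_hmc, ex, ann)
  rho_prom <- mec$correlations$rho[mec$correlations$assay == "5mC" &
                                     mec$correlations$region == "promoter"]
  expect_lt(rho_prom, -0.8)
  # high/low split contrast points the same way
  cc <- mec$class_contrast[mec$class_contrast$measure == "promoter_5mC", ]
  expect_lt(cc$mean_high, cc$mean_low)
  expect_lt(cc$p, 0.01)
  # independent expression stays inside the permutation null envelope
  counts2 <- counts[sample(n), ]
  rownames(counts2) <- genes$gene_id
  ex2 <- pairwise_expression_tests(counts2, paired_sheet(2, "rna"),
                                   setNames(rep(3000L, n), genes$gene_id))
  mec2 <- modification_expression_correlation(t_mc, t_hmc, ex2, ann)
  rho2 <- mec2$correlations$rho[mec2$correlations$assay == "5mC" &
                                  mec2$correlations$region == "promoter"]
  e_fixed <- log2(rowMeans(ex2$rpkm[, ex2$samples$group == "tumor"]) + 0.1)
  v_fixed <- prom_mc
  null_rho <- replicate(1000, cor(sample(e_fixed), v_fixed,
                                  method = "spearman"))
  env <- quantile(null_rho, c(0.005, 0.995))
  expect_gt(rho2, env[1]); expect_lt(rho2, env[2])
  expect_error(modification_expression_correlation(
    t_mc, t_hmc, structure(list(rpkm = ex$rpkm[1:5, ],
                                samples = ex$samples),
                           class = "expression_table"), ann),
    "10 shared genes")
})

test_that("over-representation testing matches the hypergeometric tail", {
  universe <- sprintf("G%03d", 1:200)
  gene_list <- universe[1:20]
  sets <- list(hit = universe[1:20], partial = universe[11:40],
               disjoint = universe[150:180])
  res <- ora_test(gene_list, sets, universe)
  expect_equal(res$set[1], "hit")
  expect_equal(res$p[res$set == "disjoint"], 1)
  # hypergeometric tail oracle for the partial set
  a <- length(intersect(gene_list, sets$partial))
  p_oracle <- phyper(a - 1, length(sets$partial),
                     200 - length(sets$partial), 20, lower.tail = FALSE)
  expect_equal(res$p[res$set == "partial"], p_oracle, tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(ora_test(gene_list, sets, character(0)), "universe")
  # p-values under random gene lists are roughly uniform
  set.seed(71)
  ps <- replicate(400, ora_test(sample(universe, 20),
                                sets["partial"], universe)$p)
  expect_gt(mean(ps), 0.35)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("GMT round trip preserves set membership", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG9"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(setA = c("G1", "G2", "G3"), setB = "G9"))
})
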