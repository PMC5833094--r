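# Tiling, midpoint counting, RPM normalization, coverage curves, element
# aggregation and metaprofiles.

test_that("tiling partitions chromosomes and keeps the trailing window", {
  ann <- bare_annotation(c(chrA = 1500, chrB = 1200),
                         list(chrA = c(10L, 60L, 700L), chrB = integer(0)))
  win <- tile_genome(ann, 500L)
  bf <- bed_frame(win)
  a <- bf[bf$chrom == "chrA", ]
  expect_equal(a$start, c(0, 500, 1000))
  expect_equal(a$end, c(500, 1000, 1500))
  b <- bf[bf$chrom == "chrB", ]
  expect_equal(b$end, c(500, 1000, 1200))   # trailing [1000,1200) retained
  # partition: widths sum to genome length, no overlaps
  expect_equal(sum(bf$end - bf$start), 2700)
  expect_true(all(tapply(bf$start, bf$chrom, function(s) all(diff(s) == 500))))
  # CpG counting per window
  expect_equal(S4Vectors::mcols(win)$n_cpg[1:3], c(2L, 1L, 0L))
})

test_that("sliding tiling produces half-overlapping windows", {
  ann <- bare_annotation(c(chrA = 2000))
  win <- tile_genome(ann, 500L, step = 250L)
  bf <- bed_frame(win)
  expect_equal(bf$start, seq(0, 1750, by = 250))
  expect_true(all(bf$end - bf$start <= 500))
})

test_that("midpoint counting respects the boundary rule and RPM closed form", {
  ann <- bare_annotation(c(chrA = 2000))
  win <- tile_genome(ann, 500L)
  # fragment [400, 600): 0-based midpoint 500 -> second window
  fr <- gr0(rep("chrA", 11), c(400, rep(10, 10)), c(600, rep(210, 10)))
  tm <- count_and_normalize(list(s1 = fr), win)
  expect_equal(tm$counts[, 1], c(10, 1, 0, 0))
  expect_equal(tm$library_sizes[["s1"]], 11)
  # 10 fragments in a window with a 10^6 library -> RPM 10
  big <- gr0(rep("chrA", 1e6), rep(c(10, 600), c(10, 1e6 - 10)),
             rep(c(210, 800), c(10, 1e6 - 10)))
  tm2 <- count_and_normalize(list(s1 = big), win)
  expect_equal(unname(tm2$rpm[1, 1]), 10)
  expect_equal(unname(tm2$rpm[3, 1]), 0)  # empty window
})

test_that("counting conserves library size and RPM is scale-invariant", {
  sim <- small_sim(seed = 3)
  cfg <- sim$tracks$config
  sim_f <- simulate_tracks(sim$annotation, cfg, fragments = TRUE)
  idx <- which(sim_f$samples$assay == "5mC")[1:4]
  fr <- sim_f$fragments[idx]
  win <- tile_genome(sim$annotation, 500L)
  tm <- count_and_normalize(fr, win)
  expect_equal(unname(colSums(tm$counts)), unname(lengths(fr)))
  # counting the materialized fragments reproduces the drawn counts exactly
  expect_equal(unname(tm$counts), unname(sim_f$counts[, idx]))
  # doubling every fragment set leaves RPM unchanged
  tm2 <- count_and_normalize(lapply(fr, function(g) c(g, g)), win)
  expect_equal(tm2$rpm, tm$rpm)
})

test_that("fragments on unknown chromosomes are skipped with a warning", {
  ann <- bare_annotation(c(chrA = 1000))
  win <- tile_genome(ann, 500L)
  fr <- suppressWarnings(c(gr0("chrA", 100, 300), gr0("chrZ", 100, 300)))
  expect_warning(tm <- count_and_normalize(list(s1 = fr), win), "unknown")
  expect_equal(tm$skipped[["s1"]], 1L)
  expect_equal(tm$library_sizes[["s1"]], 1)
})

test_that("coverage summary matches a brute-force per-site depth oracle", {
  ann <- bare_annotation(c(chrA = 1000), list(chrA = c(5L, 250L, 600L, 999L)))
  # every CpG covered by exactly 4 fragments
  fr <- gr0(rep("chrA", 4), rep(0, 4), rep(1000, 4))
  cs <- coverage_summary(fr, ann$cpg_sites, max_depth = 6L)
  expect_equal(cs$fraction, c(1, 1, 1, 1, 0, 0))
  # no fragments -> all zero
  cs0 <- coverage_summary(GenomicRanges::GRanges(), ann$cpg_sites)
  expect_equal(cs0$fraction, rep(0, 10))
  expect_true(all(diff(cs0$fraction) <= 0))
  # random fragments vs direct enumeration
  set.seed(42)
  s0 <- sample(0:900, 200, replace = TRUE)
  frr <- gr0(rep("chrA", 200), s0, s0 + sample(50:100, 200, replace = TRUE))
  sites <- ann$cpg_sites$chrA
  depth_oracle <- sapply(sites, function(p)
    sum(p >= bed_frame(frr)$start & p < bed_frame(frr)$end))
  csr <- coverage_summary(frr, ann$cpg_sites, max_depth = 10L)
  expect_equal(csr$fraction,
               sapply(1:10, function(d) mean(depth_oracle >= d)))
  expect_error(coverage_summary(frr, list(chrA = integer(0))), "CpG")
})

test_that("element aggregation averages overlapping windows and flags empties", {
  ann <- bare_annotation(c(chrA = 2000))
  ann$elements$enhancer <- gr0("chrA", 300, 700)  # spans windows 1 and 2
  win <- tile_genome(ann, 500L)
  rpm <- matrix(c(1, 3, 7, 9), 4, 1, dimnames = list(NULL, "s1"))
  tm <- manual_track(rpm, win)
  agg <- aggregate_by_element(tm, ann, "enhancer")
  expect_equal(unname(agg$means["s1"]), 2)     # mean of {1, 3}
  expect_equal(agg$n_windows, 2L)
  # class with zero overlap: undefined, not zero
  empty <- aggregate_by_element(tm, ann, "LTR")
  expect_true(empty$undefined)
  expect_true(all(is.na(empty$means)))
})

test_that("CGI shores are the CGI-subtracted 2-kb flanks", {
  ann <- bare_annotation(c(chrA = 20000))
  ann$elements$CGI <- gr0("chrA", 5000, 6000)
  sh <- element_ranges(ann, "CGI_shore")
  bf <- bed_frame(sh)
  expect_equal(bf$start, c(3000, 6000))
  expect_equal(bf$end, c(5000, 8000))
})

test_that("identical tumor/normal tracks give the degenerate p = 1", {
  ann <- bare_annotation(c(chrA = 2000))
  ann$elements$enhancer <- gr0("chrA", 0, 2000)
  win <- tile_genome(ann, 500L)
  rpm1 <- matrix(5, 4, 3)
  tr <- paired_track(rpm1, rpm1, win)
  agg <- aggregate_by_element(tr, ann, "enhancer")
  expect_equal(agg$p_value, 1)
})

test_that("metaprofile bins at the documented width and flips minus strands", {
  ann <- bare_annotation(c(chrA = 60000))
  win <- tile_genome(ann, 500L)
  prof_samples <- paired_sheet(2)
  # constant signal -> flat profile, zero SD
  tmc <- manual_track(matrix(2, length(win), 4,
                             dimnames = list(NULL, prof_samples$sample)),
                      win, prof_samples)
  anch <- GenomicRanges::GRanges("chrA", IRanges::IRanges(20001, 20001),
                                 strand = "+")
  mp <- metaprofile(tmc, anch)
  expect_equal(length(mp$bin_mid), 80L)
  expect_equal(diff(mp$bin_mid)[1], 50)   # 4 kb / 80 bins
  expect_true(all(mp$group_mean == 2))
  expect_true(all(mp$group_sd == 0))
  # planted dip at the anchor window, seen identically from both strands
  rpm <- matrix(10, length(win), 4, dimnames = list(NULL,
                                                    prof_samples$sample))
  dip_win <- which(bed_frame(win)$start == 20000)
  rpm[dip_win, ] <- 0
  tr <- manual_track(rpm, win, prof_samples)
  plus <- GenomicRanges::GRanges("chrA", IRanges::IRanges(20201, 20201),
                                 strand = "+")
  minus <- GenomicRanges::GRanges("chrA", IRanges::IRanges(20201, 20201),
                                  strand = "-")
  mp_p <- metaprofile(tr, plus)
  mp_m <- metaprofile(tr, minus)
  expect_lt(which.min(rowMeans(mp_p$group_mean)), 45)
  expect_gt(min(rowMeans(mp_p$group_mean)), -1)
  # strand flip mirrors the profile
  expect_equal(mp_m$per_sample[, 1], rev(mp_p$per_sample[, 1]))
  expect_error(metaprofile(tr, GenomicRanges::GRanges()), "anchors")
  expect_error(metaprofile(tr, plus, flank = 2000L, n_bins = 77L),
               "divisible")
})
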