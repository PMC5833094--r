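# Configuration-driven end-to-end driver: simulation (or real inputs) ->
# window quantification -> DMR/DhMR calling -> DEG analysis -> global
# patterns -> integration, with standard-format outputs and a
# deterministic run log.

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate data from `sim`) or `"real"` (read
#'   `fragment_sheet`, `annotation_dir`, `counts_file`)
#' @param sim a [sim_config()] (simulate mode)
#' @param fragment_sheet data.frame with `sample`, `patient`, `group`,
#'   `assay`, `file` (real mode)
#' @param annotation_dir directory readable by [read_annotation()]
#'   (real mode)
#' @param counts_file gene-level count TSV (real mode); gene lengths taken
#'   from the annotation's exon structure
#' @param window_size analysis window (bp)
#' @param step sliding step for differential calling (default
#'   `window_size / 2`)
#' @param min_cpg minimum CpG sites per tested window
#' @param alpha per-window significance threshold for region calling
#' @param q_max,min_abs_log2,min_pairs consensus DEG thresholds
#' @param out_dir output directory
#' @param seed integer seed governing every random draw of the run
#' @return a validated `run_config`
#' @export
run_config <- function(mode = c("simulate", "real"),
                       sim = sim_config(),
                       fragment_sheet = NULL,
                       annotation_dir = NULL,
                       counts_file = NULL,
                       window_size = 500L,
                       step = window_size %/% 2L,
                       min_cpg = 5L,
                       alpha = 0.05,
                       q_max = 0.05,
                       min_abs_log2 = 0.585,
                       min_pairs = 4L,
                       out_dir = tempfile("episcreen_run_"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "real") {
    if (is.null(fragment_sheet) || is.null(annotation_dir) ||
        is.null(counts_file))
      stop("real mode needs fragment_sheet, annotation_dir and counts_file")
  }
  stopifnot(window_size > 0, step > 0, alpha > 0, alpha < 1,
            q_max > 0, q_max <= 1, min_abs_log2 >= 0, min_pairs >= 1)
  cfg <- list(mode = mode, sim = sim, fragment_sheet = fragment_sheet,
              annotation_dir = annotation_dir, counts_file = counts_file,
              window_size = as.integer(window_size), step = as.integer(step),
              min_cpg = as.integer(min_cpg), alpha = alpha, q_max = q_max,
              min_abs_log2 = min_abs_log2, min_pairs = as.integer(min_pairs),
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes every stage and writes, under `out_dir`: the effective
#' configuration (`config.yaml`), windows BED, per-assay RPM matrices,
#' DMR/DhMR tables and BED6 tracks, the DEG table, candidate table,
#' global-pattern summaries, and (simulate mode) the truth tables and a
#' truth-recovery report.  A run log (`run_log.txt`) records the seed and
#' every filter count; outputs are byte-deterministic for a fixed
#' configuration and seed.
#'
#' @param config a [run_config()]
#' @return invisibly, a `run_report` list with the in-memory results
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("episcreen run (mode=%s seed=%d)",
                         config$mode, config$seed))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## ---- inputs ----
  if (config$mode == "simulate") {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim_cfg$window_size <- config$window_size
    sim <- simulate_all(sim_cfg, fragments = TRUE)
    annotation <- sim$annotation
    fragments <- sim$tracks$fragments
    frag_samples <- sim$tracks$samples
    expr_counts <- sim$expression$counts
    expr_samples <- sim$expression$samples
    truth <- sim$tracks$truth
    write_annotation(annotation, file.path(out, "annotation"))
    write_truth(truth, file.path(out, "truth"))
    note("simulated %d fragment tracks over %d x %s bp",
         length(fragments), length(annotation$chromosomes),
         format(annotation$chromosomes[[1]], scientific = FALSE))
    note("planted regions: %d; planted DEGs: %d; coupled genes: %d",
         nrow(truth$planted_regions), nrow(truth$planted_degs),
         nrow(truth$couplings))
  } else {
    annotation <- read_annotation(config$annotation_dir)
    fragments <- read_fragments_bed(config$fragment_sheet)
    frag_samples <- config$fragment_sheet[, c("sample", "patient", "group",
                                              "assay")]
    expr_counts <- read_counts_tsv(config$counts_file)
    expr_samples <- .counts_sample_sheet(colnames(expr_counts))
    truth <- NULL
    note("read %d fragment tracks and %d-gene count matrix",
         length(fragments), nrow(expr_counts))
  }

  ## ---- quantification (partition tiling + sliding grid) ----
  windows <- tile_genome(annotation, config$window_size)
  sliding <- tile_genome(annotation, config$window_size, config$step)
  data.table::fwrite(cbind(bed_frame(windows),
                           n_cpg = S4Vectors::mcols(windows)$n_cpg),
                     file.path(out, "windows.bed"), sep = "\t",
                     col.names = FALSE)
  note("tiled %d windows (+%d sliding windows, step %d)",
       length(windows), length(sliding), config$step)

  tracks <- list(); stracks <- list()
  for (assay in c("5mC", "5hmC")) {
    idx <- which(frag_samples$assay == assay)
    fr <- fragments[idx]
    names(fr) <- frag_samples$sample[idx]
    tracks[[assay]] <- count_and_normalize(fr, windows,
                                           frag_samples[idx, , drop = FALSE])
    stracks[[assay]] <- count_and_normalize(fr, sliding,
                                            frag_samples[idx, , drop = FALSE])
    rpm_df <- cbind(bed_frame(windows),
                    as.data.frame(round(tracks[[assay]]$rpm, 4)))
    data.table::fwrite(rpm_df,
                       file.path(out, sprintf("rpm_%s.tsv", assay)),
                       sep = "\t")
    note("%s: %d fragments counted, %d skipped", assay,
         sum(tracks[[assay]]$library_sizes),
         sum(tracks[[assay]]$skipped))
  }

  ## ---- differential regions ----
  regions <- list(); win_tests <- list()
  for (assay in c("5mC", "5hmC")) {
    wt <- test_windows(stracks[[assay]], min_cpg = config$min_cpg)
    win_tests[[assay]] <- wt
    reg <- merge_to_regions(wt, alpha = config$alpha)
    regions[[assay]] <- reg
    tag <- if (assay == "5mC") "dmr" else "dhmr"
    data.table::fwrite(as.data.frame(reg),
                       file.path(out, paste0(tag, ".tsv")), sep = "\t")
    write_regions_bed6(reg, file.path(out, paste0(tag, ".bed")))
    note("%s: %d eligible windows, %d significant, %d %ss (%d hyper/%d hypo)",
         assay, sum(wt$table$eligible),
         sum(wt$table$eligible & wt$table$p < config$alpha, na.rm = TRUE),
         nrow(reg), toupper(tag), sum(reg$direction == "hyper"),
         sum(reg$direction == "hypo"))
  }
  oe <- lapply(regions, element_oe, annotation = annotation)
  data.table::fwrite(cbind(assay = rep(names(oe), each = nrow(oe[[1]])),
                           do.call(rbind, oe)),
                     file.path(out, "element_oe.tsv"), sep = "\t")

  ## ---- expression ----
  glen <- .annotation_gene_lengths(annotation)
  shared <- intersect(rownames(expr_counts), names(glen))
  note("expression: %d/%d genes matched to annotation",
       length(shared), nrow(expr_counts))
  expr_tbl <- pairwise_expression_tests(expr_counts[shared, , drop = FALSE],
                                        expr_samples, glen[shared])
  degs <- call_degs(expr_tbl, q_max = config$q_max,
                    min_abs_log2 = config$min_abs_log2,
                    min_pairs = config$min_pairs)
  deg_out <- cbind(degs,
                   mean_rpkm = round(rowMeans(expr_tbl$rpkm), 4))
  data.table::fwrite(deg_out, file.path(out, "deg_table.tsv"), sep = "\t")
  note("DEGs called: %d (%d up / %d down) of %d genes",
       sum(degs$deg), sum(degs$deg & degs$direction == "up", na.rm = TRUE),
       sum(degs$deg & degs$direction == "down", na.rm = TRUE), nrow(degs))

  ## ---- global patterns ----
  pats <- list()
  for (assay in c("5mC", "5hmC"))
    pats[[paste0("pca_", assay)]] <- pca_separation(tracks[[assay]])
  slopes <- mc_hmc_regression(tracks[["5mC"]], tracks[["5hmC"]])
  global_df <- data.frame(
    metric = c("silhouette_5mC", "silhouette_5hmC",
               "slope_normal", "slope_tumor", "r_normal", "r_tumor"),
    value = round(c(pats$pca_5mC$silhouette, pats$pca_5hmC$silhouette,
                    slopes$normal$slope, slopes$tumor$slope,
                    slopes$normal$r, slopes$tumor$r), 6))
  data.table::fwrite(global_df, file.path(out, "global_patterns.tsv"),
                     sep = "\t")
  note("silhouette 5mC=%.3f 5hmC=%.3f; slope normal=%.3f tumor=%.3f",
       pats$pca_5mC$silhouette, pats$pca_5hmC$silhouette,
       slopes$normal$slope, slopes$tumor$slope)
  if (length(annotation$chromosomes) >= 3L) {
    feats <- chromosome_features(annotation)
    depths <- .per_chrom_depth(tracks)
    fc <- feature_correlations(feats,
                               depths$mat[feats$chrom, , drop = FALSE],
                               depths$samples)
    data.table::fwrite(fc, file.path(out, "feature_correlations.tsv"),
                       sep = "\t")
  } else {
    note("feature correlations skipped: fewer than 3 chromosomes")
  }

  ## ---- integration ----
  hits_mc <- map_promoter_regions(regions[["5mC"]], annotation)
  hits_hmc <- map_promoter_regions(regions[["5hmC"]], annotation)
  screen <- screen_candidates(hits_mc, hits_hmc, degs)
  data.table::fwrite(screen$candidates, file.path(out, "candidates.tsv"),
                     sep = "\t")
  note("promoter hits: %d genes (5mC), %d genes (5hmC); candidates: %d",
       nrow(hits_mc), nrow(hits_hmc), nrow(screen$candidates))

  ## ---- recovery report (simulate mode) ----
  recovery <- NULL
  if (!is.null(truth)) {
    rec_mc <- region_recovery(regions[["5mC"]], truth, "5mC")
    rec_hmc <- region_recovery(regions[["5hmC"]], truth, "5hmC")
    rec_deg <- deg_recovery(degs, truth)
    planted_set <- sort(truth$couplings$gene_id)
    called_set <- sort(screen$candidates$gene_id)
    recovery <- data.frame(
      metric = c("dmr_sensitivity", "dhmr_sensitivity",
                 "dmr_false_region_fraction", "dhmr_false_region_fraction",
                 "deg_recall", "deg_false_calls",
                 "screen_exact", "screen_missed", "screen_extra"),
      value = c(rec_mc$sensitivity, rec_hmc$sensitivity,
                rec_mc$false_region_fraction, rec_hmc$false_region_fraction,
                rec_deg$recall, rec_deg$false_calls,
                as.numeric(identical(planted_set, called_set)),
                length(setdiff(planted_set, called_set)),
                length(setdiff(called_set, planted_set))))
    data.table::fwrite(recovery, file.path(out, "recovery_report.tsv"),
                       sep = "\t")
    note("recovery: DMR sens=%.3f DhMR sens=%.3f DEG recall=%.3f screen_exact=%d",
         rec_mc$sensitivity, rec_hmc$sensitivity, rec_deg$recall,
         as.integer(identical(planted_set, called_set)))
  }

  ## ---- config + log ----
  yaml::write_yaml(.config_as_list(config), file.path(out, "config.yaml"))
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(structure(list(
    out_dir = out, annotation = annotation, windows = windows,
    tracks = tracks, window_tests = win_tests, regions = regions,
    element_oe = oe, expression = expr_tbl, degs = degs,
    patterns = pats, slopes = slopes, screen = screen,
    recovery = recovery, truth = truth, log = log_lines),
    class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(x$log, collapse = "\n"), "\n")
  invisible(x)
}

.annotation_gene_lengths <- function(annotation) {
  g <- annotation$genes
  if (nrow(g) == 0L) return(setNames(integer(0), character(0)))
  ex <- .exon_gr(g)
  glen <- tapply(GenomicRanges::width(ex),
                 rep(g$gene_id, lengths(strsplit(g$exons, ","))), sum)
  setNames(as.integer(glen[g$gene_id]), g$gene_id)
}

.counts_sample_sheet <- function(sample_names) {
  parts <- strsplit(sample_names, "_", fixed = TRUE)
  data.frame(sample = sample_names,
             patient = vapply(parts, `[`, "", 1L),
             group = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

.per_chrom_depth <- function(tracks) {
  t1 <- tracks[["5mC"]]
  chrom <- as.character(GenomicRanges::seqnames(t1$windows))
  mat <- NULL; samples <- NULL
  for (assay in names(tracks)) {
    tr <- tracks[[assay]]
    m <- apply(tr$rpm, 2, function(v) tapply(v, chrom, mean))
    mat <- cbind(mat, m)
    samples <- rbind(samples, tr$samples)
  }
  chroms <- sort(unique(chrom))
  list(mat = mat[chroms, , drop = FALSE], samples = samples)
}

# YAML dump of the effective configuration; paths that depend on where the
# run happens to live (out_dir, input files) are omitted so that runs of
# the same configuration are byte-identical wherever they are written
.config_as_list <- function(config) {
  out <- unclass(config)
  out$sim <- if (config$mode == "simulate") unclass(config$sim) else NULL
  out$fragment_sheet <- NULL
  out$out_dir <- NULL
  out$annotation_dir <- NULL
  out$counts_file <- NULL
  out
}
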