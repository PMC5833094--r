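# Groupwise sliding-window DMR/DhMR calling: per-window paired tests on
# log2(RPM + 1), merging of significant same-direction windows into
# regions, and element-distribution (observed/expected) statistics.

#' Per-window paired differential test
#'
#' For one assay, tests every CpG-eligible window (>= `min_cpg` CpG sites)
#' for a tumor-vs-normal difference with a two-sided paired t-test on
#' log2(RPM + 1) across patients.  Direction is the sign of the mean paired
#' difference ("hyper" = gain in tumor).  Windows with fewer CpGs are
#' marked ineligible and carry no p-value.  Degenerate windows (all paired
#' differences exactly zero) get p = 1 and no direction.  BH-adjusted
#' q-values across eligible windows are reported alongside the raw
#' p-values used for region calling.
#'
#' @param track a `track_matrix` of a single assay with a fully paired
#'   sample sheet (>= 2 pairs)
#' @param min_cpg minimum CpG sites per window (default 5)
#' @param pseudocount added to RPM before log2 (default 1)
#' @return a `window_tests` object: list with `windows` (`GRanges`) and
#'   `table` (data.frame: `eligible`, `p`, `q`, `direction`,
#'   `mean_tumor_rpm`, `mean_normal_rpm`, `n_cpg`)
#' @export
test_windows <- function(track, min_cpg = 5L, pseudocount = 1) {
  if (!is.null(track$samples) && length(unique(track$samples$assay)) > 1L)
    stop("test_windows expects a single-assay track")
  pc <- .paired_columns(track$samples)
  if (length(pc$patients) < 2L) stop("need at least 2 tumor/normal pairs")
  lt <- log2(track$rpm[, pc$tumor, drop = FALSE] + pseudocount)
  ln <- log2(track$rpm[, pc$normal, drop = FALSE] + pseudocount)
  res <- .row_paired_t(lt - ln)
  n_cpg <- S4Vectors::mcols(track$windows)$n_cpg
  eligible <- n_cpg >= min_cpg
  p <- ifelse(eligible, res$p, NA_real_)
  direction <- ifelse(eligible, res$direction, NA_character_)
  q <- rep(NA_real_, length(p))
  q[eligible] <- stats::p.adjust(p[eligible], method = "BH")
  tab <- data.frame(
    eligible = eligible, p = p, q = q, direction = direction,
    mean_tumor_rpm = rowMeans(track$rpm[, pc$tumor, drop = FALSE]),
    mean_normal_rpm = rowMeans(track$rpm[, pc$normal, drop = FALSE]),
    n_cpg = n_cpg, stringsAsFactors = FALSE)
  structure(list(windows = track$windows, table = tab,
                 assay = if (!is.null(track$samples))
                   unique(track$samples$assay) else NA_character_),
            class = "window_tests")
}

#' @export
print.window_tests <- function(x, ...) {
  cat("window_tests:", nrow(x$table), "windows,",
      sum(x$table$eligible), "eligible (assay ", x$assay, ")\n")
  invisible(x)
}

#' Merge significant windows into differential regions
#'
#' Overlapping or book-ended significant windows (p < `alpha`) with the
#' same direction merge into one region; runs of opposite direction never
#' merge.  Region p is the minimum supporting-window p; CpG support is the
#' sum over supporting windows.
#'
#' @param tests a `window_tests` from [test_windows()]
#' @param alpha per-window significance threshold (default 0.05, unadjusted,
#'   the region-calling convention of the emulated study)
#' @return a `diff_regions` data.frame: `assay`, `chrom`, `start`, `end`
#'   (0-based half-open), `direction`, `p`, `mean_tumor_rpm`,
#'   `mean_normal_rpm`, `n_windows`, `n_cpg`
#' @export
merge_to_regions <- function(tests, alpha = 0.05) {
  tab <- tests$table
  empty <- data.frame(assay = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      direction = character(0), p = numeric(0),
                      mean_tumor_rpm = numeric(0),
                      mean_normal_rpm = numeric(0),
                      n_windows = integer(0), n_cpg = integer(0),
                      stringsAsFactors = FALSE)
  out <- list()
  for (dir in c("hyper", "hypo")) {
    sig <- which(tab$eligible & !is.na(tab$p) & tab$p < alpha &
                 !is.na(tab$direction) & tab$direction == dir)
    if (length(sig) == 0L) next
    win <- tests$windows[sig]
    reg <- GenomicRanges::reduce(win, min.gapwidth = 1L)
    hits <- GenomicRanges::findOverlaps(win, reg)
    ri <- S4Vectors::subjectHits(hits)
    agg <- function(v, f) as.numeric(tapply(v, ri, f))
    out[[dir]] <- data.frame(
      assay = tests$assay,
      chrom = as.character(GenomicRanges::seqnames(reg)),
      start = GenomicRanges::start(reg) - 1L,
      end = GenomicRanges::end(reg),
      direction = dir,
      p = agg(tab$p[sig], min),
      mean_tumor_rpm = agg(tab$mean_tumor_rpm[sig], mean),
      mean_normal_rpm = agg(tab$mean_normal_rpm[sig], mean),
      n_windows = as.integer(agg(seq_along(sig), length)),
      n_cpg = as.integer(agg(tab$n_cpg[sig], sum)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(structure(empty, class = c("diff_regions",
                                                           "data.frame")))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end, res$direction), ]
  rownames(res) <- NULL
  structure(res, class = c("diff_regions", "data.frame"))
}

#' Differential regions as GRanges
#' @param regions a `diff_regions` data.frame
#' @return `GRanges` with the remaining columns as metadata
#' @export
regions_gr <- function(regions) {
  if (nrow(regions) == 0L) return(GenomicRanges::GRanges())
  gr <- gr0(regions$chrom, regions$start, regions$end)
  S4Vectors::mcols(gr) <- regions[, setdiff(names(regions),
                                            c("chrom", "start", "end"))]
  gr
}

#' Observed/expected element distribution of differential regions
#'
#' For each element class: observed = number of regions overlapping the
#' class; expected = total regions x fraction of the genome covered by the
#' class; ratio = observed / expected.  A class covering zero bp (expected
#' 0) is flagged undefined.
#'
#' @param regions a `diff_regions` data.frame (or any with
#'   `chrom`/`start`/`end`)
#' @param annotation a `genome_annotation`
#' @param elements element class names (default: the profile used for the
#'   region-distribution figure of the emulated study)
#' @return data.frame: `element`, `observed`, `expected`, `oe`,
#'   `genome_fraction`, `undefined`
#' @export
element_oe <- function(regions, annotation,
                       elements = c("promoter", "exon", "intron", "TES",
                                    "CGI", "CGI_shore", "SINE", "LINE",
                                    "LTR", "enhancer")) {
  genome_bp <- sum(annotation$chromosomes)
  n <- nrow(regions)
  rg <- if (n > 0L) gr0(regions$chrom, regions$start, regions$end) else
    GenomicRanges::GRanges()
  rows <- lapply(elements, function(el) {
    egr <- GenomicRanges::reduce(element_ranges(annotation, el))
    frac <- sum(GenomicRanges::width(egr)) / genome_bp
    expected <- n * frac
    observed <- if (n > 0L) sum(IRanges::overlapsAny(rg, egr)) else 0L
    data.frame(element = el, observed = observed, expected = expected,
               oe = if (expected > 0) observed / expected else NA_real_,
               genome_fraction = frac,
               undefined = expected == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recovery of planted regions by called regions
#'
#' Fraction of planted regions of one assay overlapped by a called region
#' of the same direction, plus the fraction of called regions not touching
#' any planted region (empirical false-discovery proxy).
#'
#' @param regions called `diff_regions` for one assay
#' @param truth a `truth_table`
#' @param assay `"5mC"` or `"5hmC"`
#' @return list with `sensitivity`, `n_planted`, `n_called`,
#'   `false_region_fraction`
#' @export
region_recovery <- function(regions, truth, assay) {
  planted <- truth$planted_regions[truth$planted_regions$assay == assay, ]
  if (nrow(planted) == 0L)
    return(list(sensitivity = NA_real_, n_planted = 0L,
                n_called = nrow(regions),
                false_region_fraction = if (nrow(regions)) 1 else NA_real_))
  pg <- gr0(planted$chrom, planted$start, planted$end)
  hit <- logical(nrow(planted))
  false_call <- rep(TRUE, nrow(regions))
  if (nrow(regions) > 0L) {
    for (dir in c("hyper", "hypo")) {
      ri <- which(regions$direction == dir)
      pi <- which(planted$direction == dir)
      if (length(ri) == 0L || length(pi) == 0L) next
      rg <- gr0(regions$chrom[ri], regions$start[ri], regions$end[ri])
      ov <- GenomicRanges::findOverlaps(pg[pi], rg)
      hit[pi[unique(S4Vectors::queryHits(ov))]] <- TRUE
      false_call[ri[unique(S4Vectors::subjectHits(ov))]] <- FALSE
    }
  }
  list(sensitivity = mean(hit), n_planted = nrow(planted),
       n_called = nrow(regions),
       false_region_fraction = if (nrow(regions)) mean(false_call)
                               else NA_real_)
}
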