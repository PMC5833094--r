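# Window-based quantification: genome tiling, fragment counting (midpoint
# rule), RPM normalization, CpG coverage curves, element aggregation and
# anchored metaprofiles.

#' Tile the genome into fixed windows
#'
#' Tiles every chromosome with windows of `window_size` bp.  With
#' `step = window_size` (the default) the windows partition the genome;
#' the trailing window is retained even when shorter than `window_size`.
#' With `step < window_size` an overlapping sliding grid is produced (used
#' by the differential-region caller).  Each window is annotated with its
#' CpG count, GC fraction and CpG observed/expected ratio; GC is the
#' package's deterministic proxy from CpG density (no base sequence exists
#' for the synthetic genome).
#'
#' @param annotation a `genome_annotation` (or any list with `chromosomes`
#'   and `cpg_sites` fields)
#' @param window_size window width in bp
#' @param step distance between window starts (default `window_size`)
#' @return a `GRanges` sorted by position with metadata columns `n_cpg`,
#'   `gc`, `cpg_oe`
#' @export
tile_genome <- function(annotation, window_size = 500L, step = window_size) {
  stopifnot(window_size > 0, step > 0)
  chroms <- annotation$chromosomes
  if (is.null(chroms) || length(chroms) == 0L)
    stop("annotation has no chromosomes")
  pieces <- lapply(names(chroms), function(cn) {
    L <- chroms[[cn]]
    s0 <- seq(0, L - 1, by = step)
    data.frame(chrom = cn, s0 = s0, e0 = pmin(s0 + window_size, L))
  })
  tab <- do.call(rbind, pieces)
  win <- .with_seqinfo(gr0(tab$chrom, tab$s0, tab$e0), chroms)
  cpg <- .cpg_gr(annotation)
  n_cpg <- GenomicRanges::countOverlaps(win, cpg)
  dens <- n_cpg / GenomicRanges::width(win)
  gc <- .gc_proxy(dens)
  S4Vectors::mcols(win)$n_cpg <- n_cpg
  S4Vectors::mcols(win)$gc <- gc
  S4Vectors::mcols(win)$cpg_oe <- dens / ((gc / 2)^2)
  win
}

.cpg_gr <- function(annotation) {
  sites <- annotation$cpg_sites
  if (is.null(sites) || sum(lengths(sites)) == 0L)
    return(GenomicRanges::GRanges())
  .pos_gr(rep(names(sites), lengths(sites)), unlist(sites, use.names = FALSE))
}

# 1-based position of the 0-based fragment midpoint; a midpoint exactly on
# a window boundary belongs to the right window (half-open convention)
.fragment_midpoints <- function(gr) {
  mid0 <- (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
  .pos_gr(as.character(GenomicRanges::seqnames(gr)), mid0)
}

#' Count fragments per window and normalize to RPM
#'
#' Each fragment is assigned by its midpoint: on a non-overlapping tiling
#' this is a partition (per-sample counts sum to the library size).
#' RPM = count x 10^6 / library size, with library size the total number of
#' fragments on known chromosomes.  Fragments on unknown chromosomes are
#' skipped with a warning and reported in the returned `skipped` field.
#'
#' @param fragments named list of `GRanges`, one per sample
#' @param windows a window `GRanges` from [tile_genome()]
#' @param samples data.frame describing the samples (columns `sample`,
#'   `patient`, `group`, `assay`); rows must match `names(fragments)`.
#'   May be `NULL` for anonymous tracks.
#' @return a `track_matrix`: list with `counts` and `rpm`
#'   (windows x samples matrices), `samples`, `library_sizes`, `windows`,
#'   `skipped`
#' @export
count_and_normalize <- function(fragments, windows, samples = NULL) {
  stopifnot(is.list(fragments), length(fragments) > 0L)
  known <- unique(as.character(GenomicRanges::seqnames(windows)))
  n_win <- length(windows)
  counts <- matrix(0L, n_win, length(fragments),
                   dimnames = list(NULL, names(fragments)))
  skipped <- setNames(integer(length(fragments)), names(fragments))
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    on_known <- as.character(GenomicRanges::seqnames(fr)) %in% known
    if (any(!on_known)) {
      skipped[i] <- sum(!on_known)
      warning(sum(!on_known), " fragment(s) on unknown chromosomes ",
              "skipped for sample ", names(fragments)[i])
      fr <- fr[on_known]
    }
    mids <- .fragment_midpoints(fr)
    hits <- GenomicRanges::findOverlaps(mids, windows)
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = n_win)
    counts[, i] <- tab
  }
  lib <- sapply(fragments, length) - skipped
  rpm <- sweep(counts, 2L, pmax(lib, 1L), "/") * 1e6
  track_matrix(counts, rpm, samples, lib, windows, skipped)
}

#' Construct a track matrix
#'
#' Container for windows x samples modification levels.  Usually produced
#' by [count_and_normalize()] or [sim_track_matrix()].
#'
#' @param counts,rpm windows x samples matrices
#' @param samples sample sheet data.frame or `NULL`
#' @param library_sizes per-sample totals used for RPM
#' @param windows the window `GRanges`
#' @param skipped per-sample count of skipped fragments
#' @return an object of class `track_matrix`
#' @export
track_matrix <- function(counts, rpm, samples, library_sizes, windows,
                         skipped = NULL) {
  stopifnot(nrow(rpm) == length(windows), all(rpm >= 0))
  if (!is.null(samples)) {
    stopifnot(nrow(samples) == ncol(rpm))
  }
  structure(list(counts = counts, rpm = rpm, samples = samples,
                 library_sizes = library_sizes, windows = windows,
                 skipped = skipped),
            class = "track_matrix")
}

#' @export
print.track_matrix <- function(x, ...) {
  cat("track_matrix:", nrow(x$rpm), "windows x", ncol(x$rpm), "samples\n")
  if (!is.null(x$samples))
    cat("  assays:", paste(unique(x$samples$assay), collapse = ", "),
        " groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

# subset a track matrix by sample index
.track_subset <- function(track, idx) {
  track_matrix(track$counts[, idx, drop = FALSE],
               track$rpm[, idx, drop = FALSE],
               if (!is.null(track$samples)) track$samples[idx, , drop = FALSE],
               track$library_sizes[idx], track$windows)
}

# check paired structure: each patient exactly one tumor and one normal
# sample; returns patient-ordered tumor/normal column indices
.paired_columns <- function(samples) {
  stopifnot(!is.null(samples))
  pats <- sort(unique(samples$patient))
  ti <- ni <- integer(length(pats))
  for (k in seq_along(pats)) {
    t_idx <- which(samples$patient == pats[k] & samples$group == "tumor")
    n_idx <- which(samples$patient == pats[k] & samples$group == "normal")
    if (length(t_idx) != 1L || length(n_idx) != 1L)
      stop("samples are not paired: patient ", pats[k])
    ti[k] <- t_idx; ni[k] <- n_idx
  }
  list(patients = pats, tumor = ti, normal = ni)
}

#' CpG coverage-depth summary
#'
#' Fraction of CpG sites covered by at least d fragments, for d = 1..max_depth
#' (full fragment overlap, not midpoint assignment).
#'
#' @param fragments a `GRanges` of fragments (one sample)
#' @param cpg_sites per-chromosome list of 0-based CpG positions
#' @param max_depth largest depth evaluated (default 10)
#' @return data.frame with columns `depth`, `fraction`
#' @export
coverage_summary <- function(fragments, cpg_sites, max_depth = 10L) {
  if (sum(lengths(cpg_sites)) == 0L) stop("no CpG sites")
  sites <- .pos_gr(rep(names(cpg_sites), lengths(cpg_sites)),
                   unlist(cpg_sites, use.names = FALSE))
  depth <- GenomicRanges::countOverlaps(sites, fragments)
  data.frame(depth = seq_len(max_depth),
             fraction = sapply(seq_len(max_depth),
                               function(d) mean(depth >= d)))
}

#' Mean modification level over an element class
#'
#' Per-sample mean RPM over the windows overlapping the element class, plus
#' a paired tumor-vs-normal test across patients when the sample sheet
#' carries a paired design.  An element class with no overlapping window is
#' flagged undefined (`NA` means), never zero.
#'
#' @param track a `track_matrix`
#' @param annotation a `genome_annotation`
#' @param element element class name understood by [element_ranges()]
#' @return list with `element`, `n_windows`, `means` (per sample),
#'   `p_value` (paired tumor/normal, `NA` when not applicable)
#' @export
aggregate_by_element <- function(track, annotation, element) {
  gr <- element_ranges(annotation, element)
  idx <- which(IRanges::overlapsAny(track$windows, gr))
  if (length(idx) == 0L) {
    return(list(element = element, n_windows = 0L,
                means = setNames(rep(NA_real_, ncol(track$rpm)),
                                 colnames(track$rpm)),
                p_value = NA_real_, undefined = TRUE))
  }
  means <- colMeans(track$rpm[idx, , drop = FALSE])
  p <- NA_real_
  if (!is.null(track$samples) &&
      all(c("tumor", "normal") %in% track$samples$group)) {
    pc <- .paired_columns(track$samples)
    p <- .paired_t_p(means[pc$tumor], means[pc$normal])
  }
  list(element = element, n_windows = length(idx), means = means,
       p_value = p, undefined = FALSE)
}

#' Anchored metaprofile around TSS or TES
#'
#' Averages window RPM in fixed-width bins across a +/- `flank` region
#' around a set of anchors; minus-strand anchors are orientation-flipped so
#' bin 1 is always 5'.  Anchors whose full span leaves the chromosome are
#' dropped.  Returns per-group mean and across-sample SD per bin.
#'
#' @param track a `track_matrix` with a grouped sample sheet
#' @param anchors `GRanges` of width-1 anchor positions with strand
#' @param flank bp on each side (default 2000)
#' @param n_bins number of bins over the 2 x flank region (default 80;
#'   `2 * flank` must be divisible by `n_bins`)
#' @return list with `bin_mid` (position of bin centers relative to the
#'   anchor), `per_sample` (bins x samples matrix), `group_mean`,
#'   `group_sd` (bins x groups matrices)
#' @export
metaprofile <- function(track, anchors, flank = 2000L, n_bins = 80L) {
  if (length(anchors) == 0L) stop("no anchors")
  if ((2L * flank) %% n_bins != 0L)
    stop("2 * flank must be divisible by n_bins")
  bw <- (2L * flank) %/% n_bins
  chroms <- tapply(GenomicRanges::end(track$windows),
                   as.character(GenomicRanges::seqnames(track$windows)), max)
  apos0 <- GenomicRanges::start(anchors) - 1L
  achr <- as.character(GenomicRanges::seqnames(anchors))
  ok <- apos0 - flank >= 0 & apos0 + flank <= chroms[achr]
  anchors <- anchors[ok]; apos0 <- apos0[ok]; achr <- achr[ok]
  if (length(anchors) == 0L) stop("no anchors fit within chromosome bounds")
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  # bin-center offsets 5' -> 3'
  off <- -flank + (seq_len(n_bins) - 0.5) * bw
  pos0 <- outer(apos0, off, function(a, o) a + o)     # anchors x bins
  # minus-strand anchors walk 5' -> 3' in decreasing genomic coordinate
  pos0[minus, ] <- outer(apos0[minus], off, function(a, o) a - o)
  # map every (anchor, bin) midpoint to its window
  qry <- .pos_gr(rep(achr, n_bins), as.integer(floor(as.vector(pos0))))
  hits <- GenomicRanges::findOverlaps(qry, track$windows)
  widx <- rep(NA_integer_, length(qry))
  widx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  per_sample <- matrix(NA_real_, n_bins, ncol(track$rpm),
                       dimnames = list(NULL, colnames(track$rpm)))
  bin_of <- rep(seq_len(n_bins), each = length(anchors))
  keep <- !is.na(widx)
  for (s in seq_len(ncol(track$rpm))) {
    v <- track$rpm[widx[keep], s]
    per_sample[, s] <- as.numeric(tapply(v, bin_of[keep], mean))
  }
  groups <- unique(track$samples$group)
  gm <- sapply(groups, function(g)
    rowMeans(per_sample[, track$samples$group == g, drop = FALSE]))
  gs <- sapply(groups, function(g)
    apply(per_sample[, track$samples$group == g, drop = FALSE], 1, stats::sd))
  list(bin_mid = off, per_sample = per_sample,
       group_mean = gm, group_sd = gs, n_anchors = length(anchors))
}
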