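#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- reduce findOverlaps countOverlaps pintersect resize granges
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom stats pt sd cor cor.test t.test wilcox.test fisher.test
#'   prcomp p.adjust rnbinom rpois rlnorm runif rnorm median quantile
#'   complete.cases dist setNames lm coef
#' @importFrom utils head tail
NULL

# All on-disk interval formats are BED (0-based half-open); in memory the
# package uses GRanges (1-based closed).  These two helpers are the only
# place the conversion happens.

#' Build a GRanges from 0-based half-open intervals
#'
#' @param chrom character vector of chromosome names
#' @param start0,end0 0-based half-open bounds (`start0 <= pos < end0`)
#' @param ... further arguments passed to [GenomicRanges::GRanges()]
#' @return a `GRanges`
#' @export
gr0 <- function(chrom, start0, end0, ...) {
  stopifnot(all(start0 >= 0), all(end0 > start0))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
}

#' 0-based half-open bounds of a GRanges
#'
#' @param gr a `GRanges`
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open)
#' @export
bed_frame <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# width-1 GRanges at 0-based positions
.pos_gr <- function(chrom, pos0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L))
}

# pin a GRanges to the full chromosome set (seqlevels + lengths), so that
# concatenation across chromosomes is silent and flank/trim respect bounds
.with_seqinfo <- function(gr, chroms) {
  GenomeInfoDb::seqlevels(gr) <- names(chroms)
  GenomeInfoDb::seqlengths(gr) <- unname(as.integer(chroms))
  gr
}

# fraction of each window covered by (reduced) gr
.overlap_fraction <- function(windows, gr) {
  out <- numeric(length(windows))
  if (length(gr) == 0L) return(out)
  gr <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(windows, gr)
  if (length(hits) == 0L) return(out)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    windows[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg) /
    GenomicRanges::width(windows)[as.integer(names(agg))]
  out
}

# Vectorized paired t-test rows of a difference matrix (windows x pairs).
# Degenerate rows (all differences zero) get p = 1 and NA direction,
# the convention used throughout for paired comparisons.
.row_paired_t <- function(D) {
  n <- ncol(D)
  m <- rowMeans(D)
  s2 <- rowSums((D - m)^2) / (n - 1)
  se <- sqrt(s2 / n)
  tstat <- ifelse(se > 0, m / se, ifelse(m == 0, 0, Inf * sign(m)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  degen <- rowSums(D != 0) == 0
  p[degen] <- 1
  direction <- ifelse(m > 0, "hyper", ifelse(m < 0, "hypo", NA_character_))
  direction[degen] <- NA_character_
  list(t = tstat, p = p, direction = direction, mean_diff = m)
}

# scalar paired t with the degenerate convention
.paired_t_p <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)
  stats::t.test(x, y, paired = TRUE)$p.value
}
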