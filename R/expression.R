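# RPKM quantification, the Audic-Claverie exact test for tag counts from
# two libraries, BH adjustment, and consensus DEG calling across patient
# pairs.

#' Reads per kilobase per million (RPKM)
#'
#' RPKM = count x 10^9 / (library_size x gene_length).
#'
#' @param count read count(s)
#' @param gene_length transcript length in bp (> 0); the longest transcript
#'   by convention
#' @param library_size total mapped reads of the sample (> 0)
#' @return numeric RPKM, vectorized over its arguments
#' @export
compute_rpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count * 1e9 / (library_size * gene_length)
}

# log point probability of observing count k in library 2 given count x in
# library 1 (library-size ratio r = N2/N1):
#   p(k | x) = r^k (x+k)! / ( x! k! (1+r)^(x+k+1) )
# computed via log-gamma for numerical stability at large counts
.ac_log_prob <- function(k, x, r) {
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

#' Audic-Claverie point probability
#'
#' @param x count in library 1
#' @param y count in library 2
#' @param ratio library-size ratio N2/N1
#' @return p(y | x)
#' @export
ac_point_prob <- function(x, y, ratio = 1) exp(.ac_log_prob(y, x, ratio))

#' Audic-Claverie two-sided p-value
#'
#' Exact comparison of a tag count between two libraries of known sizes.
#' The two-sided p doubles the smaller of the two tails (each tail includes
#' the observed point), capped at 1:
#' lower = sum over k <= y of p(k|x); upper = sum over k >= y of p(k|x).
#' Tail sums are accumulated in log-space via log-gamma terms so that large
#' counts stay finite.
#'
#' @param x,y non-negative counts in libraries 1 and 2 (vectorized)
#' @param n1,n2 library sizes (> 0)
#' @return two-sided p-value(s) in (0, 1]
#' @export
audic_claverie_p <- function(x, y, n1 = 1, n2 = 1) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  ratio <- rep_len(n2 / n1, length(x))
  vapply(seq_along(x), function(i) .ac_two_sided(x[i], y[i], ratio[i]),
         numeric(1))
}

.ac_two_sided <- function(x, y, r) {
  lp <- .ac_log_prob(0:y, x, r)
  m <- max(lp)
  lower <- exp(m) * sum(exp(lp - m))
  if (lower <= 0.5) return(min(1, 2 * lower))
  # y sits in the right tail: sum the upper tail forward from y; terms
  # decay geometrically beyond the mode so the loop terminates quickly
  upper <- 0
  k <- y
  repeat {
    term <- exp(.ac_log_prob(k, x, r))
    upper <- upper + term
    k <- k + 1
    if (term < upper * 1e-18 || term == 0 || k > y + 1e6) break
  }
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (validated wrapper around
#' the standard implementation).
#'
#' @param p p-values in \[0, 1\]
#' @return adjusted q-values
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-pair differential expression tests
#'
#' For every patient pair: Audic-Claverie two-sided p per gene (tumor count
#' vs normal count with the pair's library sizes), BH-adjusted q across
#' genes within the pair, and log2 RPKM ratio (pseudocount 0.1 on both
#' sides).
#'
#' @param counts genes x samples count matrix
#' @param samples sample sheet with `sample`, `patient`, `group`
#' @param gene_length named vector of transcript lengths (bp)
#' @return an `expression_table`: list with `genes`, `rpkm`, `counts`,
#'   `library_sizes`, and per-pair matrices `p`, `q`, `log2_ratio`
#'   (genes x pairs)
#' @export
pairwise_expression_tests <- function(counts, samples, gene_length) {
  stopifnot(nrow(samples) == ncol(counts))
  gene_length <- gene_length[rownames(counts)]
  if (any(is.na(gene_length))) stop("missing gene lengths")
  lib <- colSums(counts)
  rpkm <- compute_rpkm(counts, matrix(gene_length, nrow(counts),
                                      ncol(counts)),
                       matrix(lib, nrow(counts), ncol(counts), byrow = TRUE))
  dimnames(rpkm) <- dimnames(counts)
  pc <- .paired_columns(samples)
  n_pairs <- length(pc$patients)
  P <- Q <- L2 <- matrix(NA_real_, nrow(counts), n_pairs,
                         dimnames = list(rownames(counts), pc$patients))
  for (k in seq_len(n_pairs)) {
    tx <- counts[, pc$tumor[k]]
    nx <- counts[, pc$normal[k]]
    P[, k] <- audic_claverie_p(nx, tx, lib[pc$normal[k]], lib[pc$tumor[k]])
    Q[, k] <- bh_adjust(P[, k])
    L2[, k] <- log2((rpkm[, pc$tumor[k]] + 0.1) /
                    (rpkm[, pc$normal[k]] + 0.1))
  }
  structure(list(genes = data.frame(gene_id = rownames(counts),
                                    length = as.integer(gene_length),
                                    stringsAsFactors = FALSE),
                 rpkm = rpkm, counts = counts, library_sizes = lib,
                 samples = samples, p = P, q = Q, log2_ratio = L2),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$counts), "genes,", ncol(x$p),
      "patient pairs\n")
  invisible(x)
}

#' Consensus DEG calling across pairs
#'
#' A gene is a DEG iff in at least `min_pairs` pairs it satisfies
#' q <= `q_max` and |log2 ratio| >= `min_abs_log2` with the same sign; the
#' shared sign is the DEG direction.  0.585 = log2(1.5), so the q/ratio
#' rule and the "fold change > 1.5 in four or more samples" rule are the
#' same criterion.  If both directions independently reach `min_pairs`
#' (possible only when `min_pairs <= n_pairs / 2`) there is no consistent
#' direction and the gene is not called.
#'
#' @param tbl an `expression_table`
#' @param q_max FDR threshold per pair (default 0.05)
#' @param min_abs_log2 minimum |log2 ratio| (default 0.585)
#' @param min_pairs minimum concordant pairs (default 4)
#' @return data.frame: `gene_id`, `deg`, `direction`, `n_up`, `n_down`,
#'   `q_median`, `mean_log2_ratio`
#' @export
call_degs <- function(tbl, q_max = 0.05, min_abs_log2 = 0.585,
                      min_pairs = 4L) {
  pass <- tbl$q <= q_max & abs(tbl$log2_ratio) >= min_abs_log2
  n_up <- rowSums(pass & tbl$log2_ratio > 0)
  n_down <- rowSums(pass & tbl$log2_ratio < 0)
  up <- n_up >= min_pairs
  down <- n_down >= min_pairs
  deg <- xor(up, down)
  direction <- ifelse(deg & up, "up", ifelse(deg & down, "down",
                                             NA_character_))
  data.frame(gene_id = rownames(tbl$q),
             deg = deg, direction = direction,
             n_up = n_up, n_down = n_down,
             q_median = apply(tbl$q, 1, stats::median),
             mean_log2_ratio = rowMeans(tbl$log2_ratio),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Recall and false-call rate of planted DEGs
#'
#' @param degs output of [call_degs()]
#' @param truth a `truth_table`
#' @return list with `recall` (planted DEGs called with the planted
#'   direction), `n_planted`, `n_called`, `false_calls` (called DEGs that
#'   were not planted)
#' @export
deg_recovery <- function(degs, truth) {
  planted <- truth$planted_degs
  called <- degs[degs$deg, ]
  if (nrow(planted) == 0L)
    return(list(recall = NA_real_, n_planted = 0L, n_called = nrow(called),
                false_calls = nrow(called)))
  m <- merge(planted, called, by = "gene_id")
  hit <- sum(m$direction.x == m$direction.y)
  list(recall = hit / nrow(planted), n_planted = nrow(planted),
       n_called = nrow(called),
       false_calls = sum(!(called$gene_id %in% planted$gene_id)))
}
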