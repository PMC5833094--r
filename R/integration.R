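# Multi-omics integration: mapping differential regions to promoters,
# modification/expression correlation, the directional screen for
# epigenetically repressed (or activated) candidate genes, and a generic
# over-representation test for resulting gene lists.

#' Map differential regions to gene promoters
#'
#' A region hits a gene when it overlaps the promoter (TSS +/- `flank`,
#' strand-aware).  A gene with both hyper and hypo hits in one assay is
#' flagged ambiguous and excluded from the directional screen.
#'
#' @param regions a `diff_regions` data.frame (one assay)
#' @param annotation a `genome_annotation`
#' @param flank promoter half-width in bp (default 500)
#' @return data.frame: `gene_id`, `assay`, `direction` (`NA` when
#'   ambiguous), `n_regions`, `min_p`, `ambiguous`; one row per gene with
#'   at least one hit
#' @export
map_promoter_regions <- function(regions, annotation, flank = 500L) {
  empty <- data.frame(gene_id = character(0), assay = character(0),
                      direction = character(0), n_regions = integer(0),
                      min_p = numeric(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(empty)
  prom <- promoter_ranges(annotation, flank)
  if (length(prom) == 0L) return(empty)
  rg <- gr0(regions$chrom, regions$start, regions$end)
  hits <- GenomicRanges::findOverlaps(rg, prom)
  if (length(hits) == 0L) return(empty)
  df <- data.frame(gene_id = S4Vectors::mcols(prom)$gene_id[
                     S4Vectors::subjectHits(hits)],
                   direction = regions$direction[S4Vectors::queryHits(hits)],
                   p = regions$p[S4Vectors::queryHits(hits)],
                   stringsAsFactors = FALSE)
  sp <- split(df, df$gene_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    dirs <- unique(d$direction)
    data.frame(gene_id = d$gene_id[1],
               assay = regions$assay[1],
               direction = if (length(dirs) == 1L) dirs else NA_character_,
               n_regions = nrow(d), min_p = min(d$p),
               ambiguous = length(dirs) > 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

#' Correlate expression with promoter and gene-body modification
#'
#' Spearman correlation of group-mean log2(RPKM + 0.1) with group-mean
#' promoter RPM and gene-body RPM, per assay; plus a high-vs-low expression
#' class contrast (median split) tested with a two-sample Wilcoxon test on
#' promoter 5mC and gene-body 5hmC.
#'
#' @param track_5mC,track_5hmC `track_matrix` objects
#' @param expr an `expression_table`
#' @param annotation a `genome_annotation`
#' @param group sample group to evaluate (default `"tumor"`)
#' @return list with `correlations` (data.frame: `assay`, `region`, `rho`,
#'   `p`) and `class_contrast` (data.frame: `measure`, `p`,
#'   `mean_high`, `mean_low`, `undefined`)
#' @export
modification_expression_correlation <- function(track_5mC, track_5hmC,
                                                expr, annotation,
                                                group = "tumor") {
  genes <- annotation$genes
  shared <- intersect(genes$gene_id, rownames(expr$rpkm))
  if (length(shared) < 10L) stop("fewer than 10 shared genes")
  gsub <- genes[match(shared, genes$gene_id), ]
  e_idx <- expr$samples$group == group
  e <- log2(rowMeans(expr$rpkm[shared, e_idx, drop = FALSE]) + 0.1)

  gene_region_mean <- function(track, region_gr) {
    g_idx <- track$samples$group == group
    rpm <- rowMeans(track$rpm[, g_idx, drop = FALSE])
    hits <- GenomicRanges::findOverlaps(region_gr, track$windows)
    v <- rep(NA_real_, length(region_gr))
    agg <- tapply(rpm[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    v[as.integer(names(agg))] <- as.numeric(agg)
    v
  }
  prall <- promoter_ranges(annotation)
  prom <- prall[match(shared, S4Vectors::mcols(prall)$gene_id)]
  body <- gr0(gsub$chrom, gsub$start, gsub$end)
  mat <- list(
    c("5mC", "promoter"), c("5mC", "genebody"),
    c("5hmC", "promoter"), c("5hmC", "genebody"))
  vals <- list(
    `5mC_promoter` = gene_region_mean(track_5mC, prom),
    `5mC_genebody` = gene_region_mean(track_5mC, body),
    `5hmC_promoter` = gene_region_mean(track_5hmC, prom),
    `5hmC_genebody` = gene_region_mean(track_5hmC, body))
  correlations <- do.call(rbind, lapply(mat, function(m) {
    v <- vals[[paste(m[1], m[2], sep = "_")]]
    ok <- !is.na(v)
    if (sum(ok) < 3L || stats::sd(e[ok]) == 0 || stats::sd(v[ok]) == 0)
      return(data.frame(assay = m[1], region = m[2], rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    ct <- stats::cor.test(e[ok], v[ok], method = "spearman", exact = FALSE)
    data.frame(assay = m[1], region = m[2], rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))

  med <- stats::median(e)
  if (all(e == e[1])) {
    class_contrast <- data.frame(
      measure = c("promoter_5mC", "genebody_5hmC"), p = NA_real_,
      mean_high = NA_real_, mean_low = NA_real_, undefined = TRUE,
      stringsAsFactors = FALSE)
  } else {
    high <- e > med
    contrast <- function(v) {
      ok <- !is.na(v)
      if (stats::sd(v[ok]) == 0) return(c(NA_real_, mean(v[ok & high]),
                                          mean(v[ok & !high])))
      p <- stats::wilcox.test(v[ok & high], v[ok & !high],
                              exact = FALSE)$p.value
      c(p, mean(v[ok & high]), mean(v[ok & !high]))
    }
    a <- contrast(vals$`5mC_promoter`)
    b <- contrast(vals$`5hmC_genebody`)
    class_contrast <- data.frame(
      measure = c("promoter_5mC", "genebody_5hmC"),
      p = c(a[1], b[1]), mean_high = c(a[2], b[2]),
      mean_low = c(a[3], b[3]), undefined = FALSE, stringsAsFactors = FALSE)
  }
  list(correlations = correlations, class_contrast = class_contrast,
       group = group, n_genes = length(shared))
}

#' Directional multi-omics candidate screen
#'
#' Candidates are genes carrying an unambiguous promoter DMR, an
#' unambiguous promoter DhMR and a consensus DEG call whose three
#' directions cohere: hyper-5mC with hypo-5hmC and down-regulation
#' ("repressed", the tumor-suppressor signature) or the mirror image
#' ("activated").  Incoherent combinations are excluded.  The two-way
#' intersections are reported alongside for transparency.
#'
#' @param hits_5mC,hits_5hmC outputs of [map_promoter_regions()] for the
#'   two assays
#' @param degs output of [call_degs()]
#' @return list with `candidates` (data.frame: `gene_id`, `dmr_direction`,
#'   `dhmr_direction`, `deg_direction`, `class`, `deg_q`, sorted by
#'   `deg_q`) and `intersections` (named list of gene-id vectors)
#' @export
screen_candidates <- function(hits_5mC, hits_5hmC, degs) {
  deg_called <- degs[degs$deg, ]
  mc <- hits_5mC[!hits_5mC$ambiguous, ]
  hmc <- hits_5hmC[!hits_5hmC$ambiguous, ]
  both_marks <- intersect(mc$gene_id, hmc$gene_id)
  inter <- list(
    dmr_dhmr = both_marks,
    dmr_deg = intersect(mc$gene_id, deg_called$gene_id),
    dhmr_deg = intersect(hmc$gene_id, deg_called$gene_id))
  core <- intersect(both_marks, deg_called$gene_id)
  rows <- lapply(core, function(g) {
    d1 <- mc$direction[mc$gene_id == g]
    d2 <- hmc$direction[hmc$gene_id == g]
    d3 <- deg_called$direction[deg_called$gene_id == g]
    cls <- if (d1 == "hyper" && d2 == "hypo" && d3 == "down") "repressed"
      else if (d1 == "hypo" && d2 == "hyper" && d3 == "up") "activated"
      else NA_character_
    if (is.na(cls)) return(NULL)
    data.frame(gene_id = g, dmr_direction = d1, dhmr_direction = d2,
               deg_direction = d3, class = cls,
               deg_q = deg_called$q_median[deg_called$gene_id == g],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), dmr_direction = character(0),
               dhmr_direction = character(0), deg_direction = character(0),
               class = character(0), deg_q = numeric(0),
               stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$deg_q), ]
  rownames(candidates) <- NULL
  list(candidates = candidates, intersections = inter)
}

#' Over-representation test of a gene list
#'
#' One-sided Fisher exact test of the 2x2 overlap table of the gene list
#' against each gene set (intersected with the universe), BH-adjusted
#' across sets.  A local, catalog-free stand-in for web-service pathway
#' enrichment.
#'
#' @param gene_list character vector (subset of `universe`)
#' @param gene_sets named list of character vectors
#' @param universe background gene ids
#' @return data.frame sorted by p: `set`, `overlap`, `set_size`,
#'   `list_size`, `p`, `q`
#' @export
ora_test <- function(gene_list, gene_sets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  gene_list <- intersect(gene_list, universe)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(gene_list, s))
    tab <- matrix(c(a, length(s) - a,
                    length(gene_list) - a,
                    length(universe) - length(s) - length(gene_list) + a),
                  2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, overlap = a, set_size = length(s),
               list_size = length(gene_list), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' @param path a GMT file (set name, description, member genes per line)
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}
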