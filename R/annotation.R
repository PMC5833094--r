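# Synthetic genome annotation: chromosomes, CpG sites, gene models and
# genomic element classes (CpG islands and shores, SINE/LINE/LTR repeats,
# enhancers).  The layout emulates the element structure of a mammalian
# reference at desk scale; there is no base sequence (GC content downstream
# is a documented deterministic proxy of CpG density).

# greedy non-overlapping uniform placement of n intervals of width w on [0, L)
.place_nonoverlapping <- function(n, w, L, margin = 0L) {
  if (n <= 0L) return(integer(0))
  lo <- margin
  hi <- L - w - margin
  if (hi <= lo) return(integer(0))
  starts <- sort(as.integer(floor(stats::runif(3L * n, lo, hi))))
  keep <- integer(0)
  last_end <- -1L
  for (s in starts) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + w
      if (length(keep) >= n) break
    }
  }
  keep
}

#' Generate a synthetic genome annotation
#'
#' Places gene models, element classes and CpG sites on a set of
#' equal-length chromosomes.  Deterministic for a given configuration
#' (including its seed).  CpG sites follow a Poisson process at
#' `cpg_density` per kb genome-wide, with a 4x boosted rate inside CpG
#' islands; 60% of CpG islands are anchored at gene TSSs (so that a
#' realistic share of promoters is CpG-rich), the rest placed uniformly.
#'
#' @param config a [sim_config()]
#' @return an object of class `genome_annotation`: a list with
#'   `chromosomes` (named lengths), `cpg_sites` (per-chromosome sorted
#'   0-based positions), `genes` (data.frame with 0-based half-open
#'   `start`/`end`, `strand`, and `exons` as "start-end" comma strings) and
#'   `elements` (named list of `GRanges`)
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .generate_annotation_impl(config))
}

.generate_annotation_impl <- function(config) {
  L <- as.integer(config$chrom_length)
  chroms <- setNames(rep(L, config$n_chromosomes),
                     paste0("chr", seq_len(config$n_chromosomes)))

  ## gene models (non-overlapping, kept clear of chromosome edges so that
  ## promoter and metaprofile flanks always fit)
  genes <- .place_genes(config, chroms)

  ## elements
  elen <- c(CGI = 1000L, SINE = 300L, LINE = 2000L, LTR = 600L,
            enhancer = 800L)
  elements <- list()
  frac <- config$element_fractions
  # CGIs first: a share anchored at promoters
  cgi <- GenomicRanges::GRanges()
  if (!is.na(frac["CGI"]) && frac["CGI"] > 0) {
    n_cgi_total <- max(0L, round(sum(chroms) * frac[["CGI"]] / elen[["CGI"]]))
    n_anchor <- min(round(0.6 * n_cgi_total), nrow(genes))
    anchored <- GenomicRanges::GRanges()
    if (n_anchor > 0L) {
      gi <- sample(nrow(genes), n_anchor)
      tss <- ifelse(genes$strand[gi] == "+", genes$start[gi], genes$end[gi])
      anchored <- gr0(genes$chrom[gi],
                      pmax(0, tss - elen[["CGI"]] %/% 2L),
                      pmin(L, tss + elen[["CGI"]] %/% 2L))
    }
    free <- GenomicRanges::GRanges()
    n_free_total <- n_cgi_total - n_anchor
    for (cn in names(chroms)) {
      n_here <- round(n_free_total / length(chroms))
      st <- .place_nonoverlapping(n_here, elen[["CGI"]], L)
      if (length(st))
        free <- suppressWarnings(c(free, gr0(cn, st, st + elen[["CGI"]])))
    }
    cgi <- sort(GenomicRanges::reduce(suppressWarnings(c(anchored, free))))
  }
  elements$CGI <- cgi
  for (ty in c("SINE", "LINE", "LTR", "enhancer")) {
    gr <- GenomicRanges::GRanges()
    f <- if (ty %in% names(frac)) frac[[ty]] else 0
    if (f > 0) {
      for (cn in names(chroms)) {
        n_here <- round(L * f / elen[[ty]])
        st <- .place_nonoverlapping(n_here, elen[[ty]], L)
        if (length(st))
          gr <- suppressWarnings(c(gr, gr0(cn, st, st + elen[[ty]])))
      }
    }
    elements[[ty]] <- sort(gr)
  }
  elements <- lapply(elements, .with_seqinfo, chroms = chroms)

  ## CpG sites: Poisson background + boosted rate in CGIs
  rate <- config$cpg_density / 1000
  cpg_sites <- lapply(names(chroms), function(cn) {
    n_bg <- stats::rpois(1, L * rate)
    pos <- floor(stats::runif(n_bg, 0, L))
    cgi_c <- elements$CGI[GenomicRanges::seqnames(elements$CGI) == cn]
    if (length(cgi_c)) {
      w <- GenomicRanges::width(cgi_c)
      n_extra <- stats::rpois(length(cgi_c), w * 4 * rate)
      extra <- unlist(mapply(function(s, wd, k) {
        floor(stats::runif(k, s, s + wd))
      }, GenomicRanges::start(cgi_c) - 1L, w, n_extra, SIMPLIFY = FALSE))
      pos <- c(pos, extra)
    }
    sort(unique(as.integer(pos)))
  })
  names(cpg_sites) <- names(chroms)

  ann <- list(chromosomes = chroms, cpg_sites = cpg_sites,
              genes = genes, elements = elements)
  class(ann) <- "genome_annotation"
  ann
}

.place_genes <- function(config, chroms) {
  n <- config$n_genes
  cols <- c("gene_id", "chrom", "strand", "start", "end", "exons")
  if (n == 0L) {
    df <- data.frame(gene_id = character(0), chrom = character(0),
                     strand = character(0), start = integer(0),
                     end = integer(0), exons = character(0),
                     stringsAsFactors = FALSE)
    return(df[cols])
  }
  L <- as.integer(config$chrom_length)
  per_chr <- diff(round(seq(0, n, length.out = length(chroms) + 1L)))
  out <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    cn <- names(chroms)[ci]
    len <- as.integer(pmin(30000, pmax(2000,
      round(stats::rlnorm(per_chr[ci], log(6000), 0.5)))))
    # greedy placement with a uniform width budget: place the longest first
    ord <- order(-len)
    occupied <- IRanges::IRanges()
    for (k in ord) {
      w <- len[k]
      placed <- FALSE
      for (try in 1:50) {
        s <- as.integer(floor(stats::runif(1, 2500, L - w - 2500)))
        cand <- IRanges::IRanges(s + 1L, s + w)
        # 200 bp clearance between gene spans
        if (!IRanges::overlapsAny(cand + 200L, occupied)) {
          occupied <- c(occupied, cand)
          gid <- gid + 1L
          out[[length(out) + 1L]] <- data.frame(
            gene_id = sprintf("G%04d", gid), chrom = cn,
            strand = sample(c("+", "-"), 1L),
            start = s, end = s + w,
            exons = .make_exons(s, s + w),
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) next
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df[cols]
}

# random exon/intron structure: first and last segments are exonic
.make_exons <- function(start, end) {
  k <- sample(2:6, 1L)          # number of exons
  n_cut <- 2L * (k - 1L)
  if (end - start < n_cut + 2L) return(sprintf("%d-%d", start, end))
  cuts <- sort(sample(seq(start + 1L, end - 1L), n_cut))
  bounds <- c(start, cuts, end)
  idx <- seq(1L, length(bounds) - 1L, by = 2L)
  paste(sprintf("%d-%d", bounds[idx], bounds[idx + 1L]), collapse = ",")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes), big.mark = ","), "bp\n")
  cat("  CpG sites:", format(sum(lengths(x$cpg_sites)), big.mark = ","),
      " genes:", nrow(x$genes), "\n")
  cat("  elements:", paste(sprintf("%s=%d", names(x$elements),
                                   lengths(x$elements)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Gene models as GRanges
#'
#' @param annotation a `genome_annotation`
#' @return `GRanges` of gene spans with `gene_id` metadata and strand
#' @export
genes_gr <- function(annotation) {
  g <- annotation$genes
  if (nrow(g) == 0L)
    return(GenomicRanges::GRanges())
  gr <- gr0(g$chrom, g$start, g$end, strand = g$strand)
  S4Vectors::mcols(gr)$gene_id <- g$gene_id
  gr
}

# 0-based TSS / TES positions (TSS of a minus-strand gene is its end bound)
.gene_tss0 <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)
.gene_tes0 <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

#' Promoter ranges (TSS +/- flank)
#'
#' The promoter convention used uniformly across the package: the 0-based
#' half-open interval `[TSS - flank, TSS + flank)`, where the TSS of a
#' plus-strand gene is its start bound and of a minus-strand gene its end
#' bound.
#'
#' @param annotation a `genome_annotation`
#' @param flank bp on each side of the TSS (default 500)
#' @return `GRanges` with `gene_id` metadata
#' @export
promoter_ranges <- function(annotation, flank = 500L) {
  g <- annotation$genes
  if (nrow(g) == 0L) return(GenomicRanges::GRanges())
  tss <- .gene_tss0(g)
  L <- annotation$chromosomes[g$chrom]
  gr <- gr0(g$chrom, pmax(0, tss - flank), pmin(L, tss + flank))
  S4Vectors::mcols(gr)$gene_id <- g$gene_id
  gr
}

#' Element ranges by class
#'
#' Returns the genomic intervals of a named element class.  Annotated
#' classes (`CGI`, `SINE`, `LINE`, `LTR`, `enhancer`) come straight from the
#' annotation; derived classes are computed on the fly: `CGI_shore` (the
#' 2-kb flanks of each CpG island, CGI-subtracted), `promoter`/`TSS`
#' (TSS +/- 500 bp), `TES` (TES +/- 500 bp), `genebody` (gene spans),
#' `exon`, and `intron` (gene span minus exons).
#'
#' @param annotation a `genome_annotation`
#' @param type element class name
#' @return a `GRanges` (possibly empty)
#' @export
element_ranges <- function(annotation, type) {
  g <- annotation$genes
  L <- annotation$chromosomes
  if (type %in% names(annotation$elements))
    return(annotation$elements[[type]])
  switch(type,
    CGI_shore = {
      cgi <- annotation$elements$CGI
      if (length(cgi) == 0L) return(GenomicRanges::GRanges())
      fl <- suppressWarnings(
        c(GenomicRanges::flank(cgi, 2000L, start = TRUE),
          GenomicRanges::flank(cgi, 2000L, start = FALSE)))
      fl <- GenomicRanges::trim(fl)
      fl <- fl[GenomicRanges::width(fl) > 0L]
      GenomicRanges::reduce(GenomicRanges::setdiff(fl, cgi))
    },
    promoter = promoter_ranges(annotation),
    TSS = promoter_ranges(annotation),
    TES = {
      if (nrow(g) == 0L) return(GenomicRanges::GRanges())
      tes <- .gene_tes0(g)
      gr0(g$chrom, pmax(0, tes - 500L), pmin(L[g$chrom], tes + 500L))
    },
    genebody = {
      if (nrow(g) == 0L) return(GenomicRanges::GRanges())
      gr0(g$chrom, g$start, g$end)
    },
    exon = .exon_gr(g),
    intron = {
      if (nrow(g) == 0L) return(GenomicRanges::GRanges())
      GenomicRanges::reduce(GenomicRanges::setdiff(
        gr0(g$chrom, g$start, g$end), .exon_gr(g)))
    },
    stop("unknown element class: ", type)
  )
}

.exon_gr <- function(genes) {
  if (nrow(genes) == 0L) return(GenomicRanges::GRanges())
  parts <- strsplit(genes$exons, ",", fixed = TRUE)
  chrom <- rep(genes$chrom, lengths(parts))
  iv <- do.call(rbind, lapply(unlist(parts), function(p) {
    as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
  }))
  gr0(chrom, iv[, 1], iv[, 2])
}

#' Per-chromosome feature table
#'
#' Chromosome-scale descriptors used for feature/depth correlations:
#' length, gene density (genes per Mb), repeat density (fraction of bp in
#' SINE/LINE/LTR), CpG density, GC content and CpG observed/expected ratio.
#' GC here is the package's deterministic proxy from CpG density (the
#' synthetic genome carries no base sequence); see the methods vignette.
#'
#' @param annotation a `genome_annotation`
#' @param snp_density optional user-supplied per-chromosome SNP density
#' @return data.frame, one row per chromosome
#' @export
chromosome_features <- function(annotation, snp_density = NULL) {
  chroms <- annotation$chromosomes
  rep_gr <- GenomicRanges::reduce(c(annotation$elements$SINE,
                                    annotation$elements$LINE,
                                    annotation$elements$LTR))
  rep_bp <- sapply(names(chroms), function(cn)
    sum(GenomicRanges::width(rep_gr[GenomicRanges::seqnames(rep_gr) == cn])))
  n_genes <- sapply(names(chroms), function(cn)
    sum(annotation$genes$chrom == cn))
  cpg_dens <- lengths(annotation$cpg_sites)[names(chroms)] / chroms
  gc <- .gc_proxy(cpg_dens)
  df <- data.frame(chrom = names(chroms),
                   length = as.numeric(chroms),
                   gene_density = n_genes / (chroms / 1e6),
                   repeat_density = rep_bp / chroms,
                   gc_content = gc,
                   cpg_oe = cpg_dens / ((gc / 2)^2),
                   stringsAsFactors = FALSE)
  if (!is.null(snp_density)) df$snp_density <- snp_density
  rownames(df) <- NULL
  df
}

# deterministic GC proxy from local CpG density (per-bp); monotone, capped
.gc_proxy <- function(cpg_per_bp) pmin(0.85, 0.35 + 9 * cpg_per_bp)
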