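# Readers and writers for the standard on-disk formats: BED (0-based
# half-open) for intervals via rtracklayer, TSV with headers for tables,
# YAML for configurations.

#' Write fragments as BED3, one file per sample
#'
#' Files are named `<sample>.bed` where the sample id encodes
#' patient/assay/group (e.g. `P1_5mC_tumor.bed`).
#'
#' @param fragments named list of `GRanges`
#' @param dir output directory (created if needed)
#' @return invisibly, the written paths
#' @export
write_fragments_bed <- function(fragments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(fragments), function(nm) {
    path <- file.path(dir, paste0(nm, ".bed"))
    df <- bed_frame(fragments[[nm]])
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read fragment BED files listed in a sample sheet
#'
#' @param sheet data.frame with columns `sample`, `patient`, `group`,
#'   `assay`, `file`
#' @return named list of `GRanges` in sheet order
#' @export
read_fragments_bed <- function(sheet) {
  frs <- lapply(sheet$file, function(f) {
    if (!file.exists(f)) stop("fragment file not found: ", f)
    dt <- data.table::fread(f, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end")[1:3],
                            select = 1:3)
    gr0(dt$chrom, dt$start, dt$end)
  })
  names(frs) <- sheet$sample
  frs
}

#' Write a genome annotation to plain-text files
#'
#' `chrom_sizes.tsv`, `genes.tsv` (0-based half-open bounds, exon list as a
#' comma string), `elements.bed` (BED4, name = element class) and
#' `cpg_sites.bed` (BED3, width-1).
#'
#' @param annotation a `genome_annotation`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.frame(chrom = names(annotation$chromosomes),
                                length = as.integer(annotation$chromosomes)),
                     file.path(dir, "chrom_sizes.tsv"), sep = "\t")
  data.table::fwrite(annotation$genes, file.path(dir, "genes.tsv"),
                     sep = "\t")
  el <- do.call(rbind, lapply(names(annotation$elements), function(ty) {
    gr <- annotation$elements[[ty]]
    if (length(gr) == 0L) return(NULL)
    cbind(bed_frame(gr), name = ty)
  }))
  if (is.null(el))
    el <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), name = character(0))
  el <- el[order(el$chrom, el$start, el$name), ]
  data.table::fwrite(el, file.path(dir, "elements.bed"), sep = "\t",
                     col.names = FALSE)
  cpg <- data.frame(
    chrom = rep(names(annotation$cpg_sites),
                lengths(annotation$cpg_sites)),
    start = unlist(annotation$cpg_sites, use.names = FALSE))
  cpg$end <- cpg$start + 1L
  data.table::fwrite(cpg, file.path(dir, "cpg_sites.bed"), sep = "\t",
                     col.names = FALSE)
  invisible(dir)
}

#' Read a genome annotation written by [write_annotation()]
#'
#' @param dir directory holding `chrom_sizes.tsv`, `genes.tsv`,
#'   `elements.bed`, `cpg_sites.bed`
#' @return a `genome_annotation`
#' @export
read_annotation <- function(dir) {
  need <- file.path(dir, c("chrom_sizes.tsv", "genes.tsv", "elements.bed",
                           "cpg_sites.bed"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing annotation file(s): ", paste(missing, collapse = ", "))
  cs <- data.table::fread(need[1], sep = "\t")
  chroms <- setNames(as.numeric(cs$length), cs$chrom)
  genes <- as.data.frame(data.table::fread(need[2], sep = "\t",
                                           colClasses = list(
                                             character = "exons")))
  el <- data.table::fread(need[3], header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name"))
  elements <- lapply(split(el, el$name), function(d)
    sort(gr0(d$chrom, d$start, d$end)))
  for (ty in c("CGI", "SINE", "LINE", "LTR", "enhancer"))
    if (is.null(elements[[ty]])) elements[[ty]] <- GenomicRanges::GRanges()
  elements <- lapply(elements, .with_seqinfo, chroms = chroms)
  cpg <- data.table::fread(need[4], header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end"))
  cpg_sites <- lapply(split(cpg$start, cpg$chrom), function(v)
    sort(as.integer(v)))
  cpg_sites <- cpg_sites[names(chroms)]
  names(cpg_sites) <- names(chroms)
  ann <- list(chromosomes = chroms, cpg_sites = cpg_sites,
              genes = genes,
              elements = elements[c("CGI", "SINE", "LINE", "LTR",
                                    "enhancer")])
  class(ann) <- "genome_annotation"
  ann
}

#' Write differential regions as BED6
#'
#' name = direction, score = min(1000, round(-log10 p x 100)) so browser
#' shading preserves the p ordering.
#'
#' @param regions a `diff_regions` data.frame
#' @param path output BED path
#' @return invisibly, the path
#' @export
write_regions_bed6 <- function(regions, path) {
  score <- if (nrow(regions)) pmin(1000,
    round(-log10(pmax(regions$p, 1e-300)) * 100)) else integer(0)
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end, name = regions$direction,
                   score = as.integer(score),
                   strand = rep(".", nrow(regions)))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write/read a gene-level count matrix TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param counts genes x samples matrix
#' @param path TSV path
#' @return invisibly the path / the matrix
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write the truth table to TSV files
#'
#' @param truth a `truth_table`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(truth$planted_regions,
                     file.path(dir, "planted_regions.tsv"), sep = "\t")
  data.table::fwrite(truth$planted_degs,
                     file.path(dir, "planted_degs.tsv"), sep = "\t")
  data.table::fwrite(truth$couplings, file.path(dir, "couplings.tsv"),
                     sep = "\t")
  invisible(dir)
}
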