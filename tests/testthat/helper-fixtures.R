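# Shared fixtures: small hand-built annotations and track matrices used
# across the module tests.  Everything is generated in code.

# minimal annotation: chromosomes + CpG sites only (no genes/elements)
bare_annotation <- function(chroms, cpg = NULL) {
  if (is.null(cpg))
    cpg <- setNames(rep(list(integer(0)), length(chroms)), names(chroms))
  ann <- list(chromosomes = chroms, cpg_sites = cpg,
              genes = data.frame(gene_id = character(0), chrom = character(0),
                                 strand = character(0), start = integer(0),
                                 end = integer(0), exons = character(0),
                                 stringsAsFactors = FALSE),
              elements = list(CGI = GenomicRanges::GRanges(),
                              SINE = GenomicRanges::GRanges(),
                              LINE = GenomicRanges::GRanges(),
                              LTR = GenomicRanges::GRanges(),
                              enhancer = GenomicRanges::GRanges()))
  class(ann) <- "genome_annotation"
  ann
}

# annotation with explicit gene models
gene_annotation <- function(chroms, genes) {
  ann <- bare_annotation(chroms)
  ann$genes <- genes
  ann
}

# track matrix built directly from an RPM matrix (counts = rpm, unit lib)
manual_track <- function(rpm, windows, samples = NULL) {
  track_matrix(counts = rpm, rpm = rpm, samples = samples,
               library_sizes = rep(1e6, ncol(rpm)), windows = windows)
}

# paired sample sheet for one assay
paired_sheet <- function(n_pairs, assay = "5mC") {
  data.frame(
    sample = as.vector(t(outer(paste0("P", seq_len(n_pairs)),
                               c("tumor", "normal"), paste, sep = "_"))),
    patient = rep(paste0("P", seq_len(n_pairs)), each = 2),
    group = rep(c("tumor", "normal"), n_pairs),
    assay = assay, stringsAsFactors = FALSE)
}

# paired track with given per-pair tumor/normal rpm row-vectors
paired_track <- function(rpm_tumor, rpm_normal, windows, assay = "5mC") {
  n_pairs <- ncol(rpm_tumor)
  sheet <- paired_sheet(n_pairs, assay)
  rpm <- matrix(0, nrow(rpm_tumor), 2 * n_pairs,
                dimnames = list(NULL, sheet$sample))
  rpm[, sheet$group == "tumor"] <- rpm_tumor
  rpm[, sheet$group == "normal"] <- rpm_normal
  manual_track(rpm, windows, sheet)
}

# small default simulation reused by several tests (counts-only, fast)
small_sim <- function(seed = 11, ...) {
  cfg <- sim_config(seed = seed, n_chromosomes = 2L, chrom_length = 3e5,
                    n_genes = 40L, ...)
  simulate_all(cfg, fragments = FALSE)
}
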