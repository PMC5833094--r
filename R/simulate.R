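# Paired tumor/normal MeDIP/hMeDIP fragment simulator with planted truth.
#
# Expected fragment count of window w, sample s:
#   mu(w, s) = base_depth * widthfrac(w) * signal(w, assay, group)
#              * 2^(+-effect_log2  if w in a planted region, tumor only)
#              * depth_factor(s)
# realized as negative-binomial draws (variance mu + phi mu^2).  The signal
# term is driven by element composition; for tumor 5hmC the *enrichment*
# component of the signal is scaled by hmc_global_factor while the
# immunoprecipitation background is untouched, so a global depletion of the
# mark changes the relative (RPM) landscape the way a genuine loss of
# hydroxymethylation does (a uniform scaling of every window would be
# cancelled exactly by RPM normalization and thus unobservable).

.HMC_BACKGROUND <- 0.3

# element-driven signal multipliers per window
.signal_multipliers <- function(windows, annotation, hmc_factor = 1) {
  gene_f <- .overlap_fraction(windows, element_ranges(annotation, "genebody"))
  cgi_f <- .overlap_fraction(windows, annotation$elements$CGI)
  enh_f <- .overlap_fraction(windows, annotation$elements$enhancer)
  rep_f <- .overlap_fraction(windows, GenomicRanges::reduce(
    c(annotation$elements$SINE, annotation$elements$LINE,
      annotation$elements$LTR)))
  mc <- pmax(0.1, 1 + 0.5 * rep_f + 0.3 * gene_f - 0.5 * cgi_f)
  hmc_sig <- 1.5 * gene_f + 2.5 * enh_f + 0.8 * cgi_f
  list(mc = mc,
       hmc_normal = .HMC_BACKGROUND + hmc_sig,
       hmc_tumor = .HMC_BACKGROUND + hmc_factor * hmc_sig)
}

#' Analytic expected window counts of the generative model
#'
#' The per-window expected fragment count for each assay/group at unit
#' depth factor and before any planted effect.  Used as the closed-form
#' oracle for generative-model consistency checks.
#'
#' @param annotation a `genome_annotation`
#' @param config a [sim_config()]
#' @return list with `windows` and numeric vectors `mc_normal`, `mc_tumor`,
#'   `hmc_normal`, `hmc_tumor`
#' @export
analytic_window_means <- function(annotation, config) {
  windows <- tile_genome(annotation, config$window_size)
  sig <- .signal_multipliers(windows, annotation, config$hmc_global_factor)
  wf <- GenomicRanges::width(windows) / config$window_size
  b <- config$base_depth
  list(windows = windows,
       mc_normal = b * wf * sig$mc,
       mc_tumor = b * wf * sig$mc,
       hmc_normal = b * wf * sig$hmc_normal,
       hmc_tumor = b * wf * sig$hmc_tumor)
}

#' Simulate paired MeDIP/hMeDIP fragment tracks with planted truth
#'
#' Generates, for every patient pair and both assays, negative-binomial
#' window counts under the generative model above, plants differential
#' regions (promoter-anchored hyper-5mC regions, their coupled promoter
#' hypo-5hmC partners, and randomly placed two-window regions of random
#' direction restricted to CpG-eligible non-promoter windows), and
#' optionally materializes fragments as ~200-bp intervals whose midpoints
#' are uniform within the generating window (so midpoint counting
#' reproduces the drawn counts exactly).
#'
#' @param annotation a `genome_annotation`
#' @param config a [sim_config()]
#' @param fragments materialize fragment `GRanges` per sample? (window
#'   counts are drawn before any fragment randomness, so counts are
#'   identical for both settings under the same config)
#' @return an object of class `sim_tracks`: list with `fragments` (named
#'   list of `GRanges` or `NULL`), `counts` (windows x samples), `samples`,
#'   `windows`, `truth` (a `truth_table`), `depth_factors`, `config`
#' @export
simulate_tracks <- function(annotation, config, fragments = TRUE) {
  validate_sim_config(config)
  windows <- tile_genome(annotation, config$window_size)
  sig <- .signal_multipliers(windows, annotation, config$hmc_global_factor)
  withr::with_seed(config$seed + 1L, {
    truth <- .plant_truth(windows, annotation, config)
    sim <- .draw_tracks(windows, annotation, config, sig, truth, fragments)
  })
  sim$truth <- truth
  sim$windows <- windows
  sim$config <- config
  class(sim) <- "sim_tracks"
  sim
}

#' @export
print.sim_tracks <- function(x, ...) {
  cat("sim_tracks:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples;", nrow(x$truth$planted_regions), "planted regions\n")
  invisible(x)
}

.plant_truth <- function(windows, annotation, config) {
  genes <- annotation$genes
  eligible <- S4Vectors::mcols(windows)$n_cpg >= 5L &
    GenomicRanges::width(windows) == config$window_size
  prom <- promoter_ranges(annotation)
  prom_win <- IRanges::overlapsAny(windows, prom)

  # promoter-anchored plants: genes whose TSS window is CpG-eligible
  tss_win <- rep(NA_integer_, nrow(genes))
  gene_prom_windows <- list()
  if (nrow(genes) > 0L) {
    hits <- GenomicRanges::findOverlaps(prom, windows)
    gene_prom_windows <- split(S4Vectors::subjectHits(hits),
                               S4Vectors::queryHits(hits))
    tss_gr <- .pos_gr(genes$chrom, .gene_tss0(genes))
    th <- GenomicRanges::findOverlaps(tss_gr, windows)
    tss_win[S4Vectors::queryHits(th)] <- S4Vectors::subjectHits(th)
  }
  cand_genes <- which(!is.na(tss_win) & eligible[tss_win])

  # planted promoter region = the contiguous CpG-eligible window run
  # around the TSS window (keeps the detectability invariant)
  prom_region_windows <- function(gi) {
    wix <- sort(gene_prom_windows[[as.character(gi)]])
    wix <- wix[eligible[wix]]
    if (length(wix) == 0L) return(integer(0))
    run <- cumsum(c(1L, diff(wix) != 1L))
    wix[run == run[wix == tss_win[gi]]]
  }
  n_prom <- min(round(0.5 * config$n_planted_dmr), length(cand_genes))
  used_prom <- logical(length(windows))
  sel <- integer(0)
  sel_windows <- list()
  for (gi in sample(cand_genes)) {
    if (length(sel) >= n_prom) break
    wix <- prom_region_windows(gi)
    if (length(wix) == 0L || any(used_prom[wix])) next
    used_prom[wix] <- TRUE
    sel <- c(sel, gi)
    sel_windows[[as.character(gi)]] <- wix
  }
  n_prom <- length(sel)
  n_coupled <- round(config$coupled_fraction * n_prom)
  coupled_genes <- sel[seq_len(n_coupled)]

  region_row <- function(wix, assay, direction, gene_id, coupled) {
    data.frame(assay = assay,
               chrom = as.character(GenomicRanges::seqnames(windows[wix[1]])),
               start = min(GenomicRanges::start(windows[wix])) - 1L,
               end = max(GenomicRanges::end(windows[wix])),
               direction = direction, effect_log2 = config$effect_log2,
               gene_id = gene_id, coupled = coupled,
               stringsAsFactors = FALSE)
  }

  regions <- list(); plant_mc <- list(); plant_hmc <- list()
  used_mc <- used_prom; used_hmc <- used_prom
  for (k in seq_along(sel)) {
    gi <- sel[k]
    wix <- sel_windows[[as.character(gi)]]
    coupled <- gi %in% coupled_genes
    regions[[length(regions) + 1L]] <-
      region_row(wix, "5mC", "hyper", genes$gene_id[gi], coupled)
    plant_mc[[length(plant_mc) + 1L]] <- list(wix = wix, dir = +1)
    if (coupled) {
      regions[[length(regions) + 1L]] <-
        region_row(wix, "5hmC", "hypo", genes$gene_id[gi], TRUE)
      plant_hmc[[length(plant_hmc) + 1L]] <- list(wix = wix, dir = -1)
    }
  }

  # random two-window plants in eligible, non-promoter windows
  place_random <- function(n, used) {
    out <- list()
    pool <- which(eligible & !prom_win)
    pool <- pool[pool + 1L <= length(windows) &
                 (pool + 1L) %in% which(eligible & !prom_win) &
                 as.character(GenomicRanges::seqnames(windows[pool])) ==
                 as.character(GenomicRanges::seqnames(windows[pmin(pool + 1L,
                   length(windows))]))]
    for (i in sample(pool)) {
      if (length(out) >= n) break
      wix <- c(i, i + 1L)
      guard <- unique(pmax(1L, pmin(length(windows), c(wix - 1L, wix,
                                                       wix + 1L))))
      if (any(used[guard])) next
      used[wix] <- TRUE
      out[[length(out) + 1L]] <- wix
    }
    list(regions = out, used = used)
  }
  rmc <- place_random(config$n_planted_dmr - n_prom, used_mc)
  for (wix in rmc$regions) {
    dir <- sample(c("hyper", "hypo"), 1L)
    regions[[length(regions) + 1L]] <-
      region_row(wix, "5mC", dir, NA_character_, FALSE)
    plant_mc[[length(plant_mc) + 1L]] <-
      list(wix = wix, dir = if (dir == "hyper") +1 else -1)
  }
  rhmc <- place_random(max(0L, config$n_planted_dhmr - n_coupled), used_hmc)
  for (wix in rhmc$regions) {
    dir <- sample(c("hyper", "hypo"), 1L)
    regions[[length(regions) + 1L]] <-
      region_row(wix, "5hmC", dir, NA_character_, FALSE)
    plant_hmc[[length(plant_hmc) + 1L]] <-
      list(wix = wix, dir = if (dir == "hyper") +1 else -1)
  }

  planted_regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(assay = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               direction = character(0), effect_log2 = numeric(0),
               gene_id = character(0), coupled = logical(0))

  # planted DEGs: coupled genes are down-regulated; extra DEGs avoid any
  # gene carrying a planted promoter region (identifiability of the screen)
  degs <- list()
  for (gi in coupled_genes)
    degs[[length(degs) + 1L]] <- data.frame(
      gene_id = genes$gene_id[gi], direction = "down",
      fold = config$deg_fold, coupled = TRUE, stringsAsFactors = FALSE)
  n_extra <- max(0L, config$n_planted_deg - n_coupled)
  pool <- setdiff(seq_len(nrow(genes)), sel)
  for (gi in head(sample(pool), n_extra))
    degs[[length(degs) + 1L]] <- data.frame(
      gene_id = genes$gene_id[gi],
      direction = sample(c("up", "down"), 1L),
      fold = config$deg_fold, coupled = FALSE, stringsAsFactors = FALSE)
  planted_degs <- if (length(degs)) do.call(rbind, degs) else
    data.frame(gene_id = character(0), direction = character(0),
               fold = numeric(0), coupled = logical(0))

  couplings <- data.frame(gene_id = as.character(genes$gene_id[coupled_genes]),
                          hyper_5mC = rep(TRUE, length(coupled_genes)),
                          hypo_5hmC = rep(TRUE, length(coupled_genes)),
                          down_deg = rep(TRUE, length(coupled_genes)),
                          stringsAsFactors = FALSE)

  structure(list(planted_regions = planted_regions,
                 planted_degs = planted_degs,
                 couplings = couplings,
                 plant_mc = plant_mc, plant_hmc = plant_hmc),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  pr <- x$planted_regions
  cat("truth_table:", sum(pr$assay == "5mC"), "planted 5mC regions,",
      sum(pr$assay == "5hmC"), "planted 5hmC regions,",
      nrow(x$planted_degs), "planted DEGs (",
      nrow(x$couplings), "coupled )\n")
  invisible(x)
}

.track_sample_sheet <- function(n_pairs) {
  grid <- expand.grid(group = c("tumor", "normal"),
                      patient = paste0("P", seq_len(n_pairs)),
                      assay = c("5mC", "5hmC"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("patient", "group", "assay")]
  grid$sample <- sprintf("%s_%s_%s", grid$patient, grid$assay, grid$group)
  grid[, c("sample", "patient", "group", "assay")]
}

.draw_tracks <- function(windows, annotation, config, sig, truth,
                         make_fragments) {
  samples <- .track_sample_sheet(config$n_pairs)
  n_win <- length(windows)
  wf <- GenomicRanges::width(windows) / config$window_size
  base <- list(
    `5mC_normal` = config$base_depth * wf * sig$mc,
    `5mC_tumor` = config$base_depth * wf * sig$mc,
    `5hmC_normal` = config$base_depth * wf * sig$hmc_normal,
    `5hmC_tumor` = config$base_depth * wf * sig$hmc_tumor)
  # planted effects act on tumor expectations only
  eff <- 2^config$effect_log2
  for (p in truth$plant_mc)
    base$`5mC_tumor`[p$wix] <- base$`5mC_tumor`[p$wix] * eff^p$dir
  for (p in truth$plant_hmc)
    base$`5hmC_tumor`[p$wix] <- base$`5hmC_tumor`[p$wix] * eff^p$dir

  depth_f <- stats::rlnorm(nrow(samples), 0, 0.1)
  counts <- matrix(0L, n_win, nrow(samples),
                   dimnames = list(NULL, samples$sample))
  for (i in seq_len(nrow(samples))) {
    key <- paste0(samples$assay[i], "_", samples$group[i])
    mu <- base[[key]] * depth_f[i]
    counts[, i] <- stats::rnbinom(n_win, mu = mu,
                                  size = 1 / config$nb_dispersion)
  }

  frags <- NULL
  if (make_fragments) {
    chrom <- as.character(GenomicRanges::seqnames(windows))
    ws0 <- GenomicRanges::start(windows) - 1L
    wwid <- GenomicRanges::width(windows)
    L <- annotation$chromosomes
    frags <- vector("list", nrow(samples))
    names(frags) <- samples$sample
    for (i in seq_len(nrow(samples))) {
      cnt <- counts[, i]
      widx <- rep.int(seq_len(n_win), cnt)
      n <- length(widx)
      mid0 <- ws0[widx] + as.integer(floor(stats::runif(n) * wwid[widx]))
      len <- pmax(50L, as.integer(round(stats::rnorm(n, 200, 20))))
      half <- len %/% 2L
      s0 <- pmax(0L, mid0 - half)
      e0 <- pmin(as.integer(L[chrom[widx]]), mid0 + (len - half))
      frags[[i]] <- gr0(chrom[widx], s0, e0)
    }
  }
  list(fragments = frags, counts = counts, samples = samples,
       depth_factors = depth_f)
}

#' Track matrix of one assay from a simulation
#'
#' Subsets the simulated window counts to one assay and normalizes to RPM
#' (library size = per-sample total fragments).
#'
#' @param sim a `sim_tracks`
#' @param assay `"5mC"` or `"5hmC"`
#' @return a `track_matrix`
#' @export
sim_track_matrix <- function(sim, assay) {
  idx <- which(sim$samples$assay == assay)
  if (length(idx) == 0L) stop("no samples for assay ", assay)
  counts <- sim$counts[, idx, drop = FALSE]
  lib <- colSums(counts)
  rpm <- sweep(counts, 2L, pmax(lib, 1), "/") * 1e6
  track_matrix(counts, rpm, sim$samples[idx, , drop = FALSE], lib,
               sim$windows)
}

#' Simulate the expression count matrix
#'
#' Negative-binomial gene counts for the paired RNA-seq arm.  Planted DEGs
#' (including the promoter-coupled, down-regulated genes) have their tumor
#' expectation multiplied or divided by the planted fold; library sizes
#' vary across samples.  Planted genes get a floor on their baseline mean
#' so the planted effect is detectable by design.
#'
#' @param annotation a `genome_annotation`
#' @param truth a `truth_table` from [simulate_tracks()]
#' @param config a [sim_config()]
#' @return an object of class `expr_sim`: list with `counts`
#'   (genes x samples), `samples`, `gene_length` (longest-transcript bp,
#'   here the summed exon widths)
#' @export
simulate_expression <- function(annotation, truth, config) {
  genes <- annotation$genes
  if (nrow(genes) == 0L) stop("annotation has no genes")
  missing <- setdiff(truth$planted_degs$gene_id, genes$gene_id)
  if (length(missing))
    stop("truth references genes absent from annotation: ",
         paste(missing, collapse = ", "))
  withr::with_seed(config$seed + 2L, {
    n_g <- nrow(genes)
    base <- stats::rlnorm(n_g, log(config$expr_base_mean), 1)
    names(base) <- genes$gene_id
    planted <- truth$planted_degs$gene_id
    base[planted] <- pmax(base[planted], config$expr_base_mean / 2)

    samples <- data.frame(
      patient = rep(paste0("P", seq_len(config$n_pairs)), each = 2L),
      group = rep(c("tumor", "normal"), config$n_pairs),
      stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_%s", samples$patient, samples$group)
    libf <- stats::rlnorm(nrow(samples), 0, 0.15)

    mu <- outer(base, libf)
    if (nrow(truth$planted_degs)) {
      fold <- ifelse(truth$planted_degs$direction == "up",
                     truth$planted_degs$fold, 1 / truth$planted_degs$fold)
      tcols <- which(samples$group == "tumor")
      mu[match(planted, genes$gene_id), tcols] <-
        mu[match(planted, genes$gene_id), tcols] * fold
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$expr_dispersion),
                     nrow = n_g,
                     dimnames = list(genes$gene_id, samples$sample))
  })
  ex <- .exon_gr(genes)
  glen <- tapply(GenomicRanges::width(ex),
                 rep(genes$gene_id, lengths(strsplit(genes$exons, ","))),
                 sum)
  gene_length <- setNames(as.integer(glen[genes$gene_id]), genes$gene_id)
  structure(list(counts = counts, samples = samples[, c("sample", "patient",
                                                        "group")],
                 gene_length = gene_length),
            class = "expr_sim")
}

#' Run the whole generator
#'
#' Convenience wrapper: annotation, fragment tracks and expression matrix
#' from one configuration.
#'
#' @param config a [sim_config()]
#' @param fragments passed to [simulate_tracks()]
#' @return list with `annotation`, `tracks`, `expression`
#' @export
simulate_all <- function(config, fragments = TRUE) {
  annotation <- generate_annotation(config)
  tracks <- simulate_tracks(annotation, config, fragments = fragments)
  expression <- if (config$n_genes > 0L)
    simulate_expression(annotation, tracks$truth, config) else NULL
  list(annotation = annotation, tracks = tracks, expression = expression)
}
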