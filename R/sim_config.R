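#' Simulation configuration for the paired tumor/normal study emulator
#'
#' Collects every constant of the synthetic study design: genome geometry,
#' the paired design (six patients by default, matching the emulated study),
#' CpG and element densities, the planted differential-region and
#' differential-expression effects, the global tumor 5hmC depletion, and the
#' negative-binomial noise model of the enrichment counts.
#'
#' @param n_chromosomes number of (equal-length) chromosomes
#' @param chrom_length chromosome length in bp
#' @param n_pairs number of tumor/normal patient pairs (>= 2)
#' @param window_size tiling window width in bp (default 500, the analysis
#'   resolution of the emulated study)
#' @param cpg_density background CpG sites per kb (Poisson placement; CpG
#'   islands carry an additional boost, see [generate_annotation()])
#' @param n_genes number of non-overlapping gene models to place
#' @param element_fractions named numeric vector, genome fraction per element
#'   class (`CGI`, `SINE`, `LINE`, `LTR`, `enhancer`); each in \[0,1\] and
#'   their sum must leave room on the genome
#' @param n_planted_dmr,n_planted_dhmr number of planted differential 5mC /
#'   5hmC regions
#' @param effect_log2 log2 shift of the tumor expected count in planted
#'   regions (hyper: `+effect_log2`, hypo: `-effect_log2`)
#' @param hmc_global_factor multiplicative tumor scaling, in (0, 1], of the
#'   5hmC *enrichment* (signal) component; 1 means no global depletion.
#'   The default 0.7 reproduces the global tumor hydroxymethylation loss
#'   that characterizes the emulated study design
#' @param nb_dispersion negative-binomial dispersion phi of window fragment
#'   counts (variance = mu + phi mu^2)
#' @param base_depth expected background fragments per full window per sample
#' @param n_planted_deg total number of planted differentially expressed
#'   genes (includes the promoter-coupled ones)
#' @param deg_fold fold change of planted DEGs (> 1)
#' @param coupled_fraction fraction of the planted promoter hyper-5mC regions
#'   that also carry a promoter hypo-5hmC region and a down-regulated DEG
#' @param expr_base_mean median expected RNA-seq count per gene
#' @param expr_dispersion negative-binomial dispersion of expression counts
#' @param seed integer seed; all generator outputs are pure functions of the
#'   configuration including this seed
#'
#' @return an object of class `sim_config` (a validated named list)
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1e6,
                       n_pairs = 6L,
                       window_size = 500L,
                       cpg_density = 10,
                       n_genes = 150L,
                       element_fractions = c(CGI = 0.01, SINE = 0.10,
                                             LINE = 0.12, LTR = 0.05,
                                             enhancer = 0.02),
                       n_planted_dmr = 30L,
                       n_planted_dhmr = 30L,
                       effect_log2 = 1.5,
                       hmc_global_factor = 0.7,
                       nb_dispersion = 0.01,
                       base_depth = 60,
                       n_planted_deg = 40L,
                       deg_fold = 3,
                       coupled_fraction = 0.5,
                       expr_base_mean = 200,
                       expr_dispersion = 0.02,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_pairs = as.integer(n_pairs),
              window_size = as.integer(window_size),
              cpg_density = cpg_density,
              n_genes = as.integer(n_genes),
              element_fractions = element_fractions,
              n_planted_dmr = as.integer(n_planted_dmr),
              n_planted_dhmr = as.integer(n_planted_dhmr),
              effect_log2 = effect_log2,
              hmc_global_factor = hmc_global_factor,
              nb_dispersion = nb_dispersion,
              base_depth = base_depth,
              n_planted_deg = as.integer(n_planted_deg),
              deg_fold = deg_fold,
              coupled_fraction = coupled_fraction,
              expr_base_mean = expr_base_mean,
              expr_dispersion = expr_dispersion,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config`
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (n_chromosomes < 1L) stop("need at least one chromosome")
    if (chrom_length <= 0) stop("chrom_length must be positive")
    if (n_pairs < 2L) stop("need at least 2 tumor/normal pairs")
    if (window_size <= 0L) stop("window_size must be positive")
    if (any(element_fractions < 0) || any(element_fractions > 1))
      stop("element fractions must lie in [0, 1]")
    if (sum(element_fractions) > 0.9)
      stop("element fractions sum beyond genome capacity")
    if (hmc_global_factor <= 0 || hmc_global_factor > 1)
      stop("hmc_global_factor must lie in (0, 1]")
    if (nb_dispersion <= 0 || expr_dispersion <= 0)
      stop("dispersions must be positive")
    if (deg_fold <= 1) stop("deg_fold must exceed 1")
    if (coupled_fraction < 0 || coupled_fraction > 1)
      stop("coupled_fraction must lie in [0, 1]")
  })
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "x",
      format(x$chrom_length, big.mark = ","), "bp genome,",
      x$n_pairs, "pairs,", x$window_size, "bp windows\n")
  cat("  planted:", x$n_planted_dmr, "DMRs,", x$n_planted_dhmr, "DhMRs,",
      x$n_planted_deg, "DEGs (coupled fraction",
      x$coupled_fraction, ")\n")
  cat("  5hmC tumor signal factor:", x$hmc_global_factor,
      " seed:", x$seed, "\n")
  invisible(x)
}
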