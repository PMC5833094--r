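# Genome-scale descriptive statistics: chromosome feature/depth
# correlations, composition profiles, the binned 5mC/5hmC regression with
# tumor/normal slope comparison, PCA group separation with a silhouette
# score, and tumor/normal variability comparison.

#' Chromosome feature vs read-depth correlations
#'
#' Pearson correlation (with two-sided p and regression-line coefficients)
#' between each chromosome-scale feature and the mean per-chromosome depth
#' of each sample group.  Constant feature vectors are flagged undefined.
#'
#' @param features data.frame from [chromosome_features()] (column `chrom`
#'   plus numeric feature columns)
#' @param depths chromosomes x samples matrix of mean depth (or RPM);
#'   rownames must match `features$chrom`
#' @param samples sample sheet aligned to `depths` columns (needs `group`,
#'   `assay`)
#' @return tidy data.frame: `feature`, `assay`, `group`, `r`, `p`,
#'   `slope`, `intercept`, `undefined`
#' @export
feature_correlations <- function(features, depths, samples) {
  if (nrow(features) < 3L) stop("need at least 3 chromosomes")
  stopifnot(all(rownames(depths) == features$chrom))
  feat_cols <- setdiff(names(features), "chrom")
  combos <- unique(samples[, c("assay", "group")])
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    idx <- samples$assay == combos$assay[ci] &
      samples$group == combos$group[ci]
    d <- rowMeans(depths[, idx, drop = FALSE])
    for (f in feat_cols) {
      v <- features[[f]]
      if (stats::sd(v) == 0 || stats::sd(d) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, assay = combos$assay[ci], group = combos$group[ci],
          r = NA_real_, p = NA_real_, slope = NA_real_,
          intercept = NA_real_, undefined = TRUE, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(v, d)
      fit <- stats::lm(d ~ v)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, assay = combos$assay[ci], group = combos$group[ci],
        r = unname(ct$estimate), p = ct$p.value,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        undefined = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Modification level against window composition
#'
#' Mean RPM per fixed-width GC-content bin (5 percentage points) and per
#' CpG observed/expected bin (0.05), per sample.  Bins holding fewer than
#' `min_windows` windows are flagged.
#'
#' @param track a `track_matrix` with composition-annotated windows
#' @param min_windows flag threshold (default 10)
#' @return list of two data.frames (`gc`, `cpg_oe`), each long-format:
#'   `bin_lo`, `bin_mid`, `n_windows`, `flagged`, `sample`, `mean_rpm`
#' @export
composition_profile <- function(track, min_windows = 10L) {
  mk <- function(values, width) {
    lo <- floor(values / width) * width
    levs <- sort(unique(lo))
    n <- as.integer(table(factor(lo, levels = levs)))
    base <- data.frame(bin_lo = levs, bin_mid = levs + width / 2,
                       n_windows = n, flagged = n < min_windows)
    long <- do.call(rbind, lapply(colnames(track$rpm), function(s) {
      mean_rpm <- as.numeric(tapply(track$rpm[, s], factor(lo, levels = levs),
                                    mean))
      cbind(base, data.frame(sample = s, mean_rpm = mean_rpm,
                             stringsAsFactors = FALSE))
    }))
    rownames(long) <- NULL
    long
  }
  list(gc = mk(S4Vectors::mcols(track$windows)$gc, 0.05),
       cpg_oe = mk(S4Vectors::mcols(track$windows)$cpg_oe, 0.05))
}

#' Binned 5mC/5hmC regression per group
#'
#' Windows are ranked by group-mean 5mC RPM and partitioned into
#' `n_classes` equal-size level classes; the class means of 5mC and 5hmC
#' give one point per class, over which Pearson r and the OLS slope are
#' fitted.  The tumor-vs-normal slope contrast quantifies a global loss of
#' the 5hmC response to methylation level.
#'
#' @param track_5mC,track_5hmC `track_matrix` objects over the same windows
#' @param group `"tumor"`, `"normal"` or `NULL` for both
#' @param n_classes number of rank classes (default 20)
#' @return for a single group: list with `class_means` (data.frame `class`,
#'   `mc`, `hmc`), `r`, `p`, `slope`, `intercept`; for `NULL`, a named list
#'   of both groups
#' @export
mc_hmc_regression <- function(track_5mC, track_5hmC, group = NULL,
                              n_classes = 20L) {
  if (is.null(group)) {
    return(list(normal = mc_hmc_regression(track_5mC, track_5hmC, "normal",
                                           n_classes),
                tumor = mc_hmc_regression(track_5mC, track_5hmC, "tumor",
                                          n_classes)))
  }
  if (nrow(track_5mC$rpm) < n_classes)
    stop("fewer windows than level classes")
  mi <- track_5mC$samples$group == group
  hi <- track_5hmC$samples$group == group
  mc <- rowMeans(track_5mC$rpm[, mi, drop = FALSE])
  hmc <- rowMeans(track_5hmC$rpm[, hi, drop = FALSE])
  rk <- rank(mc, ties.method = "first")
  cls <- ceiling(rk * n_classes / length(mc))
  cm <- data.frame(class = seq_len(n_classes),
                   mc = as.numeric(tapply(mc, cls, mean)),
                   hmc = as.numeric(tapply(hmc, cls, mean)))
  fit <- stats::lm(hmc ~ mc, data = cm)
  ct <- stats::cor.test(cm$mc, cm$hmc)
  list(group = group, class_means = cm, r = unname(ct$estimate),
       p = ct$p.value, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' PCA group separation of a modification track
#'
#' PCA of the samples (observations) over window RPM (variables,
#' column-centered); windows with zero RPM in every sample are dropped.
#' Group separation is summarized as the mean silhouette width of the
#' tumor/normal labels over the first two principal components.
#'
#' @param track a `track_matrix` with >= 4 samples, >= 2 per group
#' @return list with `scores` (samples x components), `explained_variance`
#'   (non-increasing fractions), `silhouette` (mean over samples),
#'   `groups`
#' @export
pca_separation <- function(track) {
  samples <- track$samples
  if (ncol(track$rpm) < 4L) stop("need at least 4 samples")
  if (any(table(samples$group) < 2L)) stop("need >= 2 samples per group")
  X <- t(track$rpm)
  keep <- colSums(X) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L || all(apply(X, 2, stats::sd) == 0))
    stop("constant RPM matrix: PCA undefined")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  pos <- pr$sdev > 1e-12
  scores <- pr$x[, pos, drop = FALSE]
  ev <- pr$sdev[pos]^2 / sum(pr$sdev^2)
  labels <- as.integer(factor(samples$group))
  k <- min(2L, ncol(scores))
  sil <- cluster::silhouette(labels, stats::dist(scores[, seq_len(k),
                                                        drop = FALSE]))
  list(scores = scores, explained_variance = ev,
       silhouette = mean(sil[, "sil_width"]),
       groups = samples$group, loadings = pr$rotation[, pos, drop = FALSE],
       center = pr$center, kept_windows = which(keep))
}

#' Compare tumor and normal profile variability
#'
#' Paired two-sided t-test across metaprofile bins of the per-bin
#' across-sample SD of the tumor group against the normal group.
#' Identical SD profiles return p = 1 (degenerate convention).
#'
#' @param sd_tumor,sd_normal per-bin SD vectors of equal length (>= 3)
#' @return list with `p`, `mean_sd_tumor`, `mean_sd_normal`
#' @export
variability_compare <- function(sd_tumor, sd_normal) {
  if (length(sd_tumor) != length(sd_normal)) stop("unequal bin counts")
  if (length(sd_tumor) < 3L) stop("need at least 3 bins")
  list(p = .paired_t_p(sd_tumor, sd_normal),
       mean_sd_tumor = mean(sd_tumor),
       mean_sd_normal = mean(sd_normal))
}
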