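---
title: "Methods: integrative 5mC/5hmC/expression analysis of paired tumor/normal designs"
author: "episcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative 5mC/5hmC/expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Colorectal tumors differ from matched normal mucosa in both DNA
methylation (5mC) and hydroxymethylation (5hmC). Enrichment sequencing
(MeDIP-seq / hMeDIP-seq) measures these marks as fragment pile-ups, not
base-resolution calls, so all downstream statistics operate on
fragment counts in fixed genomic windows, normalized to reads per million
(RPM). This package implements the full analysis chain for a paired
design — six patients, tumor and adjacent normal tissue, both assays,
plus RNA-seq — and a synthetic-data generator that stands in for the
patient data (which are not public) with planted, recoverable truth.

The chain: window quantification → groupwise sliding-window differential
region calling (DMRs/DhMRs) → Audic–Claverie differential expression with
consensus calling across pairs → genome-scale pattern statistics → a
directional multi-omics screen for candidate epigenetically repressed
genes (promoter hyper-5mC + promoter hypo-5hmC + down-regulation, the
tumor-suppressor signature; the mirror image flags "activated" genes).

# The generative model

Each window `w` of a sample in assay `a` and group `g` receives a
negative-binomial fragment count with mean

```
mu(w) = base_depth * widthfrac(w) * signal_a,g(w)
        * 2^(+-effect_log2, planted regions, tumor only)
        * depth_factor(sample)
```

and variance `mu + phi mu^2`. The signal term is element-driven:

* 5mC: `max(0.1, 1 + 0.5 repeat + 0.3 genebody − 0.5 CGI)` — methylation
  enriched in repeats and gene bodies, depleted at CpG islands;
* 5hmC: `0.3 + 1.5 genebody + 2.5 enhancer + 0.8 CGI` — a small
  immunoprecipitation background plus enrichment where
  hydroxymethylation resides,

with each term the window's overlap fraction with that element class.

**Tumor 5hmC depletion.** The global tumor hydroxymethylation loss is
applied to the *enrichment component only*:
`0.3 + hmc_global_factor × (signal − 0.3)`. This is deliberate. RPM is
scale-invariant: multiplying *every* window of a sample by a constant
changes the library size by the same constant and leaves RPM untouched,
so a uniform depletion would be unobservable in any RPM-based statistic.
A genuine loss of the mark is loss where the mark is — enriched regions
lose coverage share, background gains it after renormalization. This is
what makes the depletion visible as (i) a tumor-vs-normal PCA separation
of the 5hmC windows, (ii) a flattened tumor slope in the binned
5hmC-versus-5mC regression, and (iii) an excess of genic hypo-DhMRs with
a background drift toward hyper. The default factor is 0.7, the regime in
which the tumor/normal slope ratio lands near the 0.7–0.8 range typical
of a strong global 5hmC loss.

**Fragments.** Fragment lengths are ~N(200, 20) bp (sonication to a mean
fragment size of 200 bp), midpoints uniform within the generating window,
so midpoint counting reproduces the drawn counts exactly — tested, and
exploited: repeated-simulation studies can skip fragment materialization
(`fragments = FALSE`) without changing any count.

**Planted truth.** Half of the planted DMRs are promoter-anchored hyper
regions (restricted to the contiguous CpG-eligible window run around the
TSS so every planted region is detectable by design); a configurable
fraction of those are *coupled*: the same promoter also gets a hypo-5hmC
region and the gene a down-regulated expression fold. Remaining regions
are random two-window plants of random direction, placed only in
CpG-eligible windows that do not touch any promoter; planted non-coupled
DEGs avoid genes carrying planted promoter regions. These exclusions make
the screen's ground truth identifiable — without them, "exact recovery of
the coupled set" would be ill-posed whenever a random plant landed in a
promoter by chance.

**Expression.** Gene baselines are log-normal around `expr_base_mean`
(planted genes floored at half that, again for detectability), library
factors log-normal (sd 0.15), counts negative-binomial. Coupling is
implemented at the generative level through shared gene labels, not via a
mechanistic methylation→expression model: the pipeline only claims to
recover associations.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `window_size` | 500 | bp | analysis resolution of the emulated design |
| `n_pairs` | 6 | patients | the emulated paired cohort |
| `base_depth` | 60 | fragments/window | with `nb_dispersion` 0.01 gives log2(RPM+1) SD ≈ 0.23, a realistic enrichment noise level at which the region caller is both calibrated and powered |
| `nb_dispersion` | 0.01 | — | overdispersion typical of good-quality enrichment libraries |
| `effect_log2` | 1.5 | log2 | planted region effect; ~3-fold, comfortably above noise |
| `hmc_global_factor` | 0.7 | — | global tumor 5hmC signal loss (see above) |
| `min_cpg` | 5 | sites/window | CpG support filter for testable windows |
| `alpha` | 0.05 | — | per-window threshold for region calling, unadjusted (BH q-values are reported alongside) |
| `step` | `window/2` | bp | sliding-window step; half-overlap balances resolution and multiplicity |
| DEG rule | q ≤ 0.05, \|log2\| ≥ 0.585, ≥ 4 pairs | — | 0.585 = log2(1.5), so the FDR/ratio rule and the "fold > 1.5 in ≥ 4 samples" rule coincide |
| promoter | TSS ± 500 | bp | the single promoter convention used everywhere (mapping, screen, correlations) |
| CGI shore | 2000 | bp | field convention for island flanks, CGI-subtracted |
| metaprofile | 4 kb / 80 bins | — | 50-bp bins across TSS/TES |
| slope classes | 20 | — | equal-size rank classes of group-mean 5mC avoid empty classes |

# Statistical choices

* **Window test.** Two-sided paired t-test on `log2(RPM + 1)` across
  patients. The design is six matched pairs; a paired location test on the
  log scale is the natural groupwise statistic, and at the generator's
  noise level it is calibrated (measured type-I error 0.048–0.050 at
  α = 0.05). Pseudocount 1 keeps zero-count windows finite. Degenerate
  windows (all paired differences exactly zero) return p = 1 with no
  direction; this degenerate-difference convention applies to every paired
  test in the package.
* **Calibration is measured on the non-overlapping grid.** The exact
  binomial interval used to check the caller's type-I error presumes
  independent tests; half-overlapping sliding windows share fragments and
  would inflate the variance of the measured rate without biasing it.
  Region *calling* still uses the sliding grid.
* **Audic–Claverie.** The point probability
  `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))` is accumulated
  in log-gamma space. Two-sided p doubles the smaller tail (observed
  point included in both), capped at 1. When the lower tail exceeds 0.5
  the upper tail is summed forward from `y` directly, which avoids the
  catastrophic cancellation of computing a tiny tail as `1 − (1 − ε)`.
  Note the doubled-tail p is *not* invariant under swapping the two
  samples (the tails condition on `x`); the invariances that do hold —
  point-probability symmetry at equal libraries, dependence on libraries
  only through their ratio — are asserted in the tests.
* **FDR.** Benjamini–Hochberg within each pair across genes (and across
  windows for the reported region q-values).
* **log2 expression ratios** use RPKM + 0.1 on both sides: finite for
  zero counts without masking large effects.
* **PCA separation.** Samples are observations over column-centered
  window RPM; all-zero windows are dropped (no variance, dominate sparse
  matrices). "Clear separation" is quantified as the mean silhouette of
  the tumor/normal labels over the first two PCs — a single reproducible
  number in [−1, 1].
* **Element O/E.** Expected = regions × element genome fraction. Under
  uniform placement of finite-width regions the expected O/E of *small*
  elements sits above 1 (a 1-kb region overlaps a 1-kb island whenever
  their starts are within 2 kb), so null envelopes are built by
  permutation of placements rather than assumed to center at 1.
* **Screen coherence.** A candidate needs all three directions coherent
  (hyper-5mC, hypo-5hmC, down — or the mirror). Genes with mixed-direction
  promoter evidence within one assay are flagged ambiguous and excluded;
  the relaxed two-way intersections are reported alongside for
  transparency.

# What the generator does and does not emulate

It emulates: the paired groupwise design; element-structured enrichment;
overdispersed counts; library-size variation; a global, signal-targeted
5hmC loss; promoter-coupled repression. It does not emulate: base
sequence (GC content and CpG O/E are a deterministic monotone proxy of
local CpG density — adequate for binning, not a sequence model); copy
number, batch, or tumor-purity effects; distance-decay correlation of
methylation; transcript isoforms (one transcript per gene, "longest" =
the only one). Passing recovery tests therefore demonstrates the
pipeline's statistical correctness under a faithful abstraction of the
design, not robustness to every artifact of real libraries.

# Problem sizes

Unit and property tests run on 2 × 300 kb to 2 × 1 Mb genomes with the
default depth; the caller-calibration study uses 2 × 5 Mb (≈ 11,000
eligible windows, which makes the exact binomial 99% band ± 0.005 around
0.05 — tight enough to detect real miscalibration); the 20-seed PCA and
slope contrasts use 2 × 500 kb. These sizes were chosen so the whole
suite exercises every code path at full statistical fidelity while
staying desk-scale.

# Known limitations

* The window statistic is a documented stand-in for the original study's
  unpublished region caller; with n = 6 pairs the t-test is adequate but
  rank-based alternatives would be preferable for heavier-tailed noise.
* Unadjusted α = 0.05 region calling (the emulated convention) implies
  many single-window false regions on null data; consumers who need FDR
  control should filter on the reported q-values.
* Real-data mode expects fragments as BED3 per sample; BAM ingestion is
  out of scope.
* GC/CpG-O/E composition profiles reflect the synthetic proxy unless the
  user supplies windows annotated from real sequence.
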