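# episcreen

Integrative analysis of DNA methylation (5mC, MeDIP-seq),
hydroxymethylation (5hmC, hMeDIP-seq) and gene expression (RNA-seq) for
paired tumor/normal designs, with a synthetic-data generator that makes
every stage testable against planted truth.

## Who this is for

Epigenomics analysts working with enrichment-based methylome and
hydroxymethylome data from matched tumor/normal cohorts, who need a
tested, deterministic pipeline from aligned fragments to a ranked list of
candidate epigenetically repressed genes — and a way to validate that
pipeline end-to-end without access to patient data.

## What it computes

* **Window quantification** — the genome is tiled into 0.5-kb windows;
  fragments are assigned by midpoint and normalized to
  `RPM = count × 10⁶ / library size`. Per-element aggregation, CpG
  coverage curves, and anchored TSS/TES metaprofiles (4 kb, 80 bins).
* **DMR/DhMR calling** — sliding windows (step = window/2), two-sided
  paired t-test on `log2(RPM + 1)` across patients, restricted to windows
  with ≥ 5 CpG sites; windows significant at p < 0.05 with the same
  direction merge into regions (`hyper` = gain in tumor). BH q-values are
  reported alongside.
* **Differential expression** — `RPKM = count × 10⁹ / (library × length)`;
  per-pair Audic–Claverie exact test

  `p(y|x) = (N₂/N₁)^y (x+y)! / ( x! y! (1+N₂/N₁)^(x+y+1) )`,

  two-sided by doubled smaller tail, BH-adjusted within pair; a gene is a
  DEG when q ≤ 0.05 and |log₂ ratio| ≥ 0.585 (fold 1.5) with the same
  sign in ≥ 4 of 6 pairs.
* **Global patterns** — PCA of samples over window RPM with
  silhouette-scored tumor/normal separation; the binned (20 rank classes)
  5hmC-versus-5mC regression whose tumor/normal slope contrast quantifies
  global 5hmC loss; profile-variability comparison; chromosome
  feature/depth correlations.
* **Integration** — DMRs/DhMRs mapped to promoters (TSS ± 500 bp,
  strand-aware); Spearman correlation of expression with promoter and
  gene-body modification; the directional screen: promoter hyper-5mC +
  promoter hypo-5hmC + down-DEG ⇒ candidate repressed (tumor-suppressor
  signature), with the mirror image flagged activated; generic Fisher
  over-representation testing of the resulting gene list.
* **Synthetic study generator** — six tumor/normal pairs × two assays as
  negative-binomial fragment tracks over an annotated synthetic genome,
  with planted DMRs/DhMRs, a global tumor 5hmC signal depletion, an
  expression matrix with planted DEGs, and promoter-coupled repressed
  genes; every planted effect is recorded in a truth table for recovery
  scoring.

## Worked example

```r
library(episcreen)
cfg <- run_config(mode = "simulate",
                  sim = sim_config(chrom_length = 5e5, n_genes = 80,
                                   n_planted_dmr = 12, n_planted_dhmr = 12,
                                   n_planted_deg = 12),
                  out_dir = file.path(tempdir(), "demo"), seed = 42)
rep <- run_all(cfg)
print(rep)
```

```
episcreen run (mode=simulate seed=42)
simulated 24 fragment tracks over 2 x 500000 bp
planted regions: 24; planted DEGs: 12; coupled genes: 3
tiled 2000 windows (+4000 sliding windows, step 250)
5mC: 1834740 fragments counted, 0 skipped
5hmC: 1557967 fragments counted, 0 skipped
5mC: 2285 eligible windows, 186 significant, 126 DMRs (52 hyper/74 hypo)
5hmC: 2285 eligible windows, 380 significant, 229 DHMRs (163 hyper/66 hypo)
expression: 80/80 genes matched to annotation
DEGs called: 12 (6 up / 6 down) of 80 genes
silhouette 5mC=0.737 5hmC=0.676; slope normal=1.822 tumor=1.242
promoter hits: 16 genes (5mC), 22 genes (5hmC); candidates: 3
recovery: DMR sens=1.000 DhMR sens=1.000 DEG recall=1.000 screen_exact=1
```

Reading the log: all 24 planted regions and all 12 planted DEGs were
recovered; the tumor slope (1.242) sits well below the normal slope
(1.822), the signature of the simulated global 5hmC depletion; and the
screen returned exactly the 3 planted coupled genes:

```r
rep$screen$candidates
#>   gene_id dmr_direction dhmr_direction deg_direction     class        deg_q
#> 1   G0048         hyper           hypo          down repressed 8.551229e-48
#> 2   G0063         hyper           hypo          down repressed 1.810293e-08
#> 3   G0036         hyper           hypo          down repressed 3.608393e-08
```

All outputs (windows BED, RPM matrices, DMR/DhMR tables and BED6 tracks,
DEG table, candidate table, truth-recovery report, run log) are written
under `out_dir`; two runs with the same configuration and seed are
byte-identical.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/06_integration.R` walk the full
study — simulation, quantification, region calling, differential
expression, global patterns, integration — each a thin narrative driver
over the package functions, writing summary tables under
`results/analysis/`. They share one deterministic configuration
(`analysis/config.R`) and can be run in any order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_differential_regions.R   # etc.
```

## Vignette

`vignettes/methods.Rmd` documents the generative model (and why the
tumor 5hmC depletion acts on the enrichment signal rather than uniformly),
every tunable parameter with its default and rationale, the statistical
conventions (degenerate paired tests, pseudocounts, tail handling in the
exact test), and what passing the recovery tests does — and does not —
say about real data.
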