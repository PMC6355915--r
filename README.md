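# polpause

Quantitative analysis of RNA polymerase II promoter-proximal pausing from
genomic coverage tracks, for labs studying transcriptional regulation with
spike-in-calibrated ChIP-seq and nascent-RNA (4sU/DRB) sequencing.

Pol II frequently pauses 20–60 nt downstream of the transcription start
site (TSS) before release into productive elongation. `polpause`
implements the estimators this kind of study runs genome-wide:

* **Pol II release ratio (PRR).** With the TSS window `TSS ± 250 bp` and
  the gene body `TSS + 500 bp … TES − 500 bp` (strand-aware),

  `PRR = log2( mean body enrichment / mean TSS-window enrichment )`

  Low PRR = strong pausing; high PRR = efficient release. Computed per gene
  on input-normalized linear enrichment (ChIP) or nascent coverage (4sU),
  with condition comparisons by two-sample Kolmogorov–Smirnov test, quartile
  and intron-size stratification (one-way ANOVA), bound-vs-unbound window
  changes (Welch t), and change-vs-change Pearson correlation.
* **Spike-in calibration.** `factor = spike-in reads per million
  experimental-genome reads`; all libraries (IP and input alike) are divided
  by their factor, making occupancy comparable across conditions.
* **Elongation rates from DRB/4sU wave fronts.** Genes > 10 kb are binned
  at 100 bp over 20 kb downstream of the TSS; the nascent-signal wave front
  is detected per timepoint (smoothed local-minimum rule with half-height
  refinement) and the rate is `(front(8 min) − front(2 min)) / 6 min`.
* **Metagene profiles** (scaled gene body with fixed flanks, TSS-centered,
  occupancy-sorted heatmap matrices) with per-position SEM across genes.
* **Peak-to-gene target assignment**: 2.0-fold enrichment cutoff, nearest
  TSS to the peak summit, multi-factor bound-set intersection, and Fisher
  exact class-enrichment tests (expression quartiles, intron-size classes).
* **A deterministic synthetic-data generator** producing gene annotations,
  spike-in ChIP tracks with known expected PRR per gene, DRB timecourses
  with known wave fronts, and narrowPeak files with a planted bound set —
  so the whole pipeline is testable end to end without external data.

Standard formats are supported throughout: bedGraph, BED12, GTF, ENCODE
narrowPeak, contig-sizes and RPKM/stats TSVs.

## A worked example

Simulate a two-condition study in which the perturbation halves the
promoter peak (reduced pausing), then measure it:

```r
library(polpause)

cfg <- sim_config(n_genes = 300, genome_length = 1.2e7, seed = 42)
sim <- simulate_genes(cfg)

chip_c <- simulate_chip(sim, cfg, "control")
chip_k <- simulate_chip(sim, cfg, "knockdown")

prr_c <- prr_table(ratio_normalize(chip_c$ip, chip_c$input), sim$genes,
                   condition = "control")
prr_k <- prr_table(ratio_normalize(chip_k$ip, chip_k$input), sim$genes,
                   condition = "knockdown")
prr_compare(prr_c, prr_k)[c("statistic", "p_value", "n")]
#> $statistic
#> [1] 0.5302013
#> $p_value
#> [1] 0
#> $n
#> [1] 298

median(prr_k$prr - prr_c$prr, na.rm = TRUE)
#> [1] 0.663424
```

The KS statistic D ≈ 0.53 over 298 eligible genes (p below numerical
resolution) and the upward median PRR shift (~+0.66 log2 units) say the
knockdown condition releases Pol II
into gene bodies much more readily — exactly the planted effect. The
elongation rate, in contrast, is recovered at its simulated 1 kb/min in
both conditions:

```r
drb <- simulate_drb_timecourse(sim$genes, cfg)
gw <- genomewide_rates(drb$tracks$t2, drb$tracks$t8, sim$genes)
c(mean = gw$mean_rate, median = gw$median_rate, n = gw$n_ok)
#>   mean median      n 
#>   1000   1000    114
```

See `vignettes/pol2-pausing-analysis.Rmd` for the model, parameter and
design details.

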