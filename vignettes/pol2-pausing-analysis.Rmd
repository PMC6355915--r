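---
title: "Quantifying Pol II promoter-proximal pausing with polpause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Pol II promoter-proximal pausing with polpause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpause)
```

## The biology and the statistic

RNA polymerase II frequently stalls 20–60 nt downstream of the transcription
start site (TSS) before being released into productive elongation. The degree
of this promoter-proximal pausing is summarized here by the **Pol II release
ratio (PRR)**: for each gene the TSS region is the window from 250 bp upstream
to 250 bp downstream of the TSS, the gene body runs from 500 bp downstream of
the TSS to 500 bp upstream of the transcription end site (TES), and

$$\mathrm{PRR} = \log_2\frac{\text{mean body enrichment}}
                            {\text{mean TSS-window enrichment}}.$$

A low PRR indicates strong pausing (signal concentrated at the promoter), a
high PRR indicates efficient release. Genes shorter than the combined window
requirements are excluded rather than scored. For genes with several annotated
transcript starts, the TSS with the highest mean control-condition signal in
its ±250 bp window is selected once and reused for every condition
(`select_tss()`); exact ties break to the 5′-most candidate so the choice is
deterministic.

PRR is computed on **linear-scale** signal — the IP/input ratio for ChIP-seq
(`ratio_normalize()`), or nascent 4sU coverage (against the t0 library) — and
window means are floored at 0.01 signal units before the log ratio so that
genes with signal in only one window stay finite; genes at the floor in both
windows are dropped as "no signal". Because PRR is a ratio of means on the
same track, it is invariant to any global rescaling of the track, in
particular to the spike-in calibration factor.

## Spike-in calibration

Libraries carrying a foreign-genome spike-in are calibrated with the factor

$$f = \frac{\text{reads mapped to the spike-in genome}}
           {\text{reads mapped to the experimental genome} / 10^6},$$

and every signal value is divided by $f$ (`spikein_factor()`,
`calibrate_track()`), for IP and input libraries alike. Two practical points
are worth stating explicitly:

* At a fixed spike-in chromatin fraction, $f$ is invariant to sequencing
  depth. Depth normalization must therefore happen on the tracks themselves;
  the package follows standard track-building practice and works with
  per-million-reads-scaled coverage, after which calibrated signal is
  invariant to depth changes and the factor corrects for IP-efficiency and
  global-occupancy differences between conditions.
* A set of libraries is only calibrated *relative to each other*; the overall
  scale is arbitrary. `calibrate_libraries()` therefore divides each track by
  its own factor and rescales the whole set by the geometric mean of the
  factors. Cross-library ratios — enrichment, PRR, window changes — are
  unchanged by the shared constant, but signal values keep their original
  magnitude, so fixed pseudocounts and floors stated in signal units remain
  meaningful.

Enrichment tracks use a symmetric pseudocount (default 0.01 signal units):
`log2((ip + p)/(input + p))`, which keeps the result finite and exactly
antisymmetric under swapping IP and input. Enrichment is computed on 10 bp
bins by default (matching common track-building practice and bounding
memory); per-base mode (`bin_width = 1`) is retained and is the reference
for the oracle tests.

## Wave-front detection and elongation rates

In the DRB/4sU design, transcription is synchronized with the pausing
inhibitor DRB; after its removal nascent transcription restarts and the
labeled-signal edge (the *wave front*) advances at the elongation rate. Genes
longer than 10 kb are divided into 100 bp bins over 20 kb downstream of the
TSS (bins past the TES are masked), and the front is located on the smoothed
profile (5-bin centered rolling mean):

1. enumerate interior local minima and keep those within 5% of the global
   minimum (relative to the signal range) — the most upstream of these
   anchors the background floor just downstream of the front;
2. walk upstream from that anchor to the **half-height crossing**, the first
   bin whose smoothed value still lies below the midpoint between floor and
   peak. That bin's center is the front.

The half-height refinement matters: the first-floor-bin reading of the rule
lands at the *end* of the front's transition (and a smooth decaying profile
has no interior local minimum at all before numerical flatness), biasing
fronts several hundred bp downstream. The half-height crossing reproduces
the plateau/floor boundary of a noiseless step exactly and is an unbiased
estimator of the center of a logistic edge under Poisson noise. Profiles
whose smoothed minimum never drops below half the maximum have no resolved
floor — the front lies beyond the analyzed window — and are flagged instead
of scored. Smoothing width and floor tolerance are arguments
(`detect_wavefront()`), not constants.

The per-gene elongation rate is the distance covered by the front between
2 min and 8 min after DRB removal divided by the 6 min interval
(`elongation_rate()`, `genomewide_rates()`). Fronts that regress between
timepoints are flagged and excluded. Because the field does not dictate
whether per-gene rates should be averaged or pooled, both the mean and the
median across genes are reported. Other timepoints (0 and 16 min exist in
such designs) are accepted by the simulator and the binning code, but the
headline rate uses the 2→8 min pair.

## Metagene profiles and heatmaps

`scaled_metagene()` places every gene on a common frame: 600 bp upstream of
the TSS at base resolution, the body rescaled to 100 bins by mean pooling
over equal-occupancy windows, 600 bp downstream of the TES; the profile
reports the mean and the standard error of the mean across genes per
position. SEM is computed across genes per position (not across replicates);
averaging replicate tracks first and profiling the average is the supported
way to combine replicates. `tss_centered_profile()` is the fixed ±1 kb
variant, and `tss_heatmap_matrix()` produces a genes × positions matrix
sorted by decreasing TSS occupancy of a sorting track with a deterministic
gene-id tie-break. Flanks that run off the covered region read as zero and
the gene is kept (an explicit drop would bias short contigs in compact
simulated genomes).

On the minus strand, downstream offset $o$ maps to base $\mathrm{TSS}-1-o$,
so plus- and minus-strand placements mirror each other exactly; all windows
in the package share this convention.

## Target assignment and set statistics

Peak calls (narrowPeak) are filtered at a 2.0-fold enrichment cutoff applied
as a post-filter on the fold-enrichment column, then each peak is assigned to
the gene whose TSS is nearest the peak summit. Distance is summit-to-TSS
(not summit-to-gene-body) because the binding being modelled is
promoter-centric; summits exactly equidistant between two TSSs are assigned
to both genes rather than dropped, and both choices are documented behavior.
A factor's bound set is the assigned genes; the conjunction of several
factors (e.g. the three pre-EJC core components) is their intersection
(`intersect_bound()`), reported with pairwise overlaps and the union
fraction.

Bound-set composition is tested per class of a gene partition (expression
quartiles, largest-intron size classes) with a two-sided Fisher's exact test
on the bound/unbound × in/out-of-class table (`class_enrichment()`).
Stratified condition comparisons use: quartile splits of a reference value
with boundary ties assigned to the lower quartile (`quartile_stratify()`);
one-way ANOVA across largest-intron classes (`intron_class_stratify()` —
intron class breakpoints are not canonical, so the package takes explicit
breaks, with reference-quartile breaks as the natural default choice);
Welch's unequal-variance t-test for bound-vs-unbound window changes
(`window_change_test()` — "two-sample t-test" is underspecified, and Welch
is the safer default); and the two-sample Kolmogorov–Smirnov test for PRR
distribution shifts (`prr_compare()`, asymptotic p for n ≥ 30 per sample,
exact below). A "Pol II bound" gene universe, where needed, defaults to mean
TSS-window enrichment > 1.3 in the control condition
(`pausing_index_bound()`) — the same strict threshold used for
pausing-index re-analyses — and is configurable.

## What the synthetic data emulates

`sim_config()` fixes the simulated study conditions; every `simulate_*`
output is byte-identical for a fixed seed.

* **Genes** (`simulate_genes()`): non-overlapping, strand-randomized genes
  with log-normal lengths (meanlog 9, sdlog 0.8 in log-bp, or a requested
  fraction of genes over 10 kb), log-normal intron sizes populating the
  largest-intron classes, and a designated bound subset (30%) recorded as
  ground truth. A per-gene pause-strength multiplier (log-normal, mean 1,
  sdlog 0.5) is drawn once and shared across conditions, so genes differ in
  how strongly they pause — as real genes do — while conditions differ only
  by their global pause scale.
* **ChIP** (`simulate_chip()`): expected IP coverage is a Gaussian promoter
  peak (sd 100 bp, height `pause_strength` × multiplier counts/bp) over a
  gene-body plateau (2 counts/bp, extended 250 bp upstream of the TSS so
  promoter occupancy fills the whole TSS window; with zero pause strength
  the expected PRR is exactly 0 by construction) plus background
  (0.2 counts/bp); the input is flat. Counts are Poisson on 10 bp bins —
  preserving the statistics the estimators consume at a fraction of the
  cost of read-level simulation — and tracks are emitted per-million-scaled.
  Spike-in reads are Poisson with mean `spike_fraction × depth` (5% of 10⁶
  by default). The truth table carries each gene's expected PRR computed
  analytically from the expectation profile. The default condition pair
  (`control` pause 16, `knockdown` 8 counts/bp) encodes a
  halving of the promoter peak at unchanged body signal.
* **DRB timecourse** (`simulate_drb_timecourse()`): at `t` minutes the
  expected nascent signal is a plateau (5 counts/bp ≙ 50 counts per 100 bp
  bin) out to `rate × t` bp downstream of the TSS — 1 kb/min by default, the
  elongation rate reported for Drosophila S2 cells — decaying to background
  through a logistic edge of scale 50 bp (the transition spans about two
  100 bp bins), so the detector faces a realistic rather than degenerate
  profile. Timepoints default to 0/2/8/16 min.
* **Peaks** (`simulate_peaks()`): one peak per bound gene, summit jittered
  N(TSS, 50 bp), fold enrichment above the 2.0 cutoff, plus optional
  sub-cutoff decoys.

What the generator does **not** emulate: read-level artifacts (duplicates,
mappability, GC bias), replicate structure, the real genome's gene density
and overlapping transcription, RNA half-life and labeling kinetics in the
4sU signal, and peak-caller behavior. Passing tests therefore demonstrate
that the estimators are correct and well-calibrated for the signal model
they assume, not that they are robust to every artifact of real libraries.

## Numerical choices and problem sizes

Window means treat uncovered bases as zero and are computed by exact
cumulative sums over the run-length encoding, so binned and per-base modes
agree with a dense-array oracle to machine precision. Wave-front threshold
comparisons are performed on the range-normalized profile with a 10⁻⁹ slack,
making detection exactly invariant under positive rescaling of the track.
The test-suite and acceptance problem sizes — 500 genes for the PRR
condition comparison (100 simulated experiments), 200 genes per elongation
rate in {0.5, 1, 2} kb/min, exhaustive 2×2 tables up to total size 20 —
were chosen as the smallest sizes at which the measured properties are
stable, and run in a few minutes on one CPU.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 300, genome_length = 1.2e7, seed = 42)
sim <- simulate_genes(cfg)

chip_c <- simulate_chip(sim, cfg, "control")
chip_k <- simulate_chip(sim, cfg, "knockdown")

cal <- calibrate_libraries(
  list(ip = chip_c$ip, input = chip_c$input),
  list(ip = chip_c$stats_ip, input = chip_c$stats_input))
ratio_c <- ratio_normalize(cal$ip, cal$input)

prr_c <- prr_table(ratio_c, sim$genes, condition = "control")
prr_k <- prr_table(ratio_normalize(chip_k$ip, chip_k$input), sim$genes,
                   condition = "knockdown")
prr_compare(prr_c, prr_k)[c("statistic", "p_value", "n")]

drb <- simulate_drb_timecourse(sim$genes, cfg)
genomewide_rates(drb$tracks$t2, drb$tracks$t8, sim$genes)$mean_rate
```

## Known limitations

* The bedGraph reader targets well-formed 4-column files; bigWig input is
  out of scope (convert externally).
* `prr_compare()` uses the asymptotic KS p-value for n ≥ 30 per sample;
  heavily tied PRR values (possible with floored signals) make the KS test
  conservative.
* The wave-front detector assumes a single front per gene; convergent or
  internal initiation produces multi-modal profiles it will not resolve.
* Gene-ID namespaces are taken at face value: annotation, RPKM tables and
  peak assignments must share identifiers.
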