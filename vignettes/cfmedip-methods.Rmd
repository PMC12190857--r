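---
title: "Methods: differential methylation analysis of cfMeDIP-seq bin counts"
author: "cfmedip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation analysis of cfMeDIP-seq bin counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

cfMeDIP-seq immunoprecipitates methylated cell-free DNA fragments and
sequences them. After alignment and deduplication, the signal is an
abundance measure: the number of fragments falling in each fixed genomic
window reflects the amount of methylated DNA originating there, not a
per-CpG methylation fraction. `cfmedip` works from exactly this
representation — a matrix of non-negative integer counts over 300-bp
non-overlapping bins (the field-standard window size) by samples, with a
sample sheet assigning each library to a diagnostic group (OC, benign,
healthy) or to the peripheral-blood-leukocyte (PBL) background panel.

Coordinates are 0-based half-open internally (the BED convention) for all
interval arithmetic; report tables echo 1-based inclusive start/stop pairs,
which is how published region tables are printed. The two
conventions round-trip losslessly through `from_one_based()` /
`to_one_based()`. Each chromosome is tiled left to right; the final bin is
truncated at the chromosome end and kept, so the tiling always covers every
base pair. (Whether a windowing tool should drop or truncate the remainder
is not standardized; truncation is this package's choice, made for tiling
completeness.)

Fragments are counted into the single bin containing their midpoint
`floor((start + end)/2)`. This conserves totals — a column sums to the
number of fragments — and avoids the ambiguity of per-overlap increments
for fragments spanning a bin boundary.

## The filtering cascade

Four bin filters run in a fixed order before testing, each with a strict
boundary:

1. **Blacklist** — any bin sharing ≥ 1 bp with an artifact region is
   removed.
2. **PBL background** — a bin is removed if *any* PBL sample has strictly
   more than 20 reads there. PBLs dominate circulating cfDNA, so
   leukocyte-high regions mostly reflect hematopoietic background rather
   than tumor signal. The rule's literal reading ("a PBL sample exceeds
   20") is ambiguous between any-sample and mean-based; we implement the
   any-sample form as the strictest background removal, and the stage
   function accepts any count matrix so a mean-based variant is a one-line
   wrapper.
3. **Low total** — bins with total count strictly below 10 across the
   cfDNA samples are removed as low-coverage noise. "Across the whole
   dataset" is taken to mean the cfDNA samples (OC + benign + healthy):
   PBL libraries enter the analysis only as the background reference of
   stage 2.
4. **CpG presence** — bins without a single CpG cannot carry MeDIP signal
   and are removed. A CpG straddling a bin boundary is credited to the bin
   containing its C.

The per-stage removal counts depend on the order (a bin failing two rules
is charged to the earlier stage), but the surviving set does not. The
cascade is idempotent and invariant to row/column order; both properties
are tested.

## The negative-binomial Wald test

Counts for bin $b$ and sample $s$ are modeled as
$K_{bs} \sim \mathrm{NB}(\mu_{bs}, \alpha_b)$ with
$\mu_{bs} = s_s\, q_{b,g(s)}$ and variance $\mu + \alpha\mu^2$. The three
estimation steps are deliberately simple and fully specified:

* **Size factors** ($s_s$): median-of-ratios — the median over reference
  bins of a sample's count divided by the bin's geometric mean across
  samples. Reference bins are those with no zero anywhere; when none
  exists (sparse data), an explicit fallback uses bins positive in at
  least half the samples, with geometric means over the positive entries.
  Factors are rescaled to geometric mean 1 so they read as relative
  depths.
* **Dispersion** ($\alpha_b$): method of moments on depth-normalized
  counts, $\hat\alpha_b = \max\{(s^2_b - \bar\mu_b)/\bar\mu_b^2,\;
  10^{-8}\}$, with the within-group pooled variance (group means removed
  first, denominator $n - g$) so real group differences do not inflate
  the estimate. No trended shrinkage is applied by default; at the
  cohort sizes this package targets (≈ 116 cfDNA samples) the
  per-bin estimate is already stable (median $\hat\alpha \approx 0.29$
  at a true 0.3 in simulation).
* **Group means**: per-group 1-D Newton–Raphson maximum likelihood for
  $\theta_b = \log q_b$ at fixed $\alpha_b$, with score
  $U = \sum_s [y - m(1+\alpha y)/(1+\alpha m)]$, $m = s_s e^\theta$.
  The curvature is strictly negative, so the iteration is stable;
  steps are clamped to ±5 on the log scale, initialization is
  $\log(\sum y / \sum s_s)$, and convergence is declared at
  $|\Delta\theta| < 10^{-12}$ (max 100 iterations). The implementation is
  vectorized across bins and is checked against a grid-search likelihood
  oracle to a relative error below $10^{-3}$.

The Wald statistic is the log2 fold change (case over control, control as
the reference level) divided by its standard error from the expected
Fisher information $I = \sum_s m/(1+\alpha m)$ per group; p-values are
two-sided normal, adjusted by Benjamini–Hochberg, and bins with
`padj < 0.1` are called DMRs. The relaxed 0.1 threshold matches the
exploratory genome-wide setting where the tumor-derived fraction of cfDNA
is small. Three deliberate omissions: no fold-change shrinkage, no
independent filtering, and no outlier-count handling — none are part of
the specified analysis, and each would change the estimand. Bins where a
group is all-zero (or the dispersion undefined) are reported untested with
`NA` statistics rather than pseudocounted; inventing a fold change for
them would fabricate effect sizes.

Subgroup contrasts (OC vs benign alone, OC vs healthy alone) re-run the
entire estimation on the selected samples, including normalization —
re-using full-cohort factors would leak information from excluded
samples. The robustness procedure does the same with one sample left out
(designed for an over-sequenced outlier) and intersects the DMR-annotated
gene sets of the two runs; each robust gene is represented by its
lowest-padj DMR, ties broken by chromosome order then start.

## Annotation conventions

CpG context uses the standard flank widths: shores are the 0–2 kb flanks
of merged islands, shelves the 2–4 kb flanks, open sea the remainder; the
four sets partition the genome exactly (verified by base-pair accounting).
Gene features are strand-aware: the promoter is the 1 kb immediately
upstream of the TSS and the "1–5 kb" category the next 4 kb; introns are
gene bodies minus exons; a region is intergenic only when it hits nothing
else. Every category a region touches by ≥ 1 bp is reported, so one 300-bp
region can be both island and shore. Distribution percentages divide by
the total number of (region, category) assignments rather than by the
number of regions — the only convention under which the bars sum to 100
while multi-category regions exist, and therefore the one used here.

## Permutation enrichment and ORA

The permutation test re-places each query region uniformly on its own
chromosome with its length preserved, independently per region; randomized
regions may overlap each other and are not masked against the blacklist or
filtered bins by default (a `mask` argument provides rejection sampling
when masking is wanted). Overlap is counted per query region (a region
touching three features counts once). The Z-score uses the null sample
mean and SD over `n = 1000` permutations (denominator $n-1$), with
|Z| > 2 read as strong evidence. On a toy genome where the per-region
overlap probability has a closed form, the engine matches the analytic
Z within Monte-Carlo error, and under a fully random null |Z| > 2 occurs
at roughly the nominal rate.

Over-representation uses the hypergeometric upper tail
$p = \sum_{i\ge k} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$ after
intersecting query and terms with the universe, BH adjustment across
terms, and a Storey q-value with fixed $\lambda = 0.5$ (falling back to
the BH value when the $\hat\pi_0$ estimate is degenerate — the two
estimators the significance rule requires are otherwise unspecified).
A term is significant only when both `padj` and `qvalue` fall below 0.1.

## Exploratory stages

The decomposition transform is `log2(count/size_factor + 1)` — a simple
monotone variance-flattener, named honestly in outputs (`log2p1_normalized`)
rather than claiming to be any particular package's variance-stabilizing
transform; the batch check only needs the count-variance relationship
flattened. The SVD batch check centers rows, takes the top two right
singular vectors, and runs one-way ANOVA of the sample scores against
library batch. Component signs are fixed by forcing the largest-magnitude
loading positive, so outputs are reproducible.

Stage exploration clusters the transposed count matrix of the case samples
over their 10,000 most variable bins (row variance, ties by index) with
k-means, k = 2, best of 10 restarts by within-cluster sum of squares
(Hartigan–Wong with `nstart`, seeded). Raw counts are the default input —
whether to transform first is genuinely open, and on raw counts a
grossly over-sequenced sample separates immediately, which is exactly the
failure mode the stage is meant to surface. The heatmap matrix extracts
each robust gene's representative bin, log2(x+1)-transforms, row-scales to
mean 0 / SD 1, and orders columns by diagnostic group (never clustered);
constant rows are zeroed with a warning.

## ddPCR quality control

Contamination is `(PBC copies / RPP30 copies) × 100` with pass below 0.5 %
and fail above 2 %; integrity is the long/short amplicon ratio with pass
below 0.4 and fail above 0.7. The published rules define only the pass and
fail inequalities; this package assigns everything in between — including
the boundary values themselves — to `warn`, which preserves both printed
inequalities verbatim and is conservative. Wells with fewer than 10,000
accepted droplets (strictly; 10,000 itself passes) are discarded before
technical replicates are averaged; a sample with no admissible well is
`invalid`. How disagreeing duplicates should be arbitrated is not
specified anywhere; the package reports the merged value only.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised and
validated without patient sequencing data. It emulates the statistical
structure the analysis assumes:

* NB counts with a CpG-density-linked baseline
  $\mu_0(c) = \mu_{base}(1 + \beta c)$ — MeDIP enrichment grows with
  methylatable CpG content; the linear link makes the dependence explicit
  and tunable since no canonical form exists.
* Log-normal per-sample depth factors (mean 1, log-SD 0.25).
* Hypermethylation spikes in the OC group only: 100 bins with log2 fold
  changes uniform on [0.9, 1.9], the range reported for robust
  ovarian-cancer DMRs. Hypomethylation spikes are supported but off by
  default, mirroring the strong hyper-dominance of the application
  qualitatively rather than numerically.
* A PBL background track: 5 % of bins where PBL samples draw from mean 40,
  far above the 20-read filter threshold. Outside those bins, PBL
  libraries run at 0.3× the cfDNA depth: the background panel represents
  an external, shallower dataset, and the 20-read threshold lives on its
  count scale. Without this scale, an ordinary CpG-dense bin would exceed
  20 reads in some of 20 PBL samples by chance alone and the filter would
  eat most of the genome — the filter is meant to remove
  blood-methylated regions, not coverage.
* One over-sequenced OC sample pinned at 10× the typical depth (the
  flow-cell-loading-error scenario), named as the last OC sample.
* ddPCR wells generated per regime (pass/warn/fail/lowdroplet), drawn away
  from the thresholds so classification is unambiguous.

Cohort sizes default to 40 OC / 38 benign / 38 healthy cfDNA samples plus
20 PBL references, the sizes of the motivating study. The genome defaults
to 4 chromosomes × 150 kb (2000 bins of 300 bp) with 10 CpG islands of
600 bp per chromosome, ~2 % CpG-free territory, 10 stranded gene models
and 60 classified repeats per chromosome — small enough that the full
pipeline runs in seconds, large enough that filter yields, power, and
enrichment Z-scores are measured on hundreds-to-thousands of bins. The
baseline mean μ_base = 8 with CpG slope β = 0.04 puts a typical bin's
cfDNA mean near 14 — enough signal that the empirical log2 ratio of
spiked bins recovers the true effect to about ±0.15 at these group
sizes — while the 0.3× PBL depth keeps ordinary bins safely below the
20-read background threshold; dispersion defaults to 0.3, a realistic
overdispersion for enrichment sequencing counts.

What the generator does **not** emulate: fragment-length distributions,
antibody efficiency and CpG-enrichment bias, GC bias, copy-number
aberrations, correlated neighboring bins, or the real hg38 CpG landscape.
One scale artifact deserves explicit mention: on a 2000-bin genome the
100 spikes are 5 % of all bins — orders of magnitude denser than a few
hundred DMRs among millions of genome-wide bins. One-sided spikes at that
density contaminate the median-of-ratios reference enough to inflate case
size factors by several percent, which shows up as a small negative shift
on null bins and a handful of hypomethylated false calls in the synthetic
cohort. This is a known composition-bias behavior of ratio normalization
under dense one-sided signal, and it shrinks toward zero at genome scale;
the calibration checks therefore use spike-free null matrices, and the
power checks score the spiked bins themselves. Passing tests demonstrate
that the statistical machinery is correct and calibrated under the
assumed count model — not that the model captures every artifact of real
cfMeDIP-seq libraries.

All randomness flows through per-stage streams derived from one config
seed, and the pipeline manifest records md5 hashes of every artifact;
re-running a config reproduces byte-identical outputs.

## Problem sizes and numerical tolerances used in validation

The validation suite uses 2000-bin null and spiked matrices at 40-vs-76
samples for calibration (type-I within [0.035, 0.065] at nominal 0.05;
spike sensitivity ≥ 70 % at padj < 0.1), 10,000 permutations against the
closed-form toy, 200 seeded repetitions for the permutation null rate, and
exhaustive enumeration up to N = 12 for the hypergeometric tail. MLE vs
grid-search agreement is required to a relative error of $10^{-3}$; BH
and overlap counting must match their definitions exactly.

## Known limitations

Two-group contrasts only (no covariates, no paired designs); a single
shared dispersion model without empirical-Bayes shrinkage, which is less
powerful than shrinkage estimators at small n; the permutation null
ignores inter-region dependence (regions are placed independently); Storey
q-values use a fixed λ rather than a smoother; and numeric parity with any
specific published count-testing package is explicitly out of scope — the
package is validated by calibration and recovery properties instead.
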