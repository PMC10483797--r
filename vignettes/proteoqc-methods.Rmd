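---
title: "Methods behind proteoqc: SNR, reproducibility and absolute quantification for multi-sample proteomics QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind proteoqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoqc)
```

# The problem

Label-free LC–MS/MS quantification is noisy in instrument-, site- and
time-dependent ways. A practical way to monitor that noise is to measure
a *reference material set* — several well-characterized biological
samples (here: four lymphoblastoid lines from one family, commonly
labelled D5, D6, F7, M8) — in technical replicate, and ask whether the
*known* biological differences between the samples stand out above the
technical variation. `proteoqc` implements the metrics for that
assessment and a ground-truthed simulator that makes every metric
testable without access to any deposited dataset.

# Relative quantification conventions

Protein abundance enters as iBAQ (summed peptide intensity divided by
the number of theoretically observable peptides). `ibaq_to_fot()`
converts it to the *fraction of total*:

$$\mathrm{FOT}_{i} = \frac{\mathrm{iBAQ}_i}{\sum_{j \in \text{identified}} \mathrm{iBAQ}_j} \times 10^5,$$

so present values in a run sum to $10^5$. Entries missing in the input
are assigned the sentinel $10^{-5}$. Two consequences shape the rest of
the package:

* the sentinel is far below any plausible genuine FOT value, so log
  transforms stay finite and "absent in one group" translates into a
  large but finite fold change;
* identification-based statistics must *not* treat the sentinel as an
  observation. Throughout the package "present" means non-missing *and*
  not equal to $10^{-5}$ (`is_present()`). I/O never applies the
  sentinel — on disk missingness is `NA`, so raw missingness stays
  recoverable.

Intensity tertiles (`assign_intensity_groups()`) rank proteins by the
mean of their *present* FOT values across an experiment's runs and cut
at the 33.33rd and 66.67th percentiles (type-7 linear interpolation,
ties broken by stable protein-id order). The estimator is a choice —
only the cut points are conventional — and the degenerate all-equal
case collapses to "medium" with a warning rather than an arbitrary
split.

# The PCA signal-to-noise ratio

Runs are embedded on the first two principal components and the SNR is

$$\mathrm{SNR} = 10\log_{10}\!\left(
\frac{m\binom{n}{2}}{\binom{m}{2}n^2}\cdot
\frac{\sum_{x<y}\sum_{i,j}\sum_{p=1}^{2} W_p\,(PC_{p,i,x}-PC_{p,j,y})^2}
     {\sum_{x}\sum_{i<j}\sum_{p=1}^{2} W_p\,(PC_{p,i,x}-PC_{p,j,x})^2}
\right),$$

with $m$ groups, $n$ replicates per group, and $W_p$ the fraction of
total variance explained by component $p$. The prefactor converts raw
sums into averages: a balanced $m \times n$ design has
$\binom{m}{2}n^2$ between-group pairs and $m\binom{n}{2}$ within-group
pairs — 54 and 12 for the 4×3 reference design (`pair_counts()`).
`compute_snr()` uses the pair-count-normalized form; the test suite
checks it against an independent brute-force enumeration of every pair
to $10^{-9}$ relative.

Numerical and design choices:

* **Preprocessing before PCA** (`embed_pca()`): sentinel-fill, $\log_{10}$,
  then per-protein centering and unit scaling. The source convention
  fixes only the sentinel; centering/scaling makes the score scale-free
  and is switchable. Zero-variance proteins are dropped first (they
  carry no geometry and break unit scaling).
* **Weights** are variance-explained fractions of the *full*
  decomposition, not renormalized over the two kept components; a
  renormalized option exists.
* **Category bins** are left-closed/right-open:
  $[0,2)$ ineligible, $[2,10)$ average, $[10,20)$ good,
  $[20,\infty)$ excellent; negative values are ineligible. The
  published range labels overlap at their endpoints, so boundary
  membership is fixed here by convention.
* **Degeneracy**: identical replicates give zero noise. This is
  reported as a distinct degenerate-replicates condition, and "zero" is
  judged relative to the signal (noise $< 10^{-12} \times$ signal),
  because noise-free simulations otherwise leak $\sim 10^{-30}$
  floating-point fuzz through the decomposition and return a finite,
  absurd score.
* **Unbalanced designs are errors.** The pair-count algebra assumes
  equal $n$; silently averaging unbalanced designs would change the
  metric's meaning.
* `derive_snr_threshold()` summarizes a collection of SNR scores as
  mean − SD, with the sample ($n-1$) standard deviation.

# Differential proteins and their reproducibility

Within one experiment, the fold change of a protein for an ordered
group pair is the ratio of mean sentinel-filled FOT across replicates;
calls are strict (`> 2` up, `< 1/2` down, exactly 2 is no call). Means
include the sentinel so that a protein absent from one group yields a
large finite ratio instead of being dropped. No significance test is
attached — the call is threshold-only by design.

Across a campaign of $E$ experiments, `dep_reproducibility()` counts
how many experiments repeat each (protein, pair, direction) call. For
$E = 24$ the low/medium/high bins are 1–9, 10–18, 19–24 — the published
partition, which is 9/9/6, not an equal third split; for other $E$ the
range $[1, E]$ is cut into equal integer thirds with remainders
assigned to the lower bins. `consistent_trend_deps()` returns the calls
repeated in every experiment, excluding any protein ever called in both
directions for the same pair.

# Reproducibility, stability and the four-dimensional summary

* `identification_frequency()`: in how many of an experiment's $n$ runs
  a protein is present (IDF).
* `occurrence_bins()`: presence fraction over *all* runs, placed into
  ten 10%-wide bins on $[0,1)$ plus a distinct exact-100% bin, so
  "identified in every run" is its own class.
* `pairwise_correlation()`: Pearson $r$ on $\log_{10}$ sentinel-filled
  FOT over the union of proteins present in either run of a pair
  (a present-in-both option exists). Union + sentinel mirrors how whole
  profiles are compared, and deliberately penalizes discordant
  detection.
* `stability_series()`: identification reproducibility of each month
  against a reference month, overall and within the reference month's
  intensity tertiles; exactly 1 at the reference month by construction.
* `four_dim_summary()`: mean per-run identification count,
  reproducibility (fraction of observed proteins present in all runs),
  mean replicate correlation, median replicate CV. Correlation and CV
  are computed within technical-replicate sets of the same biological
  group: on noise-free data the biological differences between groups
  would otherwise masquerade as "experimental CV", and the noise-free
  limit must be exactly (1, 1, 0).

CV itself (`protein_cv()`) is $100\,\mathrm{sd}/\mathrm{mean}$ with the
sample SD; proteins with fewer than two present values are skipped, not
errors.

# Absolute quantification

The anchoring chain is implemented in four explicit steps:

1. `qconcat_molar_amount()` — the molar amount of a stable-isotope
   concatenated standard protein from the heavy/light signal ratio
   against a spiked reference peptide of known amount.
2. `dilution_linearity()` — OLS of $\log_{10}$ signal on $\log_{10}$
   dilution factor; a valid internal standard should give slope ≈ 1 and
   $R^2$ ≈ 1. Zero signals are excluded with a warning; a constant
   series reports slope 0 with $R^2$ defined as 0.
3. `fit_anchor_calibration()` — OLS of $\log_{10}$(copies/cell) on
   $\log_{10}$(iBAQ) over anchor proteins. Log–log OLS is the standard
   for data spanning several decades; the source reports response
   curves and an $R^2$ but no regression convention, so this is an
   explicit choice. $R^2$ is computed from residuals directly (no
   perfect-fit warnings), and two anchors give the exact interpolating
   line.
4. `predict_copy_numbers()` — $10^{\hat\beta_1 \log_{10} x + \hat\beta_0}$,
   monotone for positive slope. Copies/cell conversion
   (`copies_per_cell()`) uses Avogadro's number and a user-supplied cell
   count: the cell-count normalization of the original preparation is
   not published, so it is a required parameter rather than a hidden
   constant.

# The simulator

`simulation_config()` + `simulate_experiment()` generate ground-truthed
data emulating the reference-material design. Defaults are the study
conditions: 4 groups × 3 technical replicates, base abundances spanning
7 decades, ~4% group-specific proteins per group, planted DEPs with
fold changes drawn log-uniformly in [4, 16] (always above the
detection threshold of 2), and intensity-dependent technical CV
(low/medium/high tertile targets 0.8/0.4/0.2 — roughly 80% CV at the
bottom of the intensity range down to 20% at the top).

Model components, each the simplest mechanism consistent with the
observed phenomena:

* **Abundance**: $\log_{10}$ base abundances are standard-normal draws
  linearly rescaled so the realized span equals the configured dynamic
  range exactly — lognormal in shape, deterministic in span.
* **Inter-individual biology** (`group_effect_sd`, default 0.1 dex):
  every protein receives a small lognormal per-group effect on top of
  which DEPs are planted. Samples from different individuals differ
  across the whole proteome, not only in a sparse DEP set; without this
  term, two principal components of a proteins ≫ runs matrix are
  dominated by technical noise and even noise-free data scores poorly.
  Setting it to 0 produces groups that are identical up to planted
  differences — the right null for DEP false-call rates.
* **Technical noise**: multiplicative lognormal with mean 1 and
  $\sigma = \sqrt{\ln(1 + \mathrm{CV}^2)}$, per intensity stratum, so
  the realized CV converges to the configured target.
* **Detection**: each protein is detected independently with
  probability $\mathrm{logit}^{-1}\!\big(s\,(\log_{10} a - a_{0.5})\big)$
  of its noiseless abundance — the simplest monotone model of
  intensity-dependent stochastic sampling in data-dependent
  acquisition. The midpoint defaults to the 30th percentile of
  $\log_{10}$ base abundance, concentrating missingness in
  low-intensity proteins.
* **Injection-order drift**: a multiplicative factor per injection slot
  applied uniformly to all proteins. Continuous modes (CI1 interleaves
  groups per cycle, 5-6-7-8/5-6-7-8/…; CI2 blocks each group,
  5-5-5/6-6-6/…) occupy consecutive slots; random mode (RI) draws slots
  from a window `ri_window_factor` (default 7) times the run count,
  reflecting runs scattered over days. A naive same-window permutation
  would make RI *less* drift-exposed than CI1 (whose replicates sit 4
  and 8 slots apart) and invert the empirically observed mode ordering;
  the widened window is what restores CI2 ≥ CI1 > RI under drift.
* **Degradation**: a configurable fraction of proteins decays
  exponentially in months past an onset month (default 12), lowering
  both abundance and detectability, which is what depresses
  identification reproducibility after the onset.
* **Twin structure** (`twin_similarity`, default 0 = off): optional
  probability that a planted DEP assigned to one of the first two
  groups is shared by both, mimicking a monozygotic pair.

Everything is a deterministic function of the configuration seed;
per-run seeds are derived from it with fixed prime strides and kept
below $2^{31}$.

What the simulator does **not** emulate: peptide-level quantification
and roll-up, correlated missingness between co-eluting peptides,
retention-time or mass-calibration drift with protein-specific
signatures, batch effects that reorder proteins rather than shift runs,
and real inter-laboratory protocol differences. Passing the simulation
suites therefore demonstrates that the metrics recover *planted*
structure under a plausible noise model — not that any particular
laboratory's data will score well.

# Problem sizes and tolerances used by the test suite

The suites run simulations at desk scale — 300–5000 proteins, 10–100
seeds or replicate draws per property — which keeps the whole test run
within a couple of minutes while leaving the Monte-Carlo bounds
comfortably away from their thresholds (e.g. DEP recall ≈ 0.999
against a 0.9 bound; null call rate ≈ 0.01 against 0.05). Exact
identities (pair counts, worked SNR examples, FOT sums) are asserted at
$10^{-9}$–$10^{-12}$; stochastic recoveries at the bounds stated with
each property. The brute-force SNR oracle, the normal-equations OLS
oracle and the hand-tallied fixtures are computed independently of the
implementation paths they check.

# Known limitations

* SNR requires a balanced design; there is no unbalanced extension.
* The Pearson/union convention makes replicate correlations sensitive
  to detection discordance; with heavy missingness the "correlation"
  axis of the four-dimensional map reflects identification as much as
  quantification. Use `mode = "intersect"` to isolate the latter.
* Median CV under data-dependent missingness is survivorship-biased:
  low-intensity proteins with fewer than two detections drop out, so
  the realized low-tertile median CV underestimates the generating CV.
* Calibration assumes a single global log–log relation per sample;
  protein-specific ionization efficiency is absorbed into scatter.
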