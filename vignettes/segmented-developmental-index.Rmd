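---
title: "The segmented developmental index: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The segmented developmental index: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devindexr)
```

## The question the method answers

A developmental time course profiled by RT-qPCR gives, per gene, a trajectory
of relative expression. Single-gene ANOVAs answer "does the treatment change
this gene", but not "does the treatment change the *pace* of development".
The segmented developmental index compresses a panel into one number per
sample — the ratio of averaged expression of genes rising with maturation to
averaged expression of genes falling with it — and asks, per time segment,
whether the two treatment arms gain index at the same rate. A maturation
delay shows up as a smaller slope in the treated arm, detected by the F-test
of the day × treatment interaction in an ANCOVA.

## Procedure

Given a replicate-level Cq table with arms DMSO (control) and ALLO (treated):

1. **Quantification.** ΔCq against the GAPDH housekeeping gene per sample;
   fold change FC = 2^−ΔΔCq against the arithmetic mean ΔCq of the DIV0
   calibrator group. Amplification efficiency is taken as exactly 2 — the
   formula is applied literally, with no per-gene efficiency correction —
   which assumes validated primers. Not-detected measurements propagate as
   missing, never as zero; detectability is decided at group level (a gene
   must amplify below the run length in at least `min_detected_fraction` of
   replicates at *every* assayed day of the group).
2. **Classification.** Within each segment (DIV26–55, 55–78, 78–95, 95–138),
   each gene is classified in the control arm by the Pearson correlation of
   log2 FC against day: up (r > 0, p < α), down (r < 0, p < α), else ns, with
   the two-sided t-transform p-value on n − 2 degrees of freedom.
3. **Index.** Per gene, FC is rescaled by the gene's control-arm mean within
   the segment; the index of a sample is mean(rescaled up) / mean(rescaled
   down). The control-derived gene sets and constants are applied unchanged
   to the treated arm.
4. **Slope comparison.** Per segment, `log2(index) ~ day * arm` is fitted on
   replicate-level values; the interaction F-test decides whether the arms'
   maturation slopes differ, and per-arm slopes are read off the full model.

Steps 2–4 are `run_devindex_pipeline()`; each segment runs independently, so
a failure (for example an empty gene set) flags that segment non-evaluable
without stopping the others.

## Design decisions and why

**Replicate-level correlations.** Segments span exactly two assayed days.
Per-day means would give two points per gene, forcing |r| = 1 with an
undefined p-value, so the significance rule is only computable on
replicate-level observations (six points at n = 3). For the same reason the
ANCOVA uses replicate-level index values by default; a per-day-mean option
exists (`index_level = "day_mean"`) for designs with more days per segment,
but with two days per segment it leaves zero residual degrees of freedom.

**"Equal weight" = per-gene rescaling.** A plain average of fold changes is
dominated by whichever gene has the largest FC. Dividing each gene's FC by
its control-arm segment mean puts every gene on the same scale; the index is
then invariant to multiplying any single gene's FC by a positive constant,
which is the operational meaning we adopt for giving all genes equal weight.
A corollary used in the tests: swapping the up and down labels maps the index
to its reciprocal, and a panel whose rescaled up and down sets coincide
scores exactly 1.

**Log2 scale for the slope comparison.** Replicate noise in qPCR is
approximately Gaussian on the Cq (log-expression) scale, so index noise is
multiplicative: the residual standard deviation is proportional to the index
level. Across a segment in which the index grows several-fold, a linear-scale
ANCOVA therefore has residual variances differing by orders of magnitude
between the two days — a Behrens–Fisher situation in which the pooled-variance
F-test is anti-conservative (its effective denominator degrees of freedom
collapse toward those of the high-variance cells). A design-stage simulation
study of exactly this layout (two days, two arms, n = 3, σ = 0.3 cycles)
showed the linear-scale test rejecting a true null at roughly 8% regardless
of panel trend strength, while on log2(index) the residuals are close to
homoscedastic and the test holds its nominal 5% level. The pipeline therefore
fits slopes on log2(index) by default; `ancova_scale = "linear"` is exposed
for comparison. The index *values* themselves remain linear-scale ratios.
`analysis/05_calibration.R` and the acceptance suite recompute the null
rejection rate; the suite requires it to sit inside the exact binomial 99%
interval around 0.05.

**Classification uses unadjusted p < α.** Multiple-testing correction is
applied to the reported per-gene ANOVAs (one Benjamini–Hochberg family per
analysis, recorded in a `family_id` column), not to the classification step,
which is a gene-set construction rule rather than an inference.

**Segments share boundary days.** Day 55 contributes to both DIV26–55 and
DIV55–78, following the segment naming; each segment is analysed as a
self-contained window.

**Type II sums of squares.** The late time point may carry more replicates
than the others (`rep_override`), so the factorial ANOVA uses Type II sums of
squares, which coincide with the classical balanced decomposition when cell
sizes are equal.

**Welch post-hoc contrasts.** The post-hoc procedure is a per-stratum Welch
two-sample test with BH adjustment across strata. This is a documented
substitution: it avoids assuming equal variances between arms, which the
multiplicative noise model makes implausible at late days.

**Exposure window.** The default exposure window is days 28–67 (the delay
window starts at withdrawal, day 67, and closes at the recovery day, 95);
both are configurable in `sim_design()` for designs that shift the window by
a day or two.

## The synthetic-data generator

The generator exists so that every claim above is testable against known
truth. It emulates:

- a 23-transcript panel plus housekeeping gene: 13 transcripts rising with
  maturation (neuronal differentiation and interneuron markers such as DCX,
  MAP2, GAD1/2, LHX6, SST), 8 falling (progenitor and proliferation markers
  such as PCNA, MKI67, SOX2, TTF1), and 2 flat controls (AKR1C2/3);
- the study layout: days 0/26/55/78/95/138, two arms, n = 3 per arm per day
  (optionally more at day 138), housekeeping Cq fixed at 20 cycles;
- linear per-gene ΔCq trends in a latent **maturation clock**: the control
  clock is the identity on days; after withdrawal the treated clock advances
  at rate 1 − δ until the recovery day, after which the deficit persists as a
  constant offset. `preset("withdrawal_delay")` uses δ = 0.5; with that
  clock, ground truth says the slope difference exists exactly in the two
  segments overlapping days 67–95;
- Gaussian replicate noise on the ΔCq scale, default σ = 0.3 cycles — strong
  enough to leave the ANCOVA non-degenerate, weak enough that the default
  trends classify cleanly at n = 3;
- clipping at the 40-cycle run length, with clipped values flagged
  not-detected.

Two generator choices are deliberately stylised. First, trend slopes are
homogeneous within the rising set (−0.08 cycles/day) and within the falling
set (+0.06): this makes log2(index) *exactly* linear in the maturation clock,
so the zero-noise ground truth ("interaction in the delay-window segments
only") holds in closed form rather than approximately; heterogeneous slopes
would curve the index trajectory and smear a small spurious interaction into
the post-recovery segment. Baselines do vary per gene, and users can supply
any `gene_trends()` table. Second, the housekeeping gene is noise-free by
default so ΔCq noise has a single source; `housekeeping_sd` adds it back for
robustness checks.

What the generator does **not** emulate — and hence what passing tests do not
establish about real data: per-gene amplification-efficiency differences,
plate and batch effects, heteroscedastic Cq noise at low abundance,
nonlinear or non-monotone trajectories, correlated noise across genes within
a sample beyond the shared housekeeping term, and organoid-to-organoid
biological heterogeneity beyond i.i.d. replicate noise.

## Numerical choices

- **Degenerate fits.** With zero residual variance (noiseless input), the
  ANCOVA flags the fit degenerate instead of dividing by zero: the
  interaction p-value is recorded as 0 when the interaction sum of squares is
  non-negligible (relative tolerance 1e-8 of the total sum of squares) and 1
  when the arms coincide. The factorial ANOVA handles the analogous case the
  same way (F = 0 or Inf per term).
- **Perfect correlations.** r = ±1 maps to p = 0 directly rather than through
  the t-transform's division by 1 − r².
- **Zero-variance genes** are ns with r undefined; genes with fewer than
  three observations are ns with a warning.
- **Non-evaluable segments** (empty up or down set) produce a flagged row,
  never a silent default.
- **Determinism.** All randomness flows through the design seed; run
  manifests record the MD5 digest of every output and omit timestamps by
  default, so a rerun at the same seed reproduces every CSV and manifest
  byte-identically.

## Problem sizes used in the checks

The test suite and acceptance script run the full
simulate → quantify → classify → index → ANCOVA pipeline 1000 times under
the null preset and 500 times under the delay preset (about 50–60 ms per
pipeline run), and validate every statistical primitive against brute-force
oracles on 50 randomised instances of at most 48 observations each. The
delay-detection bounds asserted by the suite (rejection rate at least 0.95 in
each delay-window segment, at most 0.20 outside) were frozen from a
2000-replicate calibration run of the same code.

## Known limitations

- With two days per segment the interaction test has few denominator degrees
  of freedom (8 at n = 3); power against small delays is limited and the
  log2-scale choice matters for calibration.
- Gene sets are selected on the control arm and reused for its own index;
  with borderline trend strengths this self-selection can tilt the control
  slope slightly. The effect is negligible when trends classify cleanly
  (the default panel's regime) and vanishes at σ = 0, but analysts applying
  the method to weakly-trending panels should expect mild anti-conservatism
  in the post-recovery segments.
- The index requires both a non-empty up-set and down-set; panels without
  falling genes cannot form it (segments are flagged non-evaluable).
- The 2^−ΔΔCq model assumes perfect doubling per cycle; no standard-curve
  efficiency estimation or melt-curve QC is included.
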