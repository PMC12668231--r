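---
title: "Quantifying mRNP condensation from Sed-seq data: models and methods"
author: "sedq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mRNP condensation from Sed-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedq)
```

# The measurement and the quantity of interest

Sed-seq fractionates a cell lysate by a moderate-speed spin into a total
(T), supernatant (S) and pellet (P) sample, and sequences the RNA of each.
For every transcript the quantity of interest is pSup — the proportion of
its molecules that remain in the supernatant. Condensed messenger
ribonucleoprotein (mRNP) particles sediment; soluble mRNPs do not. Under
stress, a drop in pSup is read as condensation; a transcript whose pSup
drops less than that of similar-length transcripts "escapes".

The three libraries are processed and sequenced independently, so raw
counts do not obey conservation of mass. The package's estimation chain
restores it.

# The mixing-ratio model

Within one fractionation experiment, conservation of mass for transcript
$i$ implies $T_i = a_S S_i + a_P P_i$ for two per-experiment constants
$a_S, a_P$ (the *mixing ratios*) absorbing the differential handling of
the fractions. `estimateMixingRatios()` fits

$$T_i \sim \mathrm{NB}(\mu_i = a_S S_i + a_P P_i,\ \phi)$$

over all transcripts whose three counts each exceed `minCount` (default
20), with weakly-informative priors (`priorConfig()`): by default a
Gamma(shape 2, mean 1) prior on each ratio and a half-Cauchy(0, 3) prior
on the NB size $\phi$ (variance $\mu + \mu^2/\phi$). With thousands of
genes the likelihood dominates and the ratio prior only matters on
degenerate ridges — when every gene shows the same supernatant/pellet
split, only $a_S S + a_P P$ is identified and the prior resolves the
ridge toward equal mixing, with a warning. The default estimate is the
MAP, found by bounded quasi-Newton optimization on
$(\log a_S, \log a_P, \log \phi)$ with random restarts; a full-posterior
mode (adaptive random-walk Metropolis) reports posterior means and 95%
intervals and agrees with the MAP well within those intervals on
simulated data.

Two numerical properties of this estimator are worth knowing. First, the
model conditions on the observed $S_i, P_i$, which are themselves noisy;
at high mean pSup (small pellet counts) this produces a systematic
upward bias of several percent in $\hat a_P$ — the noise in $S$
attenuates $\hat a_S$ slightly and conservation of the total then levers
$\hat a_P$ up by roughly the ratio of supernatant to pellet count mass.
The bias shrinks as dispersion weakens or pellet counts grow (stress
conditions), and it largely cancels in pSup itself, which depends on the
ratios only through a mild reweighting. Second, the estimated $\phi$ is
systematically below the simulation truth because the residual absorbs
the noise of all three counts, not just $T$; $\phi$ is a nuisance
parameter and its bias does not propagate to the ratios in any
measurable way.

Given a fit, `computePSup()` reports
$\mathrm{pSup}_i = a_S S_i / (a_S S_i + a_P P_i)$, with `NA` when both
$S_i$ and $P_i$ are zero, and its natural log-odds (`lopsup`) after
clipping into $[\epsilon, 1-\epsilon]$, $\epsilon = 10^{-4}$ (recorded
in the object metadata). `psupFromCq()` provides the qPCR analogue via
the delta-delta-Cq method against a spike-in, with a configurable
pellet/supernatant spike-mass ratio (default 1, matching a protocol that
adds equal spike mass to both fractions).

# Length-controlled condensation statistics

All scores work on the log-odds scale, which undoes the compression of
proportions near 0 and 1. `lengthProfile()` computes, for each gene, the
mean $\mu(L)$ and SD $\sigma(L)$ of log-odds pSup over all genes within
a window centred on its log-length; the window is a fixed fraction
(default 0.02) of the full log-length range, truncated at the data range.
The global residual SD of the control condition,
$\sigma(\mathrm{control}) = \mathrm{SD}\left[\mathrm{lopSup} - \mu(L)\right]$,
is the unit in which both difference scores are expressed:

* `deltaSed()`:
  $\Delta\mathrm{Sed} = [\mathrm{lopSup}(\mathrm{control}) -
  \mathrm{lopSup}(\mathrm{treatment})]/\sigma(\mathrm{control})$ —
  positive means more sedimentation under treatment; the control against
  itself is exactly zero.
* `escapeSed()`:
  $e\mathrm{Sed} = [(\mathrm{lopSup}_T - \mu(L,T)) -
  (\mathrm{lopSup}_C - \mu(L,C))]/\sigma(\mathrm{control})$ — a
  transcript's shift relative to its length cohort; positive = escape.

The windowed SD $\sigma(L,T)$ is computed and reported but does not
enter either formula by default; `sigmaMode = "windowed"` switches the
denominator to the per-gene windowed control SD for users who prefer a
length-local standardization.

`sedScore()` (rSed) is the within-condition statistic: transcripts are
sorted by length (UTRs included; ties broken by gene identifier for
determinism), partitioned into consecutive bins of 100, and each
transcript's log-odds pSup is Z-scored within its bin; per-replicate
Z-scores are averaged. A final partial bin is merged into the preceding
bin rather than dropped, because the longest transcripts are exactly the
biologically interesting extreme of the length trend. The score is
reported in the sedimentation orientation — positive rSed = sediments
more than its length cohort — so that a translationally repressed,
condensed transcript scores high and ribosome occupancy anticorrelates
with rSed. Bins whose SD is zero yield `NA` with a warning rather than
an arbitrary value.

Replicate handling: $\Delta$Sed and eSed are computed on per-condition
replicate-averaged log-odds pSup (the `combineReplicates = "scores"`
option scores each replicate pair and averages instead; the two
orderings differ only in which nonlinearity sees the replicate noise).
The sedScore averages per-replicate Z-scores, which is its defining
replicate rule.

# The biophysical length model

The baseline model for the sedimented fraction is a power law of
transcript length, $f(L) = \beta L^x$, so
$\mathrm{pSup}(L) = 1 - \beta L^x$. Under condensation-promoting
treatment the sedimented fraction is multiplied by
$\exp(s(\mu + \nu L))$ with a per-transcript term $\mu$, a
per-nucleotide term $\nu$, and a sign convention $s = \pm 1$
(`exponentSign`). The two groupings of the exponent are observationally
equivalent up to the sign of $(\mu, \nu)$, and both round-trip through
the fitter; the package default $s = +1$ makes positive $\mu, \nu$ mean
more condensation.

Fits minimize squared error on the log-odds pSup scale
(`fitBaselineSedModel()`, `fitStressSedModel()`). Numerical choices that
matter:

* The baseline is optimized over $(\log\beta, \log x)$ with the
  log-length *centred*: $\log f = a + x(\log L - \overline{\log L})$.
  In raw coordinates $\log\beta$ and $x$ are nearly collinear and
  quasi-Newton refinement stalls far from the optimum; centring makes
  the recovery of noise-free parameters exact to ~1e-9 relative.
* Multi-start: a grid of log-spaced $\beta$ and several exponents
  (defaults $10^{-6}$–$10^{-2.5}$, $x \in \{0.5, 1, 1.5\}$), each start
  refined by BFGS then Nelder-Mead polish; the returned fit dominates
  every grid start.
* Stress fits hold the control-condition baseline fixed (the
  condensation terms are *additional* parameters) and optimize the
  enabled subset of $\{\mu, \nu\}$ with parameter scaling
  $(1, 10^{-4})$ — $\nu$ is a per-nucleotide quantity three to four
  orders of magnitude smaller than $\mu$, and unscaled finite-difference
  gradients lose it.
* Predicted sedimented fractions are clipped to $1 - 10^{-6}$ before the
  logit; the model legitimately exceeds 1 for the longest transcripts
  under strong condensation, and those observations then carry no
  gradient. Parameter recovery simulations therefore use length
  distributions where the clipped tail is a few percent, mirroring real
  transcriptomes where the model is reported to deviate only for the
  longest transcripts.

`nestedFTest()` compares a full and a reduced fit on the same data:
$F = [(\mathrm{RSS}_r - \mathrm{RSS}_f)/\mathrm{df}_1] /
[\mathrm{RSS}_f/\mathrm{df}_2]$ with $\mathrm{df}_1$ the parameter-count
difference and $\mathrm{df}_2 = n - p_{\mathrm{full}}$ (the standard
nonlinear-least-squares convention; no other convention is recoverable
from the printed analyses). The scientific question it answers here:
does the treatment need a length-*independent* condensation term, i.e.
is the reduced model with only $\nu$ rejected? Under simulations from
the reduced truth the test's type-I error at $\alpha = 0.05$ is
calibrated (0.03–0.08) and power at $\mu = 0.5$, $n = 3000$, noise SD
0.3 is essentially 1. For reliable nesting in these simulations the full
fit is started at the reduced solution, which guarantees
$\mathrm{RSS}_f \le \mathrm{RSS}_r$ without relying on optimizer luck.

# Translation metrics

With a common spike-in added to every polysome fraction, absolute
ribosome occupancy is recoverable: `normalizeToSpikein()` divides every
abundance by the median abundance of that fraction's qualifying
spike-ins (estimated counts > 100), which cancels per-fraction depth
*exactly*, and `ribosomeOccupancy()` computes bound/(bound + free).
`ribosomeAssociation()` (bound TPM / total TPM) is the relative fallback
for stressed samples, where condensed RNA may pellet out of the gradient
entirely; it has no upper bound of 1. For the sucrose-cushion assay,
`occupancyFromCushion()` corrects the pelleted share for the pelleting
still observed after EDTA dissociates polysomes. The correction formula
is under-determined by the assay description; the default is the simple
floored difference `max(pSed(-EDTA) - pSed(+EDTA), 0)` and a
renormalized variant `(pSed(-) - pSed(+))/(1 - pSed(+))` is exposed —
the two agree when the EDTA background is small. Transcripts that pellet
*more* with EDTA are floored at zero and counted.

# Imaging scores

`colocalizationScore()` asks, per cell, whether RNA spots sit on
elevated marker intensity: the mean 3x3-pixel marker intensity around
spot centroids is Z-scored against the same statistic at 100 random
in-mask positions. Scoring per cell absorbs cell-to-cell background;
Z-scoring makes the score exactly invariant to affine intensity changes.
Random windows are drawn with replacement, with centres uniform over
mask pixels whose window lies inside the image, and may overlap spots —
with tens of spots in thousands of mask pixels the overlap effect is
negligible and excluding spots would bias the null upward. Constant
images (null SD 0) and spotless cells return `NA` with a warning.
`classifySGPositive()` implements the population rule: stress-granule
positive iff the median per-cell granule count exceeds zero; the
even-count midpoint convention means a median of 0.5 is positive.

# The synthetic-data generator

Every stage is testable against ground truth without external data. The
generator's defaults describe a plausible budding-yeast Sed-seq study
and were fixed once, before looking at any downstream result:

* Transcript lengths log-normal(log 1500, 0.5) truncated to
  [100, 20000] nt — median 1500 nt with a realistic long tail; UTR
  lengths log-normal around typical yeast medians (68/91 nt).
* Baseline surface $\beta = 10^{-4}$, $x = 1$: a median-length
  transcript has pSup ≈ 0.86, matching unstressed cells where most mRNA
  is soluble and sedimentation increases with length.
* Stress $\mu = \log 2$, $\nu = 2\times10^{-4}$ per nt: a
  median-length transcript roughly doubles its odds of sedimenting, long
  transcripts condense more.
* Gene-level log-odds jitter SD 0.3 around the length trend; escape
  offset $\delta_e = 1$ log-odds for induced genes (5% of genes,
  assigned to Hsf1/Msn2-4 regulons), induction log2 fold-change 2.
* Abundances log-normal (log-SD 1); NB size $\phi = 50$ for every
  count; mean total count 1000 per gene (≈2x10^6 counts per fraction at
  2000 genes).
* Counts for the three fractions are drawn independently around means
  that satisfy conservation exactly, with per-fraction depth factors
  whose ratios are the true mixing ratios, so
  $E[T] = a_S E[S] + a_P E[P]$ holds by construction.

What the generator does *not* emulate: UMI duplication, mappability and
multi-mapping artifacts, fraction cross-contamination, batch effects
between conditions, and correlated noise between fractions of one
experiment. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under the stated noise model,
not robustness to every artifact of real libraries.

One noise-floor consequence worth stating explicitly: a single
experiment's per-gene pSup estimate has standard deviation
$\approx p(1-p)\sqrt{2/\phi}$ from count overdispersion alone, which is
0.03–0.05 for mid-range pSup at $\phi = 50$ regardless of depth.
Accuracy below that floor comes only from replicate averaging, which is
how the per-condition estimates are computed and assessed here (the
study design this emulates used two biological replicates per
condition; recovery simulations use ten to separate estimator bias from
replicate noise).

# Problem sizes used in the shipped checks

The packaged validation uses 2000–5000 genes, 2–10 replicates per
condition, 20 simulated experiments for recovery medians, 500
simulations for F-test calibration and 60 for power, 10 simulations for
escape detection, and 50 synthetic cells per imaging scenario. These
sizes put Monte-Carlo error comfortably below the asserted margins while
keeping the full suite runnable on a laptop in minutes.

# Known limitations

* The mixing-ratio estimator inherits the errors-in-variables bias of
  the printed model (see above); a joint model of all three counts
  would remove it at the cost of departing from the published estimator.
* $\Delta$Sed/eSed standardize by a single global
  $\sigma(\mathrm{control})$; heteroscedasticity across the length range
  is visible in $\sigma(L)$ and can be opted into via
  `sigmaMode = "windowed"`.
* The stress-model exponent grouping is a convention, not an estimable
  quantity; only $|\mu|, |\nu|$ and the quality of fit are comparable
  across conventions.
* Imaging fixtures are 2-D analogues of maximum projections; 3-D
  z-stack scoring and spot detection are out of scope (spot coordinates
  are inputs).

```{r example, eval = FALSE}
## a complete run on synthetic data
res <- runPipeline(pipelineConfig(seed = 1,
                                  simulate = list(nGenes = 1000)))
res$summary
```
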