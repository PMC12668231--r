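# sedq — quantification of mRNP condensation from Sed-seq data

`sedq` implements the computational core of sedimentation-fractionation
RNA-seq (Sed-seq) analysis of messenger ribonucleoprotein (mRNP)
condensation. In a Sed-seq experiment a cell lysate is split by a
moderate-speed spin into total (T), supernatant (S) and pellet (P)
fractions, each sequenced separately. The proportion of each transcript's
molecules remaining in the supernatant (**pSup**) reports on its
condensation state: condensed mRNPs sediment, soluble mRNPs do not.

The package is aimed at groups analysing fractionation RNA-seq of stress
granules, translation-initiation-inhibited condensates (TIICs) and related
mRNP assemblies, and at methodologists who want the estimators exercised
against synthetic data with known ground truth.

## What it computes

**Mixing ratios and pSup.** Raw fraction counts do not obey conservation
of mass because the three libraries are processed independently. Per
experiment, `estimateMixingRatios()` fits the Bayesian count model

    T_i ~ NB(mean = aS*S_i + aP*P_i, size = phi)

over genes with all three counts above a threshold (default 20), with
weakly-informative priors on the mixing ratios `aS`, `aP` and a
half-Cauchy prior on the negative-binomial dispersion. `computePSup()`
then reports `pSup_i = aS*S_i / (aS*S_i + aP*P_i)` and its log-odds.

**Length-controlled condensation statistics.** On the log-odds scale,
with `mu(L)`/`sigma(L)` the windowed mean/SD over transcripts of similar
log-length (window = 0.02 of the log-length range):

* `deltaSed()` — `[lopSup(control) − lopSup(treatment)] / sigma(control)`,
  the stress-induced sedimentation change in control-SD units;
* `escapeSed()` — the change relative to same-length transcripts
  (positive = escapes condensation);
* `sedScore()` (rSed) — within-condition Z-score of log-odds pSup among
  the 100 transcripts of most similar length, averaged over replicates,
  reported so that positive = sediments more.

**Biophysical length model.** `fitBaselineSedModel()` fits
`pSup(L) = 1 − beta*L^x`; `fitStressSedModel()` adds per-transcript
(`mu`) and per-nucleotide (`nu`) condensation terms multiplying the
sedimented fraction by `exp(±(mu + nu*L))`; `nestedFTest()` asks whether
the length-independent term is required.

**Translation metrics.** `normalizeToSpikein()` + `ribosomeOccupancy()`
give absolute occupancy `bound/(bound+free)` from spike-in-anchored
polysome fractions; `ribosomeAssociation()` gives the relative
`TPM_bound/TPM_total`; `occupancyFromCushion()` applies the
EDTA-corrected sucrose-cushion estimate; `psupFromCq()` covers qPCR
delta-delta-Cq quantification.

**Imaging.** `colocalizationScore()` computes the per-cell smFISH
colocalization Z-score (spot-window marker intensity vs 100 random
in-cell windows) and `classifySGPositive()` applies the median-count
stress-granule positivity rule.

**Synthetic data.** `simulateTranscriptome()`,  `simulateTruePSup()`,
`simulateSedSeqCounts()`, `simulateSedSeqExperiment()`,
`simulatePolysomeTPM()` and `simulateCellScene()` generate every input
with known ground truth; `runPipeline()` drives the whole chain from a
YAML-able configuration.

## Worked example

```r
library(sedq)

## simulate a mock + stress experiment, quantify, score
res <- runPipeline(pipelineConfig(seed = 3, simulate = list(nGenes = 600)))
res$summary
#>        median_delta_sed    median_e_sed_induced median_e_sed_background
#>            3.769502e+00            2.622955e+00           -1.157334e-01
#> occupancy_rsed_spearman             f_statistic               f_p_value
#>           -2.796980e-01            8.343951e+01            1.007588e-18
```

Reading the output: the transcriptome's median deltaSed of ~3.8 control-SD
units says the simulated stress condensed most transcripts; induced
transcripts escape (median eSed ≈ 2.6 vs ≈ −0.1 for the background);
ribosome occupancy anticorrelates with relative sedimentation (Spearman
≈ −0.28), the TIIC coupling built into the simulation; and the nested
F-test sharply rejects a stress model without the length-independent
condensation term.

The estimator itself on a tiny exactly solvable system:

```r
S <- c(100, 10, 50); P <- c(10, 100, 50); T <- c(205, 70, 125)
fit <- estimateMixingRatios(T, S, P, minCount = 5,
                            priors = priorConfig(ratioFamily = "flat"))
mixingRatios(fit)
#>  aS  aP
#> 2.0 0.5
```

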