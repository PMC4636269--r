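---
title: "Monitoring acaricide resistance with acariscan: models and design choices"
author: "acariscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring acaricide resistance with acariscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acariscan)
```

## The monitoring problem

Field populations of the two-spotted spider mite (*Tetranychus urticae*)
evolve resistance to acaricides quickly. Two complementary measurements are
used to track it:

* **Phenotypic** — the residual contact vial (RCV) bioassay: mites are
  enclosed in acaricide-coated glass vials and mortality is scored after a
  fixed exposure (8 h). Once a *diagnostic dose* is established on a
  susceptible reference strain, a single-dose assay discriminates resistant
  populations: survivors at that dose indicate resistance.
* **Genotypic** — quantitative sequencing (QS): the frequency of a
  target-site resistance allele in a pooled DNA sample is read off the
  relative heights of the two nucleotide peaks at the SNP position in a
  Sanger chromatogram, through a calibration curve built from known allele
  mixtures.

`acariscan` implements both and the Spearman correlation layer that asks
whether the allele frequency at a locus can stand in for the phenotypic
resistance level.

## Probit dose-mortality model

Mortality in a vial at dose $d$ is modelled as binomial with

$$P(\text{death}\mid d) \;=\; c + (1-c)\,\Phi\!\big(\alpha + \beta \log_{10} d\big),$$

where $\beta$ is the probit slope (steeper = more homogeneous response),
$\alpha$ the intercept, and $c$ the natural (control) response. The dose
killing a fraction $p$ is
$\mathrm{LD}_p = 10^{(\Phi^{-1}(p') - \alpha)/\beta}$ with
$p' = (p - c)/(1 - c)$.

`fitProbit()` maximises the binomial likelihood. With $c = 0$ (the
default — RCV assays here have no solvent control correction) this is done
through `stats::glm` with a probit link, which computes exactly that MLE.
With `controlCorrection = TRUE` and dose-0 control rows present, the
three-parameter likelihood (including $c$ on a logit scale) is maximised
directly by BFGS, with the covariance taken from the numerical Hessian.

**Goodness of fit and heterogeneity.** A Pearson chi-square is computed over
the distinct doses (replicate vials pooled), with degrees of freedom $k$
minus the number of fitted parameters. When the statistic exceeds its 0.05
critical value, the classical heterogeneity convention is applied: the
parameter covariance is inflated by $\chi^2/\mathrm{df}$ and interval
quantiles switch from the normal to $t(\mathrm{df})$. This mirrors the
behaviour of the mainstream probit-analysis software that practitioners
compare against.

**Confidence limits for LD~p~.** The default is the delta method on
$\log_{10} \mathrm{LD}_p$; Fieller limits (solving the quadratic in
$m = (\Phi^{-1}(p)-\alpha)/\beta$) are available via `ci = "fieller"`. The
delta default was chosen because it is always defined and is what the
reported interval asymmetry on the dose scale (symmetric on the log scale)
corresponds to; Fieller is preferable when the slope is poorly determined.

**Diagnostic dose.** `diagnosticDose()` returns exactly $2\times$ the
*unrounded* LD90. Doubling the unrounded value is deliberate: doubling a
2-significant-figure LD90 and then rounding again can disagree with the
published convention (e.g. an LD90 printed as 0.22 with a diagnostic dose
printed as 0.441). Display rounding is applied only in report output.

**Degenerate inputs.** Fewer than 3 distinct positive doses, or all-dead /
all-alive across every dose, raise errors. A non-positive fitted slope is
flagged on the result (`validSlope`) and quantile operations then refuse;
`fitProbitBatch()` converts all of these into structured `"nd"` rows so a
batch over many acaricides never aborts (mirroring 'not determined' rows in
published toxicity tables).

**Vial dose conversion.** `ppmToSurfaceDose()` converts a stock
concentration to the deposited surface dose,
$\mathrm{ppm} \times V_{\mu l} \times 10^{-3} / A_{cm^2}$, with defaults of
a 100 µl aliquot and 16.39 cm² of coated vial wall — so 0.3–1000 ppm maps
to 1.83×10⁻³–6.1 µg/cm².

## QS calibration and inverse prediction

**Signal ratio.** For a two-allele SNP the resistant signal ratio is
$R = 100\,H_{mut}/(H_{mut}+H_{wild})$ using only the two segregating
nucleotides' peak heights; the other two channels are background and are
ignored. The ratio is invariant to rescaling all heights, so it does not
depend on overall trace intensity.

**Calibration.** Standards are made by mixing pure resistant and pure
susceptible templates at molar ratios 0:10, 1:9, 3:7, 5:5, 7:3, 9:1 and
10:0 (fractions 0–100%). `fitCalibration()` regresses observed ratio on
known fraction by ordinary least squares (classical calibration) and
`predictFrequency()` inverts it, $(R - b)/a$, clipping to $[0, 100]$. The
classical direction (ratio on fraction, then invert) is the default
because the errors live in the measured ratio, not in the known mixtures;
the paired "regression and prediction equations" convention follows from
it.

**Detection limits.** The published protocols state detection limits "at
the 95% confidence level" without a formula; we fix the convention as the
crossing points of the 95% inverse-prediction band with the scale ends.
The half-width of that band on the frequency scale is

$$h(x) = t_{0.975,\,n-2}\,\frac{s}{|a|}\sqrt{1 + \tfrac1n + \frac{(x-\bar
x)^2}{S_{xx}}},$$

and the lower limit solves $x = h(x)$ (the band separates from 0%), the
upper solves $x = 100 - h(x)$. Both are found by `uniroot` on monotone
functions. Consequences worth knowing: as the residual SD $\to 0$ the
limits tend to 0 and 100 (identity calibration gives exactly 0/100), and
the limits are monotone in the noise level. A sample whose point estimate
falls below the lower limit is reported `below_detection` (statistically
indistinguishable from a pure susceptible pool), and symmetrically
`above_detection`.

## Correlation layer

`spearmanCor()` computes the Spearman rank correlation with average-rank
ties. For the panel sizes used in monitoring (at most 12 strains) the
p-value defaults to the exact null distribution of the rank statistic
(identical to full permutation enumeration, verified against one in the
test suite); with ties or larger n it falls back to the t approximation.
Cells with `nd` in either vector are deleted pairwise — published panels
contain `nd` cells yet report correlations — and a constant vector yields
an `nd` correlation rather than an error. `correlationMatrix()` builds the
full mutation × acaricide (or mutation × mutation) matrix with `*`/`**`
flags on raw p-values at 0.05/0.01; a Benjamini–Hochberg column is
available with `adjust = TRUE` for users who want multiplicity control,
but raw p-values are the default for fidelity with standard reporting.

`renderHeatmap()` writes an annotated heat map (each cell printed with its
value, `nd` cells grey and labelled) plus the underlying table as TSV with
the literal `nd`; the table writer is byte-deterministic.

## Synthetic data: what it emulates, and what it does not

The generator exists so every stage is testable with known ground truth.

* `simulateBioassay()` draws vial counts from the binomial-probit model
  itself. Defaults: slope 2 and ~51 mites per dose (three replicate vials
  of 17, the realistic RCV occupancy), six doses log-spaced around the
  LD50.
* `simulateChromatogram()` draws the two segregating peak heights as
  truncated-at-zero Gaussians with means $pT$ and $(1-p)T$ and SD
  `noiseSd` × T. The default `noiseSd = 0.03` was set so that simulated
  calibrations reproduce the r² range (≈0.98–0.999) reported for real QS
  regressions; a lognormal height model was considered and rejected as
  indistinguishable at this noise level.
* `simulateLinkedPanel()` creates the monotone genotype→phenotype link the
  correlation layer tests for: strain LD50 is shifted multiplicatively,
  $LD50 = LD50_S\,(1 + (RR_{max}-1)\,p)$, shifts multiplying across loci
  on the dose scale, and mortality is observed at the susceptible-derived
  diagnostic dose. The published work implies but never formalises such a
  link, so it lives only in the generator.

What the simulations do **not** capture: real chromatogram artefacts
(dye blobs, mobility shifts, context-dependent peak heights that make the
true calibration slope differ from 1), copy-number variation at the locus
(e.g. AChE gene amplification, which decouples allele frequency from
phenotype), metabolic resistance mechanisms, and between-replicate
overdispersion in bioassays. Passing tests therefore demonstrate the
correctness of the estimators under their assumed models — not field
performance.

## Numerical choices and problem sizes

* Probit MLE via IRLS (`glm`); control-corrected fits via BFGS with
  analytic-free Hessian; likelihood floors at 1e-12 guard log(0).
* Quantile intervals: delta on log10 dose by default; t quantiles only
  under significant lack of fit.
* Detection-limit roots bracketed on [0, 100]; a calibration so noisy that
  the bands overlap everywhere is flagged uninformative rather than
  returning crossed limits.
* Recovery studies in the test suite use 200 simulated assays of 6 doses ×
  50 mites, 100-replicate calibration sweeps, and 500 null panels for the
  size of the exact Spearman test — sizes chosen to keep Monte-Carlo error
  well inside the asserted bands while the whole suite runs in under a
  minute.
* With ~300 mites per assay the sampling CV of an LD50 estimate is of
  order 10%; recovery assertions therefore check median *bias* (which is
  near zero for the MLE) and interval coverage, not absolute deviation,
  which is variance-dominated at this size.

## A worked example

```{r example}
# phenotypic side: fit the susceptible reference, derive the D/D
assay <- simulateBioassay(ld50 = 0.1, slope = 2, seed = 1)
fit <- fitProbit(assay)
fit
diagnosticDose(fit)

# genotypic side: calibrate and inverse-predict a pooled sample
std <- simulateStandards(noiseSd = 0.03, seed = 8)
curve <- fitCalibration(std$resistant_fraction, std$signal_ratio, "G323D")
curve
pool <- simulateChromatogram(0.65, noiseSd = 0.03, seed = 9)
predictFrequency(signalRatio(pool, "G", "A"), curve, sample = "field_pop")
```

## Known limitations

* Single-locus probit only; no time–mortality modelling of different
  scoring endpoints, and no logit/complementary log-log links.
* Calibration curves are strictly linear; saturation at extreme template
  ratios would need a monotone spline and is not implemented.
* AB1 trace parsing is out of scope here: the peak-table CSV is the input
  contract, and upstream basecalling/extraction must supply the four
  channel intensities at the substituted position.
* Exact Spearman p-values are unavailable under ties (t approximation is
  used), which matters for heavily saturated frequency panels.
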