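---
title: "Modeling and correcting reporter-ion interference in MS2 multiplex proteomics"
author: "tmteil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and correcting reporter-ion interference in MS2 multiplex proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmteil)
```

## The problem

Isobaric labeling (TMT, TMTpro) quantifies up to 16-18 samples in one
LC-MS run: every sample's peptides carry an isobaric tag, and fragmentation
releases channel-specific reporter ions whose intensities encode per-sample
abundance. The Achilles heel of MS2-level quantification is *ion
interference*: other labeled ions co-isolated with the targeted precursor
are co-fragmented and contribute reporter signal. Because the bulk of a
proteome is unchanged between samples, this contribution is approximately
uniform across channels and shrinks observed fold changes toward 1 -
*ratio compression*.

Isolation-window purity metrics (the fraction of MS1 signal in the window
belonging to the precursor) systematically understate interference: Orbitrap
raw files discard peaks below a local noise threshold, so a substantial part
of the co-isolated ion population is invisible in the recorded MS1 spectrum.
What remains of it is the *noise value* annotated on every centroided peak.
This package models reporter signal causally - visible precursor, visible
co-isolated ions, and noise-hidden ions - and turns the fitted model into a
per-PSM *estimated interference level* (EIL) that drives ratio
decompression and interference-balanced PTM-site-to-protein normalization.

## PSM-wise variables

For each peptide-spectrum match (PSM) the package derives, from the raw
MS1 snapshots and the PSM table:

* **PPF** (precursor purity fraction): all centroided peaks inside the
  isolation window (closed interval `precursor_mz ± isolation_width/2`,
  uniform isolation efficiency assumed) of the two bordering MS1 scans are
  collected. Peak intensities are weighted by retention-time proximity,
  `w_i = 1 - d_i / (d_-1 + d_+1)` with `d_i = |t_i - t_MS2|`; a single
  usable scan receives weight 1 (the limit in which it carries all
  information). Peaks within ±0.0025 Th of the declared precursor m/z, or
  within ±0.00125 Th of the ±1 isotope positions spaced `1.00335484/z`,
  count as precursor. PPF is the precursor share of the total weighted
  window intensity. The isotope spacing is charge-scaled because a literal
  ±1 Th offset would miss the isotopes of multiply charged precursors.
* Branch logic for imperfect data: a precursor absent from the preceding
  scan is searched in the second-last MS1 scan (which then substitutes,
  with its own retention time entering the weight); failing that, its
  intensity is imputed at the declared m/z as the minimum peak intensity of
  the preceding scan (the same minimum is reused when imputing into the
  following scan, a literal reading of the procedure). An empty following
  window is skipped; if the precursor is found in neither bordering scan,
  the following scan is skipped as well. A PSM with no preceding MS1 scan
  at all is flagged unquantifiable.
* **TIW**: the total weighted isolation-window intensity (the PPF
  denominator).
* **PIC** (total peptide ion current): MS2 total ion current minus the
  summed reporter intensity, clamped at 0. PIC replaces TIW as the
  precursor-size regressor in the general model because the MS1-intensity
  to reporter-signal relationship shows a slight nonlinearity that the
  MS2-derived PIC does not.
* **noiseEstimate**: the average noise value of the preceding-scan window
  peaks times the run-specific peptide density interpolated at the PSM's
  (precursor m/z, MS2 retention time). The density factor converts a local
  noise *ceiling* into an expectation of how much labeled-peptide signal
  actually hides below it. When the preceding window holds no peak, the
  noise value of the nearest peak in m/z is used (noise floors are locally
  smooth).
* **OIL** (observed interference level; ground-truth designs only): the
  mean normalized reporter intensity over the interference-only channels
  divided by the mean over the remaining peptide channels, capped at 1.
  Missing values are excluded from both averages; the channel sets come
  from the layout rather than being hard-coded.

Reporter intensities themselves are inferred as the maximum peak intensity
within a closed ±0.002 Th window at each expected reporter m/z (centroided
MS2 data assumed), and corrected for isotopic impurities by solving
`observed = M · true` exactly, clamping negative solutions to zero.
Impurity correction precedes between-sample normalization.

## Run-specific peptide density

Identified uniquely charged peptide features - distinct (sequence,
modifications, charge) triples, each at the coordinates of its
highest-intensity PSM - feed a two-dimensional Gaussian-product kernel
density estimate over (m/z, retention time), evaluated on a 200 × 200 grid.
The bandwidth follows the normal reference rule per axis (overridable); the
grid spans the feature range padded by one bandwidth per axis so border
cells are not starved. Values are rescaled to sum to 1, zeros replaced by
the smallest positive value, and square-rooted, in that order; the square
root tames the orders-of-magnitude contrast across the plane. Duplicate
feature coordinates are dropped before estimation - they carry no
information and would otherwise shrink the data-driven bandwidth. PSM-wise
values come from bilinear interpolation with out-of-range queries clamped
to the border.

## Empirical peptide classes

Reporter yield per unit of precursor fragment current varies strongly
between peptides. The package groups PSMs into empirical classes of
homogeneous fragmentation efficiency with a greedy binary decision tree
over: charge category (charges above 3 set to 3), number of isobaric labels,
presence of H, R, K, E, D, an extra-charge flag (`charge > #R + #H + 1`,
a formalization of charge not explained by basic residues), and any
variable modification present in the data. The response is
`log(total reporter intensity / (PIC · PPF))`.

At each node every admissible split is scored by the within-child sum of
squares; the best split must reduce the node's variance by at least
`min_improvement` (default 5%) and leave both children with more than
`min_leaf` (default 100) PSMs. The improvement floor is what stops growth:
a chance split of a homogeneous node always reduces the within sum of
squares a little (order 1/n), whereas genuine class structure removes the
between-class variance share, typically tens of percent. Gross response
outliers (beyond 5 MADs from the median) are excluded from tree *training*
only - plain variance is so outlier-sensitive that a handful of aberrant
scans can otherwise mask real structure - and are still routed to a class
afterwards. Ties break on a fixed variable order and smallest threshold,
so refits are bit-identical. Classes are refit per dataset, never reused:
their composition varies with collision energy, chromatography and sample
type.

## The interference model and the EIL

Per raw file (and, for FAIMS data, per compensation voltage) the package
fits, with the intercept fixed at zero,

```
Y ~ 0 + precursor:pepClass + nonprecursor:rawfileCharge + noiseEstimate
```

where `Y` is the scan's total reporter intensity, `precursor = PIC · PPF`,
`nonprecursor = PIC · (1 - PPF)`, and the interactions give one slope per
peptide class and per charge category. A companion ground-truth form
(`Y` = interference-only channel sum, `nonprecursor = TIW · (1 - PPF)`)
exists for validation against OIL in spike-in designs.

Estimation is iteratively reweighted least squares M-estimation with the
Tukey bisquare psi (tuning constant 4.685) and MAD residual scale, 50
iterations maximum, convergence at 1e-8 - the conventional defaults of
robust regression, all overridable. Two refinements matter in practice:

* **Variance weighting.** Reporter-signal noise is multiplicative, so
  residual spread grows with the signal. With a single global residual
  scale, the bisquare weights then effectively select the small-signal
  observations, which biases size-correlated coefficients down and pushes
  the compensation into the noise term. After a pilot fit, observations are
  therefore case-weighted by the inverse squared fitted value (two rounds);
  this stabilizes the variance, and the remaining skew affects all
  coefficients by a common factor that cancels in the EIL ratio. Setting
  `variance_weight_rounds = 0` restores the plain unweighted fit.
* **Small categories.** Charge categories with fewer than 25 observations
  merge into the nearest category; aliased columns are dropped with a
  warning; negative coefficients are retained (only the EIL is clamped).

The estimated interference level of a PSM with regressor vector `x` is

```
EIL = min{ 1 - (x_precursor' b_precursor) / (x' b), 1 }
```

clamped to [0, 1]; the numerator keeps only the peptide-class slopes, so
the EIL is the fitted non-precursor share of the fitted total reporter
signal. PSMs with non-positive fitted totals get a missing EIL.

## Interference correction and site-to-protein normalization

Reporter matrices are log2-transformed, normalized by median-ratio size
factors (one factor per channel, computed on PSMs shared across channels;
cyclic-LOESS is a planned alternative), and back-transformed. Correction
subtracts the uniform background: with `Ibar` the mean normalized intensity
over non-empty peptide channels (missing values excluded),

```
I_c_corrected = I_c - Ibar · min(EIL, 0.8)
```

The 0.8 ceiling mitigates overcorrection. Values falling below the
spectrum-wise minimum peak intensity are replaced by that minimum, as are
missing values; when no MS2 peak list is available the minimum non-missing
reporter intensity of the scan stands in. The correction is deliberately
not idempotent - applying it twice over-corrects.

For PTM data, site and protein features are built by summing normalized
PSM intensities and intensity-weighting PSM EILs (features from
interference-free acquisition, e.g. FAIMS-MS3, get EIL 0). Before a site is
divided by its parent protein, the partner with the lower EIL receives a
uniform interference addition `Ibar · (1-EIL_low)/(1-EIL_high) - Ibar`
until the two implied interference levels match; the channel-wise ratios
are then normalized to median 1. Equalizing first is what removes the bias
that unequal compression would imprint on the ratios, and it does not
inflate within-group ratio variance the way subtractive correction can.
Sites matching several protein groups are normalized against the group
with the most quantified PSMs (ties alphabetical).

## The simulator

`simulate_dataset()` emulates a controlled two-proteome design: a constant
background proteome (10:1 mass ratio to the spike), a spiked proteome
whose relative amounts across four 3-channel groups are 0:18:27:36 (design
fold changes 1.5, 4/3 and 2), one label-only channel, and three channels
free of the spiked proteome. Per PSM it draws peptide identity (random
tryptic sequences, charges 2-4), PIC (lognormal, median 2e5, sdlog 0.9),
PPF (Beta(12, 2) with a protein-level logit shift, sd 0.7 - peptides of
one protein share abundance and elution context), window noise values
(lognormal, median 5000, sdlog 0.5, protein-level multiplier sdlog 0.4),
and a planted peptide class (default: arginine-containing vs not, with
precursor slopes 0.55 / 1.15; nonprecursor slopes 0.9 / 0.65 by charge;
noise slope 800). Total reporter signal follows the generative form of the
general model, times lognormal measurement noise (sdlog 0.3, median 1),
with 5% of scans inflated 100-fold as gross outliers. The precursor part
splits across channels by the group design, the interference part
uniformly; additive Poisson-like jitter perturbs the channel split while
preserving the scan total. MS1 snapshots are emitted so that PPF and TIW
recompute from them exactly; the hidden-noise interference component never
appears as an MS1 peak - only the emitted noise values betray it, which is
precisely why `1 - PPF` under-predicts the observed interference here as it
does on real data.

When a target interference share is requested
(`interference_fraction = 0.3`), per-PSM shares are drawn from a Beta law
with that mean (concentration 40) and the noise component absorbs the
remainder. The share cannot be pinned to one exact value for every PSM:
that would make interference exactly proportional to the precursor
contribution and the regression unidentifiable (the noise column becomes an
exact linear combination of the others).

What the simulator does *not* emulate: chromatographic elution profiles,
fragment-level MS2 spectra, search-engine behavior, isotopic impurity
leakage (the default impurity matrix is the identity), and non-uniform
interference from a differential background. Passing tests therefore
demonstrate the correctness and calibration of the computational chain
under the stated generative assumptions, not instrument-level fidelity.

## Numerical choices and problem sizes

Matching tolerances are ±0.002 Th (reporters), ±0.0025 Th (precursor),
±0.00125 Th (isotopes); all window comparisons are closed intervals. The
density grid is 200 × 200 in production; validation exercises use 40-80
nodes where the oracle comparison is resolution-independent. End-to-end
validation runs use one raw file of 5,000 PSMs - large enough that every
peptide class and charge category clears the leaf and merging floors, and
small enough that the full simulate-fit-correct chain completes in well
under a minute. Fold-change evaluation aggregates spiked PSMs to proteins
(about 80) and takes the median of per-protein log2 ratios between group
channel means.

## Limitations

The model assumes interference is channel-uniform after normalization;
designs with a strongly differential background violate this and are
better served by purity-based PSM filtering or weighting. EIL quality
degrades when a raw file has too few PSMs to support its class tree and
per-charge slopes. The noise regressor takes the vendor noise annotation at
face value and does not model detector-specific noise-band structure. The
correction trades a small loss of precision for accuracy; statistical power
in differential testing is essentially unchanged, so the benefit is in
effect-size interpretability, not discovery rate.
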