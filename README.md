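# tmteil

Interference modeling and ratio-compression correction for MS2-quantified
multiplex (TMT / TMTpro) proteomics.

## The problem

In isobaric-labeling experiments, reporter-ion intensities of an MS2 scan
are supposed to encode per-sample peptide abundance. In practice, other
labeled ions co-isolated with the targeted precursor are co-fragmented and
add a near-uniform background to every reporter channel, shrinking observed
fold changes toward 1 ("ratio compression"). Classical isolation-window
purity metrics understate this interference badly, because Orbitrap raw
files discard sub-threshold MS1 peaks: a large share of the co-isolated ion
population is hidden in the spectral noise and is visible only through the
noise values annotated on the recorded peaks.

`tmteil` is for proteomics data analysts who want PSM-level interference
estimates and decompressed quantification from standard MS2 TMT data — no
special acquisition (MS3, FAIMS) required, although per-compensation-voltage
fitting is supported.

## The model

For each PSM the package computes the precursor purity fraction (PPF, the
retention-time-weighted precursor share of the isolation-window MS1 signal,
including ±1 isotopes at spacing 1.00335484/z), the total peptide ion
current (PIC = MS2 TIC − reporter sum), and a noise estimate (average
window noise value × run-specific 2D peptide density over m/z and retention
time). Peptides are grouped into empirical fragmentation-efficiency classes
by a greedy variance-minimizing decision tree over charge, label count,
amino-acid content, and extra-charge flags (leaf floor > 100 PSMs). Per raw
file, a zero-intercept robust linear model (bisquare IRLS, c = 4.685) is
fit:

    Y ~ 0 + precursor:pepClass + nonprecursor:rawfileCharge + noiseEstimate

with `precursor = PIC·PPF` and `nonprecursor = PIC·(1−PPF)`. The estimated
interference level of a PSM with regressors `x` is

    EIL = min{ 1 − (x_precursorᵀ β̂_precursor) / (xᵀ β̂), 1 }

i.e. the fitted non-precursor share of its fitted reporter signal. The EIL
drives per-PSM correction, `I_c − Ī·min(EIL, 0.8)` with a spectrum-minimum
floor, and interference-balanced PTM site-to-protein normalization (the
lower-interference partner receives uniform background until the implied
interference levels match, then ratios are taken).

A seeded simulator reproduces a two-proteome spike-in design (constant
background; spiked proteome at relative amounts 0:18:27:36 across four
3-channel groups, i.e. design fold changes 1.5, 4/3, 2; three spike-free
channels giving a direct observed interference level, OIL) with a planted
hidden-noise interference component, so the whole chain is testable without
raw instrument data.

## Worked example

```r
library(tmteil)
cfg <- sim_config(seed = 1, psms_per_run = 2000)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$psms, sim$ms1, sim$layout)
print(res$tree)
print(res$fits[[1]])
```

```
pep_class_tree: 2 class(es) over 1910 PSMs
  R-                             n=   885  mean=  0.4492
  R+                             n=  1025  mean= -0.0091
interference_fit (general model), raw file sim_run01, n = 2000, converged
  precursor.class.R-   precursor.class.R+ nonprecursor.charge2
            1.172244             0.576569             0.842467
nonprecursor.charge3        noiseEstimate
            0.717656           767.366253
```

The tree recovers the two planted fragmentation-efficiency classes
(arginine-containing peptides retain charge and yield fewer reporter ions:
planted slopes 0.55 vs 1.15, fitted 0.58 / 1.17), the per-charge
nonprecursor slopes (planted 0.9 / 0.65) and the noise slope (planted 800).
Comparing the model's interference estimate against the directly observed
interference of the spiked peptides:

```r
ev <- evaluate_ground_truth(res$metrics, res$metrics$eil, sim$truth, sim$layout)
print(ev$correlations, digits = 3)
print(ev$fold_changes[, c("numerator", "denominator", "design_log2fc",
                          "uncorrected_log2fc", "corrected_log2fc")],
      digits = 3, row.names = FALSE)
```

```
    level r_eil r_impurity
1     psm 0.987      0.536
2 protein 0.988      0.752
 numerator denominator design_log2fc uncorrected_log2fc corrected_log2fc
     100:9       100:6         0.585              0.431            0.555
    100:12       100:6         1.000              0.777            0.967
    100:12       100:9         0.415              0.336            0.410
```

The EIL tracks the observed interference level far better than the
isolation-window impurity 1−PPF (r = 0.99 vs 0.54 at PSM level), and
EIL-based correction moves the compressed median log2 fold changes
(0.43 / 0.78 / 0.34) back to the design values (0.585 / 1 / 0.415) within a
few hundredths of a log2 unit.

A thin command-line front end ships in `inst/cli/tmtd.R`
(`simulate | metrics | classes | fit | correct | run`).

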