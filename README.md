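# firstpass

Quantitative analysis of first-pass contrast-enhanced cardiac MR
perfusion imaging, paired with a digital phantom for studying how
acquisition choices — spatial resolution versus acquisition-window
duration versus temporal fidelity — shape what the quantification sees.

It is written for perfusion-imaging researchers who want (a) a clean,
tested implementation of the two standard perfusion readings and (b) a
controlled synthetic test bed where the true flow is known and the
dark-rim (Gibbs) artifact can be dialed in or out.

## What it computes

**Semiquantitative — maximal upslope and MPRI.** Each myocardial
segment's signal-intensity curve gets a five-point sliding linear fit;
the maximum slope, averaged over the six mid-slice segments, is
normalized by the LV blood-pool maximal upslope (three-point fit). The
stress/rest ratio of normalized slopes is the myocardial perfusion
reserve index:

    MPRI = (stress myo slope / stress AIF slope) / (rest myo slope / rest AIF slope)

**Fully quantitative — Fermi-constrained deconvolution.** The myocardial
curve is modelled as the AIF convolved with a Fermi-shaped impulse
response R(t) = A / (1 + exp((t − T0)/W)) (delayed by τd, fitted over the
first pass only). Myocardial blood flow is the initial response height,

    MBF = 60 · A / (1 + exp(−T0 / W))   [ml/min/g]

and MPR = stress MBF / rest MBF.

**Dark-rim artifact measurement.** Automated detection of the transient
subendocardial hypointense band (inner-half wall pixels more than 2 SD
below the remote myocardium), reported as thickness (mm), extent (% of
myocardial slice area) and duration (frames), on the most prominent
frame.

**Phantom.** A concentric-disc LV scene driven by a gamma-variate AIF and
a Fermi tissue response at known MBF, with an acquisition simulator:
k-space truncation to the acquired matrix (Gibbs ringing), acquisition-
window motion, moving-average temporal filtering, and Rician noise. The
four shipped sequence profiles reproduce the geometry of a published
four-way comparison (SENSE reference plus three 8× k-t accelerated
variants; acquired matrices 128/256/128/192 at 340 mm FOV, acquisition
windows 119/117/64/109 ms).

**Repeatability statistics.** Friedman rank test (with exact permutation
option), Bland–Altman within-subject SD, pooled prevalence arithmetic,
and CSV report tables.

## Worked example

Simulate a stress study with the SENSE-like reference geometry (128
acquired lines reconstructed to 256 — the coarsest voxel, hence the
biggest rim), then quantify it:

```r
library(firstpass)

cfg <- phantom_config(mbf_ml_min_g = 3.5, seed = 7)   # truth: 3.5 ml/min/g
study <- simulate_study(cfg, sp = sequence_profile("SENSE", n_frames = 32))
curves <- extract_si_curves(study$series, study$rois)

quantify_study(curves)
#> <fermi_fit> MBF 3.822 ml/min/g (A 0.1021 /s, T0 1.72 s, W 3.41 s, delay 0 s), RMS 0.17

measure_rim(study$series, study$rois)
#> # A tibble: 1 x 4
#>   thickness_mm extent_pct duration_frames prominent_frame
#>          <dbl>      <dbl>           <int>           <int>
#> 1         2.66       5.60               4              12
```

The fitted MBF of 3.82 sits above the true 3.5 because at this voxel size
the Gibbs rim bleeds into the subendocardial segments; with the
high-spatial-resolution profile (`"kt_high"`, 256 acquired lines) the
same seed yields MBF 3.44 and **no detectable rim** — the spatial-
resolution effect the phantom exists to demonstrate. A 2.66 mm-thick rim
lasting a handful of frames at a 2.66 mm voxel is one ringing lobe wide,
as theory predicts.

Key experiment drivers:

```r
mbf_recovery_study(snr = Inf)        # noiseless calibration across 0.5-5 ml/min/g
mpr_recovery_study(snr = 20, n_seeds = 100)  # stochastic MPR error at SNR 20
rim_matrix_experiment()              # rim size vs acquired matrix 128/192/256
temporal_filter_experiment()         # MPR under temporal smoothing
```

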