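# cardiofluor

Label-free optical readouts of myocardial remodeling: time-resolved
autofluorescence (TCSPC) decay analysis and diffuse-reflectance absorbance
for cardiac tissue, with the cohort statistics used to compare infarcted
(MI) and age-matched control (AMC) hearts across weeks post-infarction.

The package is aimed at biophotonics groups doing single-point fluorescence
lifetime spectroscopy of tissue: it provides the decay model and fitting
machinery, the spectral and reflectance calibrations, the group-comparison
statistics, and a synthetic-data generator that emulates the full study
design (4 detection channels at 20 MHz excitation, 3 positions x 3 repeats
per region of interest, cohort group sizes per week), so the whole pipeline
runs and is validated without any instrument data.

## The models

**Decay model.** The measured fluorescence in each spectral channel is a
multi-exponential decay

    I(t) = sum_i alpha_i exp(-t / tau_i) + C

fitted by reconvolution: the model is convolved with the measured
instrument response function (IRF) rather than deconvolving the data. Two
instrument effects are part of the model:

* *Incomplete decay.* At a 20 MHz repetition rate (period T = 50 ns)
  fluorescence from preceding pulses piles into the current period. In
  steady state the pulse train sums to a geometric factor per component,
  `1 / (1 - exp(-T / tau_i))`, and the convolution is circular over one
  period.
* *Afterpulsing.* Spurious delayed PMT pulses are modeled as a
  time-uniform background proportional to the detected signal
  (probability `p_ap`, default 0.01).

Channel 1 (410 +/- 10 nm, low photon counts, collagen-dominated) uses a
single exponential; channels 2-4 use a double exponential. The
intensity-weighted mean lifetime is

    tau_mean = (alpha1 tau1^2 + alpha2 tau2^2) / (alpha1 tau1 + alpha2 tau2)

**Spectral fractions.** Channel intensities under 372 nm excitation are
reported as fractions `F_n = I_n / (I1 + I2 + I3)`; channel 4 (separate
438 nm laser) is excluded from the ratio.

**Reflectance absorbance.** Diffuse reflectance is calibrated against a
white-reference lamp spectrum and converted to absorbance
`A(lambda) = -log10(I / I0)`, normalized to its 500-600 nm in-band maximum,
where oxyhemoglobin/oxymyoglobin (double peak ~542/577 nm) and reduced
cytochrome c (~550 nm) dominate.

**Statistics.** AMC-vs-MI comparisons per parameter, region and week use
Welch's t-test, Holm-Sidak step-down adjustment within each
parameter/region family of four weekly tests, Cohen's d effect sizes, and
the star notation `* p < 0.05` through `**** p < 0.0001` on adjusted
p-values. The unit of analysis is the animal (mean over its 9
measurements).

## Worked example

Simulate one channel-4 measurement at the week-1 infarct ground truth
(short lifetime 303 ps, long component 2.7 ns, 5x10^4 photons), then refit
it by reconvolution:

```r
library(cardiofluor)
cfg   <- sim_config()                       # 1024 bins x 48.8 ps, 20 MHz
irf   <- simulate_irf(cfg, seed = 2, channel = 4)
truth <- decay_params(alpha = c(0.75, 0.25), tau_ns = c(0.303, 2.7))
h     <- simulate_decay(truth, irf, cfg, seed = 3, channel = 4)
fit   <- fit_decay(h, irf)
fit
#> <decay_fit> channel 4, 2 component(s)
#> <decay_params> alpha=2002 tau=0.2966 ns; alpha=638 tau=2.743 ns | C=0.5438, p_ap=0.01, shift=4.24 ps
#>   tau_mean = 2.123 ns, chi2_r = 0.968
```

The fitted short lifetime (297 ps) recovers the 303 ps truth within 2% on
this realization; the reduced chi-squared near 1 indicates the
Poisson-consistent fit. `fit$intensity_fractions` gives the per-component
share of the signal (`0.253 0.747` here: the short component carries ~25%
of the intensity even though its amplitude fraction is 75%).

Re-analyzing a published summary table works from the printed
`mean +/- SD (n)` values:

```r
welch_t_summary(2.33, 0.12, 4, 3.89, 0.38, 3)   # t = -6.86, df = 2.30, p = 0.014
holm_sidak_adjust(c(0.01, 0.04))                # 0.0199 0.0400
cohen_d_summary(2.33, 0.12, 4, 3.89, 0.38, 3)   # -6.05
```

## Analysis workflow

The `analysis/` scripts run the full study-scale simulation and analysis
(about two minutes total) and write small tables under `results/`; bulky
intermediates go to `scratch/`:

```sh
Rscript analysis/01_simulate_cohort.R   # synthetic cohort, ground truths
Rscript analysis/02_fit_decays.R        # 3456 reconvolution fits -> animal table
Rscript analysis/03_spectra.R           # group-mean absorbance + peak table
Rscript analysis/04_statistics.R        # Welch / Holm-Sidak / Cohen's d table
```

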