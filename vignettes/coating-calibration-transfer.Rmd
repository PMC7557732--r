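---
title: "Core-independent Raman calibration for tablet film coating: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-independent Raman calibration for tablet film coating: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramancoat)
```

## The problem

During pan coating, tablets are sprayed with a polymer suspension while an
inline Raman probe acquires one spectrum of the moving tablet bed every
10 s. The applied coating mass — and, at the end point, the film thickness —
is the quality attribute to control. A partial-least-squares (PLS) model can
map preprocessed spectra to applied mass, but building one model per core
formulation is expensive. The idea implemented here is *calibration
transfer*: subtract each run's mean core spectrum so that only the growing
coating signal remains, rescale the resulting differential spectra by an
end-point normalization value, and a PLS model trained on a single core can
then predict coating mass on chemically different cores sprayed with the
same coating.

## The processing chain

For a run with spectra $s_t(\nu)$ the default chain is

1. **SNV** per spectrum: $z_t = (s_t - \bar s_t)/\mathrm{sd}(s_t)$, using the
   sample ($n-1$) standard deviation. This removes global intensity
   fluctuations. We use the sample convention throughout; the alternative
   $n$ convention differs only by a constant factor that cancels in PLS
   after centering, but a fixed choice makes tests exact.
2. **Core subtraction**: the mean of the SNV spectra of the last eight
   warm-up acquisitions is subtracted from every SNV spectrum, yielding
   differential spectra that isolate the coating contribution.
3. **Trailing moving average** over six spectra (60 s of process time). The
   window is causal because the intended use is real-time prediction; a
   centered window would need future spectra.
4. **End-point normalization**: division by either the maximum of the final
   differential spectrum (`max`) or the mean final intensity at the three
   anatase TiO~2~ bands 398/516/640 cm^-1^ (`max3`). References can come
   from the run itself (retrospective) or from the calibration run
   (the real-time variant).
5. **Savitzky–Golay second derivative** (window 21 points, polynomial
   order 2) to suppress broad baseline-like structure.
6. **Range crop** to the model's wavenumber window (inclusive bounds).

Two ordering choices deserve comment, since the steps are usually listed
without a unique order:

* The moving average runs **before** reference extraction. The end-point
  reference is a single scalar that rescales an entire run; reading it off
  one raw acquisition makes every prediction of the run ride on one noise
  draw. Averaging first reduces the reference noise by $\sqrt{6}$, and the
  "final spectrum" is then the 60 s-averaged one — consistent with a chain
  in which the moving average is applied to all inline-measured spectra
  before any further processing.
* The derivative runs **after** normalization. Both are linear maps so the
  order does not change the model space, but normalization-by-a-maximum is
  defined on the differential spectrum, not on its derivative.

Savitzky–Golay filtering delegates to the `signal` package; edge points use
the asymmetric least-squares fits over the available window rather than
padding, so no signal is fabricated at range boundaries. The derivative is
returned in index units — on a uniform axis this is a constant factor,
which is immaterial downstream of centering. The polynomial order is the
minimum (2) that supports a second derivative.

## PLS, outliers, and model selection

PLS1 is implemented from first principles with NIPALS. For a single
response the weight vector of each factor is the $X^\top y$ covariance
direction, so the algorithm is fully deterministic — no random
initialization. $X$ columns are centered but not variance-scaled: SNV
already normalizes spectra row-wise, and channel-wise autoscaling would
amplify noise channels. Strong outliers are flagged on the training scores
with Hotelling's $T^2$,

$$T^2_i = \sum_a t_{ia}^2/s_a^2, \qquad
T^2_{crit} = \frac{A(n-1)(n+1)}{n(n-A)} F_{1-\alpha}(A,\, n-A),$$

at a default confidence of 99% ("strong" outliers only), and excluded in a
single pass followed by one refit — outliers concentrate at the unstable
start of the process, and one exclusion step mirrors the original
protocol.

The spectral range and the factor count are chosen by exhaustive grid
search minimizing RMSEP on an evaluation set. When the evaluation set is
the test batch this reproduces the historical optimize-on-the-test-batch
protocol, which leaks test information into model selection; the function
documentation labels this clearly and an independent held-out run can be
passed instead. Ties are broken by fewer factors, then by the narrower
range (the simpler model); exact ties are rare in floating point but the
rule makes selection deterministic.

Performance is reported as $R^2$ of the calibration fit and RMSE / SE as a
percentage of the **total** sprayed coating mass of the run. A per-time-point
relative error would diverge near zero applied mass at the start of
spraying, so a single fixed denominator is used for every number the
package prints.

## The synthetic-run generator

No instrument data accompany this problem, so the package ships a
first-class generator that produces runs with the statistical structure the
analysis assumes:

$$s_t = j_t\left[c(\nu)\,e^{-\alpha m_t/M} + g(\nu)\,\frac{m_t}{M}\right]
 + b(\nu) + \epsilon_t,$$

with core spectrum $c$, coating spectrum at full mass $g$, polynomial
baseline $b$, applied mass $m_t$ growing at the spray rate (clipped at the
total $M$), log-normal per-spectrum intensity jitter $j_t$, and additive
Gaussian channel noise $\epsilon_t$. Key choices:

* **Linear coating growth**: the observed marker-band growth is near
  linear, and linearity makes PLS recovery exact in the noise-free limit —
  so failures of the chain are attributable to the chain, not the data.
* **Exponential core attenuation** (default $\alpha = 0.3$): the film
  physically masks the core. A single parameter keeps the generator
  analytic; 0 disables it. Attenuation is the main source of curvature in
  the feature–mass relationship and hence the reason more than one factor
  can help.
* **Built-in signatures**: the three cores differ strongly in overall
  intensity (acetylsalicylic acid ≫ diclofenac ≫ placebo) with their
  characteristic bands (ASA double band near 1605 cm^-1^ and the
  990–1340 cm^-1^ cluster; diclofenac 441/1046/1578/1605 cm^-1^; placebo a
  few weak bands around the 985 cm^-1^ phosphate stretch). The enteric
  coating carries the anatase TiO~2~ triplet 398/516/640 cm^-1^; the
  immediate-release coating the CaCO~3~ bands 280/712/1086 cm^-1^ with a
  dominant-band amplitude 2.7× weaker than the TiO~2~ one.
* **Amplitude and noise scales** were fixed once against the published
  phenomenology of differential spectra: on placebo cores the dominant
  TiO~2~ differential peak ends near 1–2 a.u. with only slight noise
  (noise_sd = 0.02 raw units, jitter σ = 0.01), and the coating marker is
  the global maximum of the final differential spectrum for every core —
  a prerequisite of `max` normalization. They were not revisited
  afterwards.
* **Defaults are the study conditions**: 10 s cadence, 8 warm-up spectra,
  11.5 g/min spray rate (middle of the 11–12 g/min band), 1373 g sprayed
  suspension for the enteric coating and 1330 g for the immediate-release
  coating on a 3800 g tablet batch, axis 200–1800 cm^-1^ at 1 cm^-1^.
  Spray-rate variability is *not* modeled: the recorded applied mass is
  the regression target, so rate jitter would add nothing testable.

What the generator does **not** emulate: radiative transfer in a turbid
moving tablet bed, detector shot noise (noise is homoscedastic Gaussian),
cosmic-ray spikes, probe fouling, wavenumber-axis drift, and run-to-run
changes of the true spectral response. Passing tests therefore demonstrate
the correctness and internal consistency of the chain under its stated
assumptions, not instrument-grade performance on real spectra.

## Thickness arithmetic

The end-point film thickness converts predicted sprayed mass to a
per-tablet dry film volume: tablets per batch $N = $ batch mass / mean
tablet mass; dry mass per tablet = predicted mass × solids fraction / $N$;
volume = mass / film density; thickness = volume / tablet surface area.
The biconvex tablet is modeled as a cylindrical band plus two spherical
caps ($R = ((d/2)^2 + h^2)/2h$, lateral area $2\pi R h$ per cap), the
standard geometric model; the area function is a plain argument so another
geometry can be plugged in. Whether plasticizer mass counts as film solid
is ambiguous in general, so the solids fraction is a configuration value
(0.22 for the enteric suspension, 0.15 for the immediate-release one), not
hard-coded truth. Film densities of the dried coatings are set to
plausible values (1.35 and 1.45 g/cm^3^) because measured pycnometry
densities are not available; thickness checks in the tests are therefore
self-consistency checks (simulate → recover), not comparisons against
published thickness values.

## Problem sizes and runtime

The unit tests run on shortened runs (≈100 spectra on a reduced axis); the
acceptance-style end-to-end tests and `scripts/acceptance.R` use the full
study-scale conditions (725 spectra × 1601 channels per run, 6 simulated
runs for a design grid). These sizes were chosen so the whole suite
completes in a few minutes on a single CPU while still exercising the
full-scale numerical path.

## Known limitations

* SNV is nonlinear in the mixing fraction (the per-spectrum standard
  deviation changes as the coating grows), so differential spectra are
  only approximately linear in applied mass; with core attenuation the
  curvature is core-dependent, which is the dominant systematic limit of
  cross-core transfer in the simulation.
* The `max` reference is sensitive to which channel happens to carry the
  maximum; on strongly scattering cores with weak coatings the maximum can
  sit on an imperfectly cancelled core band, degrading the normalization —
  the simulated analogue of the difficulty with strong cores and the
  TiO~2~-free coating.
* The grid search in its default usage optimizes on the test batch; treat
  the reported RMSEP of the selected model as an optimistic estimate, and
  use an independent evaluation run when honest generalization error is
  needed.
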