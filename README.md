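# endoquanta

Quantitative machinery for studying how active, tyrosine-phosphorylated
EGF receptor (p-EGFR) is packaged in endosomes. Activated receptors are
internalized through clathrin-coated vesicles and delivered to EEA1-positive
early endosomes, where — strikingly — the *mean* amount of p-EGFR per
endosome settles at a roughly constant value ("quanta") across a wide range
of EGF doses. `endoquanta` implements the analysis stack needed to measure
and model that behaviour, exercised end to end on synthetic data with known
ground truth:

* **FRET bleed-through correction.** Per-endosome FRET intensities are
  contaminated by spectral bleed-through. The classical correction
  `F = I - k·T` goes negative for a substantial fraction of endosomes, so
  the package models the bleed-through ratio `m = (I - F)/T` as a Gaussian
  (or two-component Gaussian mixture, fitted by EM on control objects) and
  reports the expectation of `F` under that model truncated to `0 ≤ F ≤ I`:

  `⟨F⟩ = E[F | 0 ≤ F ≤ I]`, with `F ~ N(I - μT, (σT)²)`,

  which is always positive, never exceeds `I`, and reduces to `I - μT`
  when the signal dominates.

* **Per-endosome statistics.** Integral intensities and number densities
  per 1000 µm² of cell area, log-binned histograms, normalized histogram
  differences between conditions with enrichment integrals, log-normal and
  two-lobe log-normal curve fits, disc-overlap colocalization (matched when
  cross-sectional overlap exceeds 30% of the smaller object), and
  bi-exponential time-course fits `A·e^(-t/τ₁) + B·e^(-t/τ₂)` whose decline
  constant τ₂ estimates the decay time.

* **Single-molecule counting by photobleaching.** Frame-to-frame intensity
  changes of tracked objects are pooled; the *neg-double-difference*
  function `freq(-ΔI) - freq(+ΔI)` cancels symmetric fluctuations and its
  periodic maxima at `u, 2u, 3u, …` reveal the single-fluorophore intensity
  unit `u`, from which per-endosome molecule counts follow (with optional
  expression-ratio and antibody-labelling corrections).

* **Trafficking ODE model.** A six-state system for EGFR at the plasma
  membrane, early endosomes and recycling endosomes, plus the number of
  p-EGFR-positive endosomes `N_pe` (fed by vesicle delivery, reduced by
  homotypic fusion `ρ·N_pe²`, increased by fission `f·N_pe`). The key
  nonlinearity is a sigmoidal dephosphorylation rate
  `β₁ + (β₂-β₁)·S_pe^r / ((Q·N_pe)^r + S_pe^r)`: dephosphorylation switches
  on when the load per endosome exceeds the characteristic quantum `Q`,
  buffering the mean p-EGFR per endosome against dose. A first-order
  variant (`β₁ = β₂`) is provided for model discrimination.

* **Multi-dose fitting.** Weighted least squares over four EGF doses
  (0.5, 1, 5, 10 ng/ml) and four observables, with each intensity
  observable rescaled by the analytic scale factor
  `scale = Σ dᵢsᵢ/σᵢ² / Σ sᵢ²/σᵢ²` (endosome *numbers* are absolute
  densities and are not rescaled), Latin-hypercube multi-start and bounded
  Levenberg–Marquardt over log-parameters.

## Worked example

```r
library(endoquanta)

mix <- ratio_mixture(c(0.6, 0.4), c(0.35, 0.9), c(0.1, 0.25))
cfg <- synth_config(seed = 1, bleedthrough_mixture = mix)
tab <- generate_fret_channels(generate_endosome_table(cfg), cfg)

fit <- fit_ratio_mixture((tab$I_fret - tab$F_true) / tab$I_ptyr, K = 2)
fit$mixture
#> Bleed-through ratio mixture (2 components):
#>   a=0.6106  mu=0.3406  sigma=0.1033
#>   a=0.3894  mu=0.9370  sigma=0.2866

corrected <- correct_object_table(tab, fit$mixture)
mean(corrected$F_corrected)  # 546.4 a.u. vs true mean 537.1 a.u.
```

The fitted mixture recovers the generating bleed-through components, and
the corrected per-endosome intensities average within ~2% of the stored
ground truth — while the naive linear correction, although fine on average,
returns negative intensities for individual endosomes.

```r
sim <- simulate_model(reference_params(), stimulus(10), seq(0, 60, 5))
tail(sim$observables, 3)
#>    time n_pe  s_pe s_pe_per_endosome s_vesicular
#> 11   50 7.57 44.64              5.89      427.79
#> 12   55 7.59 44.86              5.91      413.82
#> 13   60 7.57 44.86              5.92      401.77

plateau_metric(reference_params())$fold   # 1.62
```

Under continuous 10 ng/ml EGF the model reaches ~7.6 p-EGFR endosomes per
1000 µm² carrying ~5.9 a.u. each; across a 20-fold dose range the steady
mean per endosome changes only 1.62-fold (the first-order variant changes
8.5-fold — the signature that discriminates the two mechanisms).

```r
tr <- generate_bleach_series(cfg)
det <- detect_unit_intensity(
  neg_double_difference(delta_intensity_histogram(tr, 20)))
det$unit_intensity          # 200 a.u., secondary peaks at 400, 600, ...
vesicles_required(102, 8.5) # 12 vesicles to deliver one endosome's load
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages —
synthesis, correction, statistics, counting, fitting, comparison — writing
CSV intermediates and an MD5 manifest so reruns are verifiably identical.
A thin CLI wrapper lives at `inst/scripts/endoquanta`
(`endoquanta synth|simulate|pipeline`).

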