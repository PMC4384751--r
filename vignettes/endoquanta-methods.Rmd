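---
title: "Models and methods behind endoquanta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind endoquanta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquanta)
```

This vignette is the package's own account of its science: the estimators
and the kinetic model it implements, the assumptions behind them, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The probabilistic FRET bleed-through correction

A FRET-based assay for phosphorylated EGFR measures, per segmented
endosome, a raw FRET-channel intensity $I$ and an acceptor
(anti-phosphotyrosine antibody) intensity $T$. Part of $I$ is spectral
bleed-through — acceptor fluorescence excited directly by the donor laser —
quantified on control objects that carry no donor as the ratio
$m = (I - F)/T$, where $F$ is the true FRET signal.

The classical linear correction $F = I - kT$, with $k$ the ratio of control
means, is unbiased on average but the *distribution* of $m$ is broad: on a
per-endosome basis the subtraction goes negative for a substantial fraction
of objects, which makes per-endosome means meaningless. The package's
estimator instead treats $m$ as a random draw from the control
distribution, so that $F = I - mT$ is itself random with density
$N(I - \mu T,\ (\sigma T)^2)$, and reports the conditional expectation
given the physical constraint $0 \le F \le I$:

$$\langle F\rangle \;=\;
\frac{\int_0^I F\,P(F)\,dF}{\int_0^I P(F)\,dF}.$$

`expected_fret()` evaluates this in closed form (a truncated-normal mean).
For $I - \mu T \ge 0$ the closed form coincides with the published
sign-split expression built from $\mathrm{erf}$ and Gaussian terms; for
$I - \mu T < 0$ the two differ, and the exact truncated-normal mean is the
one that agrees with direct quadrature of the defining integral, so it is
the default (`method = "as-printed"` retains the historical formula). The
term-by-term expression is continuous at $I = \mu T$ with the convention
$\mathrm{sgn}(0) = 0$.

When the control ratios are better described by a two-component Gaussian
mixture (two physically distinct bleed-through routes), $F$ is a mixture of
Gaussians. Two constructions are conceivable: truncating the mixture
jointly to $[0, I]$, or mixing per-component truncated means.
`expected_fret_mixture()` implements the **joint truncation** — the
conditional expectation of the actual mixture distribution given
$0 \le F \le I$ — because it is the unique answer to "the expectation of
$F$ given what was measured and the constraint". It is computed per
component in closed form,
$\langle F\rangle = \sum_i a_i Z_i m_i^{tr} / \sum_i a_i Z_i$, with $Z_i$
the component's truncated mass and $m_i^{tr}$ its truncated mean; the
single-formula variants built from pooled moments (`method = "restored"`,
`"as-printed"`) are retained for comparison but are approximations.
Components with zero weight are dropped first, so a degenerate mixture
reduces *exactly* to the single-component estimator.

**Estimator bias.** Conditioning on $0 \le F \le I$ uses an improper flat
prior on $F$; when the true signal is small relative to the bleed-through
spread $\sigma T$, the truncation correction is systematically positive
("small but positive values" replace negatives), so the population mean is
biased upward. The effect shrinks as the signal-to-bleed-through ratio
grows: in the synthetic default regime (donor intensities log-normal with
meanlog 6.5, true-FRET fraction 0.5) the population mean agrees with
ground truth within about 3%; at a four-fold weaker signal the bias reaches
tens of percent. This is a property of the estimator, not of the
implementation, and is why the correction is used for per-endosome
statistics rather than absolute calibration.

**Numerics.** Truncation windows deep in a Gaussian tail are evaluated in
log space via survival functions; where even that loses all precision
(both tail masses equal at double precision) a rescaled quadrature fallback
is used. The mixture fit behind `fit_ratio_mixture()` is a standard
unequal-variance univariate Gaussian mixture EM (via *mclust*); with
`K = 3` the two lowest-mean components are flagged as bleed-through and
renormalized, matching the control experiment in which the third component
absorbs residual genuine signal. Ratios from objects with near-zero
acceptor intensity should be excluded before fitting (ratio instability).

## Per-endosome statistics and time-course fits

Intensities are *integral* intensities (summed fluorescence of a segmented
object); totals and object counts are normalized per 1000 µm² of
cell-covered area. Endosome-size distributions are summarized on
histograms with bins linear in log-area; histograms are normalized to unit
sum, and condition-minus-control differences therefore sum to zero exactly.
The enrichment integral over an area interval approximates the CDF
difference between conditions across that interval; choosing interval
bounds on bin edges avoids discretization bias, and agreement with the
analytic CDF difference for log-normal populations is verified in the
acceptance suite. Distribution fits are least squares of a (scaled)
log-normal density through the binned points — matching how such histograms
are usually summarized — with a two-component signed variant for difference
curves that show a depletion and an enrichment lobe. Defaults (40 bins,
5% log-range padding) are configurable; no canonical binning exists for
this kind of data.

Colocalization approximates segmented objects by discs of the measured
cross-sectional area centered at the object position, pairing objects whose
intersection exceeds 30% of the smaller cross-section (strict inequality at
the boundary). This preserves the overlap semantics at desk scale where
pixel masks are unavailable; it ignores object eccentricity.

Time courses are fitted with $A e^{-t/\tau_1} + B e^{-t/\tau_2}$ — one term
for growth, one for decline, opposite signs for rise-then-decay curves —
weighted by $1/\text{SEM}^2$ when SEMs are available. Bi-exponential least
squares is multimodal, so fits run from 16 log-spaced time-constant pairs;
pure single-exponential decays are a degenerate ridge of the model (any
amplitude split of one constant), so a single-exponential candidate is also
fitted and preferred when it fits equally well. The *decline* constant
$\tau_2$ (reported as `tau_decay`) is the positive-amplitude component,
ignoring negligible amplitudes, with the slower constant chosen on ties; a
"decline" slower than twice the observation window was never actually
observed and is flagged unreliable.

## Counting molecules from photobleaching

During continuous imaging, fluorophores bleach stochastically, so an
object's integral intensity decreases in discrete steps of one
single-fluorophore unit $u$. Frame-to-frame changes $\Delta I$ pooled over
objects are dominated by symmetric measurement fluctuations; the
neg-double-difference curve
$\mathrm{NDD}(\Delta I) = \text{freq}(-\Delta I) - \text{freq}(+\Delta I)$
cancels the symmetric part, leaving positive peaks at $u, 2u, 3u, \dots$
from frames in which one, two, three molecules bleached.

Peak detection smooths the curve with a 3-bin moving average and requires a
local maximum to exceed three times its null sampling SD. The null model is
exact: under pure fluctuations each NDD bin is the difference of two
Poisson counts, so its variance is the *sum* of the paired bin counts —
using this per-bin SD (rather than a global noise floor) is what keeps the
huge-count bins near $\Delta I = 0$ from generating false peaks. Edge bins
cannot be certified as local maxima. Default bin width is Freedman–Diaconis
on $|\Delta I|$; studies with known truth use $u/10$.

Counts follow as `round(intensity / u)`, optionally corrected by an
endogenous-to-tagged expression ratio (for GFP counts) or an antibody
labelling scale (for antibody counts); rounding to nearest is unbiased
under symmetric noise, and population means should be taken before
rounding. `vesicles_required()` uses nearest-integer rounding
(102/8.5 = 12 exactly); `vesicle_packing_capacity()` reports a
geometry-labelled upper bound (square-lattice or disc-area footprints on
the spherical shell inside the vesicle membrane) and deliberately does not
claim a single "true" capacity, since real vesicles carry mixed cargo.

## The trafficking model

States (arbitrary intensity units, except $N_{pe}$ in endosomes per
1000 µm²): non-phosphorylated and phosphorylated receptor at the plasma
membrane ($S_m$, $S_{mp}$), in early endosomes ($S_e$, $S_{pe}$), receptor
in recycling endosomes ($S_{re}$), and the p-EGFR-positive endosome number
$N_{pe}$. Binding of EGF (dose $c$ in ng/ml, absorbed into $k_{in}$'s
units) carries a squared-exponential onset delay
$1 - e^{-(t/\delta\tau)^2}$ summarizing ligand binding, coat assembly and
delivery (~minutes). Vesicle formation is basal plus a Hill term in
plasma-membrane p-EGFR, $K_v = k_{v0} + k_{v1} S_{mp}^q/(Q_v^q +
S_{mp}^q)$, and the internalized flux is partitioned between ligand-free
and phosphorylated receptor with weight $w$. Dephosphorylation in early
endosomes is the central nonlinearity:

$$\beta(S_{pe}, N_{pe}) = \beta_1 + (\beta_2 - \beta_1)
\frac{S_{pe}^r}{(Q\,N_{pe})^r + S_{pe}^r},$$

a sigmoid in the *load per endosome* (p-EGFR taken as evenly distributed):
above the characteristic quantum $Q$ phosphatase activity switches from
$\beta_1$ to $\beta_2$, pulling the mean load back toward $Q$. At
$N_{pe} = 0$ with load present the rate is the continuous limit $\beta_2$.
Endosome number obeys
$dN_{pe}/dt = (K_v/s_v) \cdot \frac{w S_{mp}}{S_m + w S_{mp}} S_{mp}
- \rho N_{pe}^2 + f N_{pe}$: creation equals the p-EGFR vesicle flux
divided by the mean vesicle content $s_v$ (the printed form of this term
duplicates $w$, which we attribute to typesetting — endosome creation must
equal flux over content), fusion removes endosomes pairwise, fission splits
them. Without influx the number relaxes logistically to $f/\rho$, which the
tests check against the closed-form solution.

Receptor mass is conserved except for the early-to-late sorting flux
$k_{le} S_e$ — the sum of the five receptor derivatives is exactly
$-k_{le}S_e$, checked both symbolically and as an integrated budget.
The four fitted observables are $N_{pe}$, $S_{pe}$, $S_{pe}/N_{pe}$, and
total early-endosomal receptor $S_e + S_{pe}$; whether recycling-endosome
receptor belongs in the vesicular observable is genuinely open (the assay
measures EEA1-colocalized intensity, which excludes it), so it is excluded
by default and available via `include_recycling = TRUE`.

**Numerics.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10` (the
Hill terms are mildly stiff); solver-level negative round-off is clipped at
zero; solutions are verified invariant under 10× grid refinement and
tolerance tightening. The initial condition is all receptor on the plasma
membrane and $N_{pe}(0) = 10^{-6}$, a floor that avoids 0/0 in the
per-endosome observable before any endosome exists.

**Reference parameter set.** The published fit archive for this model is
not available, so the package ships a reference set chosen once — and
documented as a package choice, not a reproduction — to satisfy two
requirements. First, the qualitative behaviours that motivate the model:
under the sigmoidal mechanism the steady (60-min) mean load per endosome
varies less than two-fold across the 20-fold dose range 0.5–10 ng/ml,
while the first-order variant ($\beta_1 = \beta_2$) varies more than
five-fold; and raising the homotypic fusion rate suppresses endosomal
p-EGFR at every dose, with a reduction to 37% of baseline keeping endosome
numbers above baseline at all later times. Second, practical
identifiability of the default free quintet ($\beta_2, Q, \rho, k_{in},
s_v$): $\beta_2$ is informative only while dephosphorylation is
rate-limiting in the data, which constrains it to the same order as the
observed relaxation rates (an earlier candidate with $\beta_2 = 0.9$
min⁻¹ met the fold criteria but left $\beta_2$ likelihood-flat upward).
The frozen values are the defaults of `model_params()`.

## Multi-dose fitting

The observables are measured in arbitrary intensity units, so each
intensity observable is compared through the analytic weighted
least-squares scale factor
$\mathrm{scale} = \sum_i d_i s_i/\sigma_i^2 \big/ \sum_i s_i^2/\sigma_i^2$,
shared across doses (one microscope calibration per observable; a per-dose
option exists). The endosome-*number* observable is an absolute density and
its scale is fixed at 1. This is not merely cosmetic: with a free number
scale, rescaling $(s_v, Q, \rho)$ by a common factor rescales $N_{pe}$
exactly and every observable change is absorbed by the scale factors — an
exact degeneracy that would make those parameters unidentifiable.

Optimization is bounded Levenberg–Marquardt on the weighted residual
vector over log-transformed parameters (positivity for free), from a
midpoint start plus Latin-hypercube restarts; all restart SSRs are
reported, and parameters within $10^{-3}$ (log scale) of a bound are
flagged. During optimization the ODE runs at `rtol = 1e-6` for speed;
`objective()` and the reported scale factors use the reference tolerances.
Full 18-parameter fits are supported but the default free set is the
quintet above — identifiability of the full set from four doses and four
observables is not established, and pretending otherwise would be false
precision.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the analyses rely on:
Poisson object counts per image (density 20 per 1000 µm² by default, the
order observed in quantitative endosome surveys), log-normal intensities
and cross-sectional areas (meanlog −2.2, sdlog 0.7 µm² — sub-µm²
endosomes), mixture-distributed bleed-through ratios, binomial per-frame
bleaching (probability 0.08 over 40 frames, Poisson(30) fluorophores per
object, additive read noise SD 50 at unit intensity 200 — i.e. single-step
signal-to-noise ≈ 4, typical of integral intensities of small objects) and
multiplicative 5% observation noise on model time courses with
SEM = CV × value, floored at 5% of the per-observable maximum so that
early near-zero points do not get unbounded weight. One global seed expands
to fixed per-generator offsets (+1 … +5), so generators are individually
reproducible and mutually independent.

They do *not* emulate pixel-level imaging: no point-spread function, no
segmentation errors, no tracking mistakes, no spatial correlation between
neighbouring endosomes, no photophysics beyond one-step bleaching (no
blinking, no partial maturation). Passing tests therefore demonstrate that
the estimators are correct and calibrated *given* faithful object tables —
not that segmentation itself is reliable. Study sizes (10⁴ objects for
calibration checks, 20 fit replicates, 50 seeds for the lighter recovery
studies, 60-minute simulations) were chosen as the smallest designs at
which the sampling error of each check is comfortably below its decision
threshold.

## Known limitations

* The truncated-expectation correction is intentionally biased upward for
  weak signals (see above); it buys per-endosome positivity.
* Disc colocalization ignores object shape; overlap fractions near the 30%
  threshold are geometry-sensitive.
* The NDD unit estimate assumes a single fluorophore species; mixed
  populations (e.g. chromophore heterogeneity) broaden and shift the peaks.
* The ODE model is well-mixed and deterministic: no per-endosome
  heterogeneity, no spatial gradients, no intraluminal-vesicle
  sequestration; the endosome-number equation treats p-EGFR as evenly
  distributed.
* Bi-exponential fits cannot distinguish growth and decline when their
  time constants coincide; the reliability flag marks declines that were
  not actually observed within the measurement window.
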