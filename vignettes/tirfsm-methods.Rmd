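---
title: "Models and methods behind tirfsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tirfsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfsm)
```

`tirfsm` quantifies single-molecule TIRF experiments in which a
GFP-tagged protein complex (the motivating system is the human augmin/HAUS
complex) binds surface-immobilized microtubules, and in which that binding
is controlled by importins and released by Ran-GTP. Because raw microscopy
data for such experiments are rarely deposited, the package pairs every
analysis stage with a synthetic-scene generator producing rendered image
stacks with exact ground truth, so each estimator can be validated end to
end. This vignette documents the models, the tunable parameters, and the
numerical decisions.

## The competition equilibrium

Inhibition and rescue are modelled with the smallest mass-action system
consistent with the observed behaviour: two coupled 1:1 equilibria,

$$\mathrm{cargo} + \mathrm{imp} \rightleftharpoons \mathrm{cargo{\cdot}imp}
  \;(K_{d,ci}), \qquad
  \mathrm{Ran} + \mathrm{imp} \rightleftharpoons \mathrm{Ran{\cdot}imp}
  \;(K_{d,ri}),$$

where "imp" is importin β or the preformed importin α/β heterodimer
(importin α alone is autoinhibited and inert in this model, and the
heterodimer abundance is limited by the β subunit, so the effective
inhibitor total is the β-containing total). Ran binding renders importin
unavailable for the cargo; the model does not distinguish active
displacement of cargo-bound importin from sequestration of free importin —
both give the same equilibrium end state, which is all a mass-action
treatment can see.

Given free importin $I$, both complexes follow from the isotherms, and
importin conservation becomes a strictly increasing scalar equation in
$I$, solved by bisection on $[0, I_{tot}]$ to $10^{-12}$ nM; the solution is
checked against a brute-force grid/bisection oracle in the tests. Defaults:
$K_{d,ci} = 13.1$ nM (the thermophoresis-measured cargo–importin α/β
affinity) and $K_{d,ri} = 0.3$ nM (Ran–importin β binding is sub-nanomolar;
only $K_{d,ri} \ll K_{d,ci}$ matters for the rescue behaviour).

A consequence worth stating plainly: with $K_{d,ci} = 13.1$ nM, 1 nM cargo
and 100 nM importin α/β, the exact free-cargo fraction is
$13.1/(13.1 + 99.1) \approx 0.117$. The model therefore predicts ~88%
inhibition at this dose ("almost complete"), not >90%; >90% inhibition is
reached from ~120 nM upwards (97% at 400 nM). A strict 10%-residual
readout at 100 nM would require an affinity of ≤11 nM or cooperative
binding, which this deliberately minimal model does not assume.

## The synthetic scene

`scene_config()` fixes the study conditions; the defaults are the
conditions the estimators are validated under:

| parameter | default | meaning |
|---|---|---|
| `dt` | 0.113 s | single-molecule frame interval |
| `pixel_size` | 0.107 µm/px | EMCCD pixel at 100× with 1.5× lens |
| `psf_sigma` | 1.3 px | Gaussian PSF SD |
| `D` | 0.05 µm²/s | lattice diffusion regime (0.01–0.1) |
| `static_fraction` | 0.2 | statically bound subpopulation |
| `unit_intensity` | 300 photons/frame | per fluorophore |
| `camera_gain` | 50 ADU/photon | EMCCD gain |
| `background_rate` | 20 photons/px/frame | cytoplasmic + camera background |
| `read_noise_sd` | 10 ADU | Gaussian read noise |
| `bleach_rate` | 0.02 s⁻¹ | per-fluorophore photobleaching |

Particles perform 1D Brownian motion along the microtubule arclength
($\Delta s \sim N(0, 2D\Delta t)$) with *reflecting* boundaries at the
filament ends and no unbinding — matching complexes that stay
lattice-bound for the full ~2 min observation window. Oligomers of 1–10
fluorophores bleach stochastically (exponential per-fluorophore lifetimes).
Rendering uses pixel-integrated Gaussians (error-function differences, so a
noiseless spot integrates to `camera_gain * unit_intensity` to machine
precision inside the truncation window), Poisson shot noise scaled by the
gain, Gaussian read noise, and clipping to the 16-bit range. The EMCCD
excess-noise cascade is approximated by Poisson × gain + read noise, not a
full gamma cascade — adequate for estimator validation, and stated here so
nobody mistakes the renderings for a camera calibration tool.

Motion blur: by default the emitter position is sampled once per frame, and
the matching motion-blur coefficient downstream is $R = 0$. With
`motion_blur = TRUE` the emitter is averaged over sub-frame positions
(continuous exposure), and the paired estimator setting is $R = 1/6$. The
pairing is documented because mixing the two silently biases the
localization-variance estimate.

What the generator does **not** emulate: microtubule dynamics or branched
nucleation (filaments are static line segments), binding/unbinding
kinetics, spectral bleed-through, drift, or subtilisin-treated lattices.
Passing tests on these scenes show estimator correctness under the stated
forward model — not robustness to every artefact of real data.

## Detection, linking, segmentation

Spot detection follows the standard candidate-then-refine scheme: local
maxima of a lightly smoothed frame above `median + snr_min × MAD` (default
`snr_min = 4`) are refined by least-squares 2D Gaussian fits in a 9×9 px
window (amplitude, sub-pixel centre, σ, offset). Fits are discarded on
non-convergence, σ outside $[0.5, 3]\times$ the PSF guess, amplitude below
the SNR cut, or centre drift out of the window; overlapping fits closer
than $2\sigma$ keep the brighter one. Integrated intensity is the fitted
Gaussian volume $2\pi\sigma^2 A$ in ADU, background-subtracted by
construction. At ~480 photons/spot over ~20 photons/px background the
measured per-axis localization RMSE is ≈0.12 px, which is at the
least-squares information bound for these counts; quoting localization
precision per coordinate axis is the convention used throughout.

Linking is greedy nearest-neighbour with a hard displacement gate
(`max_disp`, default $3\sqrt{2 D_{max} \Delta t}/\text{pixel size}$ with
head-room in $D_{max}$) and gap closing up to `max_gap` frames, the gate
scaling with the gap length. Greedy assignment (rather than global/Hungarian)
is sufficient at the sparse densities of single-molecule binding assays
and is far easier to verify; it is a documented limitation at high density.
Identity through a crossing of two particles diffusing on the same 1D
lattice is fundamentally ambiguous, so trajectory-recovery validation
places particles spread along the filament; long-lived mergers are exactly
the tracks a manual curation step would discard.

Microtubule segmentation replaces manual ROI drawing for reproducibility:
Otsu threshold on the time-averaged filament channel, connected components,
Zhang–Suen thinning (implemented in the package; no installed image package
provides 2D thinning), ordering of skeleton pixels by walking from an
endpoint, and a dilated mask (default radius 4 px) defining the
"area around the microtubule" used for intensity measurements. Manual ROIs
can still be supplied as masks.

## Diffusion estimation

Tracks are projected onto an averaged path before estimation. The paper-gap
here is what "averaged path" means; the package default is the
total-least-squares (principal-axis) line through the track's own
positions, which removes transverse localization jitter and is exactly
testable (projection is an isometry for straight paths). A segmented
filament path can be supplied instead.

The diffusion coefficient uses the covariance-based estimator (CVE) on the
projected displacements $\Delta s_i$:

$$\hat D = \frac{\langle \Delta s^2\rangle}{2\Delta t}
         + \frac{\langle \Delta s_i \Delta s_{i+1}\rangle}{\Delta t},
\qquad
\hat\sigma^2_{loc} = R\,\langle \Delta s^2\rangle
         + (2R-1)\,\langle \Delta s_i \Delta s_{i+1}\rangle.$$

The lag-1 covariance term removes the localization-noise and motion-blur
bias that plagues naive MSD slopes. $\hat D$ is unbiased but not positive:
short or noisy tracks legitimately produce negative values, which are
reported as-is; condition-level summaries use medians, so no truncation
bias is introduced. Displacements spanning detection gaps are excluded from
both moments rather than rescaled. `min_steps = 10` is the floor for
reporting an estimate (no guidance existed; 10 steps is where the
estimator's variance stops being useless). An MSD/OLS estimator over lags
1–10 is kept as an independent cross-check only.

Static/diffusive classification compares the dimensionless ratio
$\hat D \Delta t / \hat\sigma^2_{loc}$ with the $(1-\alpha)$ quantile of
its null distribution for a purely static particle of the same track
length (simulated once per length and cached). The null must be built on
the *ratio*: $\hat D$ and $\hat\sigma^2_{loc}$ are estimated from the same
displacements and are anticorrelated, and calibrating on $\hat D$ alone
roughly doubles the false-positive rate (measured 11% instead of the
nominal 5%).

## Intensity quantification and molecule counting

Per-microtubule binding is the mean complex-channel intensity over the
dilated filament mask minus the mean over a background annulus around it
that excludes every filament mask in the field; one microtubule averaged
over frames is one data point, and the measurement is exactly invariant to
constant offsets. Track intensities average the fitted integrated
intensity over the first 20 localizations, limiting photobleaching bias.

The single-fluorophore unit is calibrated from photobleaching traces:
penalized change-point analysis (binary segmentation accepted while BIC
improves) selects traces with exactly one downward step whose terminal
level is consistent with background (within 2 robust noise SDs); the unit
is the mean pre-bleach plateau. Selecting single-step traces this way is
the package's answer to an unspecified manual selection step; fewer than 20
accepted traces flags the calibration low-confidence. Molecule numbers are
the intensity/unit ratio, reported both as a positive real and as a nearest
integer of at least 1.

## Statistics

* **Mann–Whitney U** (two-sided everywhere): midranks with tie-corrected
  variance. For pooled $n \le 16$ without ties the p-value is computed by
  exact enumeration of all rank assignments; above that, the
  continuity-corrected normal approximation. The switch point matters: the
  normal approximation is worst-case ~0.04 off the exact p at $n=3+3$ and
  only drops below ~0.02 around pooled $n \approx 12{-}16$, so the package
  never reports an approximate p where enumeration is cheap.
* **Median with 95% CI**: distribution-free binomial order-statistic
  interval (attained coverage reported); bootstrap percentile fallback for
  $n < 8$ where order statistics degenerate to the range.
* **Hierarchical bootstrap slope** for replicate-structured titrations:
  each of 1000 iterations resamples the replicate set with replacement,
  then draws one point per (replicate, concentration) cell with
  replacement, pools the draws, and fits OLS; the slope is the bootstrap
  median with 2.5/97.5 percentile CI. The procedure's verbal description
  is ambiguous between this reading and drawing a single replicate per
  iteration; the per-replicate-per-concentration draw dominates the
  sentence, so it is the default, and the single-replicate reading is
  available via `scheme = "single_replicate"`.
* **Kd fit**: 1:1 binding with ligand depletion (quadratic isotherm),
  nonlinear least squares over $(K_d, r_{free}, r_{bound})$ with $K_d > 0$.
  The depletion model is the default because the labelled partner (5 nM
  final) is comparable to the measured affinity (13.1 nM), where the
  hyperbolic isotherm is biased; the hyperbolic model is provided and the
  two agree within 1% once the fixed partner is below $K_d/100$. Fits are
  flagged uninformative when the curve never leaves saturation or the
  amplitude collapses. Unweighted residuals by default (instrument
  weighting unknown); relative-error weights are available.

## Problem sizes and reproducibility

Validation runs use ensembles sized to make the checks sharp but quick:
200 tracks × 100 steps per diffusion condition, 10³ static tracks for the
noise closed form, 10⁴-step tracks for estimator cross-validation, 500
traces for oligomer-mixture recovery, 500 meta-replicates for bootstrap
coverage, and rendered stacks with 500–1000 ground-truth spots for
detection metrics. Every stochastic routine draws from a single seeded
generator (`scene_config(seed=)`, or the `seed` argument of the stochastic
functions), and identical seeds give bitwise-identical outputs; the run
log written by `run_pipeline()` records seed, parameters and package
version.

## Known limitations

* Greedy linking degrades at high particle density; no multi-emitter
  fitting, so spots merging below ~2σ separation are detected as one.
* The equilibrium model is strictly 1:1; avidity or cooperativity of the
  importin α/β heterodimer is not modelled (see the 100 nM discussion
  above).
* Intensities stay in ADU; no photon-transfer calibration is attempted for
  real data.
* The renderer's noise model is a Poisson–Gaussian approximation of an
  EMCCD, and microtubules are static straight or gently curved filaments.
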