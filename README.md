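# tirfsm — single-molecule TIRF analysis of microtubule-bound complexes

`tirfsm` is an R package for quantifying total internal reflection
fluorescence (TIRF) microscopy experiments in which a GFP-tagged protein
complex binds surface-immobilized microtubules. The motivating biology is
the regulation of the human augmin (HAUS) complex: importins sequester the
complex and block its microtubule binding, and Ran-GTP releases it. The
package covers the three analyses such experiments need:

1. **Binding dose–response** — per-microtubule background-corrected
   intensity under named conditions (importin dose, Ran rescue), summarized
   as medians with distribution-free 95% confidence intervals and compared
   with Mann–Whitney U tests.
2. **Single-molecule diffusion and stoichiometry** — sub-pixel Gaussian
   spot detection, nearest-neighbour linking, projection of each track onto
   an averaged path, and the covariance-based estimator (CVE) of the
   one-dimensional diffusion coefficient:

   D̂ = ⟨Δs²⟩/(2Δt) + ⟨Δsᵢ·Δsᵢ₊₁⟩/Δt,  σ̂²loc = R·⟨Δs²⟩ + (2R−1)·⟨Δsᵢ·Δsᵢ₊₁⟩

   which is unbiased in the presence of localization noise (variance
   σ²loc) and motion blur (coefficient R). Track intensities are converted
   to molecule numbers via a photobleaching-calibrated single-fluorophore
   unit.
3. **Solution binding and titration statistics** — 1:1 binding-isotherm
   dissociation-constant fits with ligand depletion (quadratic isotherm)
   and the hierarchical bootstrap regression slope for replicate-structured
   dose–response data (n = 1000 resamples, median with 95% CI).

Because raw single-molecule microscopy data are rarely deposited, the
package includes a first-class synthetic-scene generator: a mass-action
importin/Ran competition model (solved by bisection and verified against a
brute-force oracle), 1D Brownian tracks on microtubule paths with a static
subpopulation, stochastic photobleaching of 1–10-mer oligomers, and
pixel-integrated Gaussian PSF rendering with Poisson shot noise and
Gaussian read noise. Every estimator in the pipeline is validated against
this ground truth. See `vignettes/tirfsm-methods.Rmd` for the models and
numerical choices.

## Worked example

Solve the competition equilibrium at 1 nM cargo and 100 nM importin α/β
(cargo–importin Kd 13.1 nM), then simulate, render and analyse a small
single-molecule scene:

```r
library(tirfsm)

solve_competition(equilibrium_state(aug_total = 1, impB_total = 100,
                                    kd_aug_imp = 13.1))
#> Importin/Ran competition equilibrium
#>   totals (nM): cargo 1, impA 0, impB 100, Ran 0
#>   Kd (nM): cargo-importin 13.1, Ran-importin 0.1
#>   free cargo fraction: 0.1167
#> aug_free imp_free ran_free  aug_imp  ran_imp
#>   0.1167  99.1167   0.0000   0.8833   0.0000

cfg   <- scene_config(image_size = c(48L, 160L), n_frames = 20, D = 0.06,
                      static_fraction = 0.2, seed = 42)
path  <- straight_path(c(6, 24), c(153, 24), pixel_size = cfg$pixel_size)
truth <- simulate_tracks(cfg, path, n_particles = 6)
stack <- render_stack(truth, cfg)
stack
#> image_stack: 20 frames of 48 x 160 px (complex channel), 0.107 um/px, dt 0.113 s

spots  <- detect_stack(stack, psf_sigma_guess = cfg$psf_sigma)
tracks <- link_tracks(spots, max_disp = 5, max_gap = 2)
dtab   <- estimate_diffusion_table(tracks, cfg$pixel_size, cfg$dt, min_steps = 5)
head(dtab, 3)
#>   track_id      D_hat sigma2_loc_hat n_steps too_short motility_class
#> 1        1 0.16891224  -0.0052091287      16     FALSE      diffusive
#> 2        2 0.06741645   0.0019543254      17     FALSE      diffusive
#> 3        3 0.04421697   0.0004404223      19     FALSE      diffusive

ci <- median_ci(dtab$D_hat[!dtab$too_short])
sprintf("median D = %.3f um2/s (95%% CI %.3f-%.3f)", ci$median, ci$ci_low, ci$ci_high)
#> [1] "median D = 0.064 um2/s (95% CI -0.001-0.169)"
```

The free cargo fraction of 0.117 at 100 nM importin is the model's exact
prediction of near-complete inhibition; with 3.5 µM Ran-GTP added the
fraction returns to >0.999. Per-track D̂ values are noisy on 20-frame
tracks (negative localization-variance estimates are legitimate and
reported as-is); condition-level summaries use medians over hundreds of
tracks. An end-to-end experiment (manifest of TIFF stacks → binding,
diffusion, oligomer and statistics tables) runs through `run_pipeline()`,
or from a shell via `inst/cli/tirfsm simulate|run`.

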