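# flics

Simulation and reconstruction for **compressed-sensing fluorescence
lifetime imaging** (FLI) with time-resolved single-pixel detection.

Wide-field macroscopic FLI instruments illuminate the sample with binary
Hadamard patterns and record, for each pattern, a time-resolved photon
histogram on a single detector. Recovering images from such data means
solving, for every time gate *t*, the underdetermined linear system

&nbsp;&nbsp;&nbsp;&nbsp;**P** · *I*(t) = **S**(t)

(**P** the pattern matrix, **S** the measured traces), and then estimating
each pixel's fluorescence lifetime τ from its reconstructed temporal point
spread function (TPSF), modeled as a mono-exponential decay
*A·e^(−t/τ)* convolved with the instrument response function (IRF).

`flics` implements, in pure R on BLAS primitives:

* a **synthetic phantom generator** — glyph-like 32×32 scenes with
  per-region lifetimes (0.3–1.5 ns) and photon levels from 25 to 1600
  counts, emulating handwritten-character training corpora with no
  download;
* the **forward model** — decay sampling, IRF convolution,
  sequency-ordered Hadamard projection (512 of 1024 patterns by default),
  Poisson noise;
* **TVRecon**, the classical route — per-gate total-variation regularized
  inversion (augmented-Lagrangian/ADMM) followed by counts-weighted
  log-linear tail fitting with background zeroing;
* **Net-FLICS-style direct reconstruction** — a residual convolutional
  network mapping the raw 256×512 measurement straight to the intensity
  and lifetime images, trained with the sum of intensity and lifetime MSE
  (lifetime weighted 1e5), RMSprop, a halve-every-10-epochs schedule and
  early stopping; the measurement-to-pixel layer is initialized at the
  pattern bank's pseudo-inverse so desk-scale CPU training converges;
* an **evaluation harness** — MAE, SSIM, region statistics,
  photon-level stratification — plus a dataset container, seeded
  configuration/pipeline runner and a thin command-line wrapper
  (`inst/cli/flics.R`).

For whom: researchers prototyping single-pixel FLI reconstruction methods,
and anyone needing a fully simulated, ground-truthed testbed for
lifetime-imaging algorithms.

## Worked example

```r
library(flics)

axis <- temporal_axis()                    # 256 gates x 40 ps
irf  <- gaussian_irf(axis)                 # FWHM 0.2 ns, peak 1.0 ns
bank <- build_hadamard_bank(1024, 512)     # 512 sequency-ordered patterns

# one scene: a glyph at photon level 3 (400-1600 counts)
scene <- make_scene(list(make_glyph(1)), level = "3", rng_seed = 5)
print(scene)

sample <- simulate_sample(scene, bank, irf, axis, rng_seed = 42)
print(sample$measurements)

rec <- reconstruct_tv(sample$measurements, bank, gate_bin = 4)
print(rec)

rep <- evaluate_recon(list(rec), list(scene))
print(rep)
```

```
<lifetime_scene> scene_5: 32x32, 166 fg px, max 1241.27 counts, tau 0.934-0.934 ns, level 3
<measurement_set> 256 gates x 512 patterns (noisy), bank hadamard1024_k512_sequency_hadamard_pos
<recon_result> tvrecon: 32x32, total 1.758e+05 counts, fg tau 0.643-3.98 ns
<eval_report> tvrecon on 1 samples
  intensity_mae     41.0230 +/- NA
  lifetime_mae       0.0579 +/- NA
  lifetime_mae_fg    0.1703 +/- NA
  intensity_ssim     0.8696 +/- NA
  lifetime_ssim      0.7787 +/- NA
```

The scene carries one dye (τ = 0.934 ns). Over the whole image the
reconstructed lifetime map is off by 0.058 ns on average (most pixels are
background, forced to exactly 0 on both sides); over the 166 foreground
pixels the mean error is 0.17 ns, dominated by the glyph's dim soft edge
where tail fits run out of photons — the bright core sits close to the true
value, as the fitted range shows. `predict_netflics()` produces the same `recon_result` shape from a
trained network (`build_model()` + `train_netflics()`), and
`run_pipeline()` chains simulate → reconstruct → evaluate with one seeded
configuration.

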