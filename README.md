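# nativenoise

Denoising very low-field MRI with **native noise modeling**, in R.

Portable low-field MRI scanners (B0 ≤ 0.3 T, down to 0.05 T) are cheap
and accessible but severely noise-limited. Learning-based denoisers need
paired noisy/clean images, which such scanners cannot produce, so
training pairs are usually synthesized by corrupting high-field images
with Gaussian noise. That is the wrong distribution: the noise in a
magnitude MR image is **Rician** — Gaussian in the real and imaginary
channels of the complex acquisition, Rayleigh in the magnitude
background where the true signal is zero.

`nativenoise` implements the alternative: measure the target scanner's
noise level from the corner patches of its images (SNR = mean ROI signal
/ corner noise sd), then **iteratively inject Gaussian noise into the
complex domain** of clean images,

    I_r^i = I_r^(i-1) + ρ·n1,  I_m^i = I_m^(i-1) + ρ·n2,  n ~ N(0, σ²)
    I_s   = sqrt(I_r² + I_m²)

re-measuring the magnitude SNR each iteration until it matches the
target — producing training pairs whose noise is natively Rician. A
compact U-Net denoising autoencoder (base 8 channels, depth 4, MSE loss,
Adam, validation-PSNR model selection) is trained patch-wise on these
pairs and applied to whole images in a single fully convolutional
forward pass. Evaluation machinery covers corner-patch SNR and SNR gain
(dB), PSNR, SSIM, 95% confidence intervals, paired t-tests, difference
maps, line-intensity profiles, and effective receptive fields. A seeded
generator of brain-like and phantom test images makes the whole pipeline
runnable and testable on one CPU without external data.

## Worked example

Simulate a 0.05 T-like acquisition from a clean synthetic brain slice
and check what the simulator did:

```r
library(nativenoise)

clean <- make_clean_image(synthetic_spec("brain_like", size = 256, seed = 1))
profile <- lf_noise_profiles()$invivo     # SNR 4.17, the 0.05T in vivo profile
sim <- simulate_native_noise(clean, profile, sim_config(seed = 42))

estimate_snr(sim$image)
#> <snr_result> SNR 4.247 (12.56 dB); signal 0.9479, noise sd 0.2232, ROI 38 px
nrow(sim$trace)
#> [1] 4690
background_distribution_test(sim$image, "rayleigh")$p_value
#> [1] 0.8478148
background_distribution_test(sim$image, "gaussian")$p_value
#> [1] 0.0001789362
```

The simulator needed 4,690 small noise injections (ρσ = 0.005 per step)
to bring this slice from noise-free down to the measured SNR of 4.25 —
within the 2% stopping tolerance of the 4.17 target — and the resulting
background is statistically Rayleigh (KS p = 0.85) and decidedly not
Gaussian (p < 0.001), which is precisely the property Gaussian-corrupted
training data lacks.

The full experiment — native-noise and Gaussian-noise training sets from
the same clean volumes, two identically configured U-Nets, comparison on
native-noise test slices — runs from a single config:

```r
res <- run_experiment(experiment_config(list(seed = 1, out_dir = "run1")))
res$report
```

or from the shell via the thin CLI:

```sh
Rscript inst/cli/nativenoise.R run --config exp.yaml
```

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic images | `synthetic_spec`, `make_clean_image`, `make_volume`, `make_lf_test_set` |
| Noise model | `estimate_noise_std`, `estimate_snr`, `magnitude_to_complex`, `add_noise_step`, `simulate_native_noise`, `simulate_random_noise`, `background_distribution_test`, `lf_noise_profiles` |
| Patch datasets | `paired_slice`, `split_dataset`, `extract_patches`, `write_patchset`/`read_patchset` |
| Denoiser | `unet_config`, `build_unet`, `train_denoiser`, `denoise_image`, `compute_erf`, `save_checkpoint`/`load_checkpoint` |
| Evaluation | `mse`, `psnr`, `ssim`, `snr_gain`, `paired_ttest`, `difference_map`, `line_profile`, `evaluate_methods`, `write_metric_report` |
| Orchestration | `experiment_config`, `validate_config`, `run_experiment`, `derive_seed`; CLI at `inst/cli/nativenoise.R` |

The methods vignette (`vignettes/native-noise-denoising.Rmd`) documents
the model, conventions (corner patches, population sd, dB), design
decisions, and the desk-scale problem sizes the tests use.
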