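# uitrans

Volumetric restoration of low-dose light sheet fluorescence microscopy
(LSFM) with a dual-branch CNN-transformer ("UI-Trans") network, plus the
full workflow around it: a synthetic LSFM degradation simulator, rigid
pixel-level registration, quantitative evaluation metrics, tiled
inference, and post-acquisition cardiac-cycle synchronization for 4D
(3D + time) heartbeat reconstruction.

## The problem

Fast volumetric imaging of living, beating hearts forces economical
acquisitions: milliseconds of exposure at minimal laser power with plain
full-frame detection. Such volumes are doubly degraded — photon-limited
noise from the restricted light budget, and a long-range *scattering
haze*, the signal-correlated background that tissue scattering spreads
over the image and that no exposure increase removes. Confocal
line-scanning LSFM suppresses the haze and, at high dose, produces clean
volumes, but requires ~3000x the light and 30x the time — incompatible
with live time-lapse imaging.

The approach implemented here trains a network on paired acquisitions of
fixed specimens (economical input vs. confocal high-dose ground truth),
then restores economical acquisitions alone. The network couples a
convolutional U-Net encoder branch (local detail) with a parallel
multi-headed self-attention branch over interval-extracted global tokens
(long-range context); per stage both branches are down-sampled and
channel-concatenated, and a convolutional decoder with skip connections
restores the input resolution. Training minimizes

    L_total = L_MAE + lambda * L_perc,      lambda = 0.01

the volumetric mean absolute error plus a perceptual feature distance
computed on 2D z-slices under a frozen convolutional extractor, optimized
with ADAM on a seeded 9:1 train/validation split.

Because the original acquisitions are not publicly deposited, the package
ships a physics-motivated simulator (anisotropic PSF blur; additive
wide-kernel scattering haze scaled by a confocal rejection factor;
Poisson-Gaussian photon noise) that generates aligned training pairs and
beating 4D sequences, so every component is exercisable and tested end to
end on synthetic data. See the methods vignette
(`vignettes/uitrans-methods.Rmd`) for the model, assumptions and design
choices.

## Worked example

```r
library(uitrans)

# simulate 40 aligned input/ground-truth pairs (32^3 voxels)
pairs <- simulate_training_pairs(40, c(32, 32, 32), seed = 20260926)

# fit the desk-scale network: 9:1 split, ADAM, MAE + 0.01 * perceptual loss
fit <- uitrans(pairs,
               config = uitrans_config_desk(),
               train  = train_config(learning_rate = 1e-3, epochs = 4,
                                     patch_size = c(32, 32, 32), seed = 101),
               seed = 7)
print(fit)
#> Dual-branch CNN-transformer restoration fit
#> <uitrans_model> 3 stages, base 8, heads 4, token stride 2, conv+transformer
#>   1,883,225 parameters (seed 7)
#>   trained 144 steps over 4 epochs; best val loss 0.028909 (epoch 4)
#>   train/val volumes: 36 / 4

# restore a held-out volume and score it
p   <- pairs[[fit$split$val_idx[1]]]
res <- predict(fit, p$input)
metric_report(normalize_volume(p$input), res, normalize_volume(p$ground_truth))
#>    volume   nrmse pearson psnr_db   ssim  snr_db contrast contrast_enhancement
#>     input 0.22205  0.3275   13.07 0.1365 -0.4091   0.2310                1.000
#>  restored 0.04833  0.9675   26.32 0.7930 17.7457   0.7340                3.177
#>        gt 0.00000  1.0000  120.00 1.0000 18.9276   0.7391                3.199
```

The restored volume recovers almost all of the ground truth's masked SNR
(+18 dB over the input), suppresses the haze (contrast enhancement 3.18x
against 3.20x for the ground truth itself), and raises voxelwise fidelity
(Pearson 0.33 -> 0.97, NRMSE 0.22 -> 0.05). Numbers vary slightly with
the simulation seed.

4D reconstruction from per-slice movies:

```r
ph   <- generate_heart_phantom(c(20, 24, 24), seed = 4)
beat <- deform_beating(ph, n_frames = 10, period_frames = 10, amplitude = 0.08)
mov  <- make_slice_movies(beat, T_frames = 40, noise_sd = 0.02, seed = 17)
hb   <- synchronize_movies(mov)  # period auto-estimated; warns on the few
                                 # edge slices that carry no cardiac signal
hb$period_frames
#> [1] 10
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/uitrans-cli.R` (subcommands `simulate`, `train`, `align`,
`evaluate`, `restore`, `sync4d`); see `?uitrans_cli`.

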