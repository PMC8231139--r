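# carpo

Quantification of dynamic wrist movement from real-time MRI sequences.

## The problem

Dynamic carpal instability — pathologic kinematics of the carpal bones that
appears only during motion — eludes static imaging. Real-time MRI of the
wrist during continuous radial–ulnar deviation ("waving") produces about ten
frames per second, far too many to evaluate by hand. carpo implements a
fully automatic processing chain for such 2D+time sequences, aimed at
researchers in musculoskeletal imaging:

1. **Preprocessing** — per-image 10th/99th-percentile clipping, Z-score
   normalization, and biquadratic 2× upsampling (168 × 168 at 1.0 mm/px →
   336 × 336 at 0.5 mm/px) with matching polygon-annotation scaling.
2. **Segmentation** — a classic symmetric U-Net (two 3×3 conv + BN + ReLU
   per level, 2×2 max-pooling, transposed-conv decoder, 1×1 head over 64
   features) scoring eight bone classes — radius, ulna, scaphoid, lunate,
   triquetrum, hamate, capitate, trapezium/trapezoid — plus background,
   trained with the unweighted sum of a soft-Dice loss and a
   distance-transform Hausdorff loss under Adam with multi-step learning-rate
   decay.
3. **Post-processing** — mean-field CRF refinement, Gaussian-weighted
   temporal label voting over a five-frame window (cumulative allocation
   0–5, threshold 0.6 on the mean), opening/closing with a 5-pixel cross,
   and largest-connected-component selection per class.
4. **Measurement** — per frame: the scapholunate (SL) and lunotriquetral
   (LT) gap widths, measured where the carpal-arc centerline (medial axis of
   the fused proximal row, spline-smoothed) crosses the facing bone
   cortices, and the wrist angle from the minimum-area bounding boxes of the
   forearm and the distal carpal row (radial negative, ulnar positive).
5. **Evaluation** — per-class Dice coefficients, Bland–Altman limits of
   agreement, subject-level train/test splits, and equal-interval selection
   of 15 frames per movement cycle.

Because clinical dynamic wrist MRI cannot be redistributed, the package
includes a synthetic articulated-wrist **phantom** (`phantom_spec()`,
`generate_sequence()`): eight parametric bones sweeping from −15° (radial)
to +35° (ulnar) with known, angle-dependent gap widths — including an
SL-ligament-injury mode (SL ≈ 4 mm radially, collapsing toward 1 mm in deep
ulnar abduction) — plus pixel-perfect label masks and truth curves, so the
whole chain is testable end to end. See the methods vignette
(`vignettes/carpo-methods.Rmd`) for models, parameter choices and
limitations.

## Worked example

Generate a short noise-free phantom, measure it from its own truth masks,
and compare against the built-in truth:

```r
library(carpo)
spec <- phantom_spec(duration_s = 4, frame_interval_ms = 200,
                     native_size_px = 84, noise_sigma = 0, seed = 1)
ph <- generate_sequence(spec)
metrics <- quantify_sequence(ph$truth$masks, ph$truth$mask_spacing_mm,
                             frame_interval_ms = 200)
head(round(metrics[, 1:5], 2))
#>   frame time_ms wrist_angle_deg sl_gap_mm lt_gap_mm
#> 1     1       0          -15.06      2.00      1.47
#> 2     2     200          -13.79      2.00      1.40
#> 3     3     400          -10.14      2.00      1.35
#> 4     4     600           -4.65      1.84      1.32
#> 5     5     800            2.00      1.69      1.18
#> 6     6    1000           10.02      1.79      1.23
```

The wrist sweeps from the radial extreme toward ulnar deviation; the healthy
SL gap stays near 1.7 mm (the first frames read high by a fraction of a
pixel) and the LT gap near 1.3 mm, with the slight decrease toward ulnar
angles built into the truth model. Recovery accuracy over the sweep:

```r
round(c(max_sl_err = max(abs(metrics$sl_gap_mm - ph$truth$sl_mm)),
        max_lt_err = max(abs(metrics$lt_gap_mm - ph$truth$lt_mm)),
        max_angle_err = max(abs(metrics$wrist_angle_deg - ph$truth$angle_deg))), 3)
#>    max_sl_err    max_lt_err max_angle_err
#>         0.280         0.207         0.277
```

i.e. gaps within 0.3 mm (about half an interpolated pixel) and angles within
0.3°. Agreement between measured and true SL gaps in Bland–Altman terms:

```r
bland_altman(metrics$sl_gap_mm, ph$truth$sl_mm)
#> Bland-Altman agreement (n = 20)
#>   mean difference 0.1094, SD 0.1241
#>   limits of agreement [-0.1339, 0.3527]
```

Training and segmenting (`unet_spec()`, `train_unet()`,
`predict_sequence()`, `run_postprocess()`) follow the same pattern; the
`exec/carpo` script exposes the chain as shell subcommands
(`simulate`, `preprocess`, `train`, `segment`, `postprocess`, `quantify`,
`bins`, `evaluate`, `agree`, `run`, `demo-injury`), e.g.

```sh
exec/carpo simulate --out sim/ --duration 30 --interval 100
exec/carpo quantify --masks sim/masks.nii.gz --spacing 0.5 --out metrics.csv
exec/carpo demo-injury --out demo/ --seed 1
#> mean radial SL separation: 2.2 mm; separated: TRUE
```

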