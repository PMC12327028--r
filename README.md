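# octavess

3D OCT angiography (OCTA) processing and vessel quantification for skin
imaging, in R.

OCTA examinations of skin yield two aligned volumes: a structural OCT
volume and an angiographic decorrelation volume in which flowing blood is
bright. Tracking inflammatory skin disease (e.g. atopic dermatitis in the
mouse ear) calls for *3D* readouts — layer thickness and dermal
microvascular metrics — but raw decorrelation volumes carry Gaussian and
salt-and-pepper noise, motion-induced stripe artifacts and axial tails
under large vessels, and most existing analyses flatten to 2D en face
images, discarding the curved depth structure. `octavess` implements a
complete, tested processing chain for this problem, exercised end to end
on synthetic phantoms with exact ground truth:

* **Phantoms** — seeded generators for layered speckled tissue (curved
  epidermis/dermis boundaries, Gamma speckle) and tubular vascular volumes
  with configurable noise, stripe, and tail artifacts, plus frozen
  ground-truth masks and centerlines.
* **Segmentation** — CLAHE-enhanced B-scans fed to a compact U-Net
  (native RcppArmadillo forward/backward, Adam, weighted cross-entropy +
  soft Dice, k-fold cross-validation), boundary surfaces AB1/AB2/AB3,
  boundary-error evaluation and per-layer thickness maps.
* **Curvelet denoising** — an exactly tight 3D curvelet frame
  (machine-precision Parseval and inversion) with scale-dependent hard
  thresholding, keeping a coefficient iff |c| ≥ C(s)·σ̂, and
  direction-selective stripe suppression in sub-bands aligned with the
  stripe orientation.
* **OOF enhancement** — the oriented-flux matrix
  Q_ij(x, r) = ∮ ∂_i(G*f)(x + r n) n_j r² dΩ computed spectrally, per-voxel
  eigenvalues λ1 ≤ λ2 ≤ λ3, and the multi-radius response
  R(x) = max_{2≤r≤6} max(−(λ1+λ2)/2 / r², 0).
* **Vesselization** — 5×5×5 Gaussian smoothing, global (Otsu/fixed/
  percentile) thresholding, 26-connected small-component removal, and
  topology-preserving 3D thinning to a 1-voxel skeleton.
* **Metrics** — vessel area VA, skeleton length VS, and dermis-restricted
  densities VAD = VA/|dermis|, VSD = VS/|dermis|, in 3D and on en face
  maximum-intensity projections, plus the longitudinal statistic
  mean(|v_{i+1} − v_i| / v_i) ("average rate of change") with a bundled
  published reference time course (`ad_timecourse()`).
* **Pipeline** — `run_pipeline()` orchestrates all stages over many
  timepoints with YAML configuration, TIFF/NIfTI I/O with JSON sidecars,
  config-hash provenance and byte-identical reruns; `inst/cli/octa` is a
  thin shell front end.

## Worked example

Simulate a two-day vascular phantom series, run the full chain, and read
the metrics:

```r
library(octavess)

# a noisy angiographic phantom with known truth
ph <- make_vessel_volume(vessel_phantom_spec(
  c(48, 48, 48),
  tubes = list(tube(c(24, 5, 24), c(24, 44, 24), radius = 3, intensity = 1)),
  gaussian_sigma = 0.1, stripe_count = 5, seed = 5))

den  <- denoise_volume(ph$volume)         # curvelet hard threshold + stripe filter
resp <- oof_response(den, radii = 2:6)    # tubular enhancement
vz   <- vesselize(resp, min_volume = 27)  # smooth -> Otsu -> filter -> skeleton

dermis <- array(1L, dim(ph$mask))         # whole volume as ROI here
vessel_metrics(vz$binary, vz$skeleton, dermis, day = 0)
#> # A tibble: 8 × 4
#>     day dims  parameter       value
#>   <dbl> <chr> <chr>           <dbl>
#> 1     0 3D    VA        4157
#> 2     0 3D    VS          44
#> 3     0 3D    VAD          0.0376
#> 4     0 3D    VSD          0.000398
#> 5     0 2D    VA         506
#> 6     0 2D    VS          44
#> 7     0 2D    VAD          0.220
#> 8     0 2D    VSD          0.0191
```

VA counts vessel voxels (here the rasterized tube plus the halo the
enhancement-smoothing-threshold chain admits around it), VS counts
skeleton voxels (≈ the 40-voxel centerline plus short spurs), and VAD/VSD
are those counts divided by the ROI size. The longitudinal statistic on
the bundled reference series:

```r
summarize_rates(ad_timecourse())
#> # A tibble: 8 × 5
#>   dims  parameter n_days  rate rate_3dp
#>   <chr> <chr>      <int> <dbl>    <dbl>
#> 1 2D    VA             8 0.211    0.211
#> 2 2D    VAD            8 0.168    0.168
#> 3 2D    VS             8 0.211    0.211
#> 4 2D    VSD            8 0.168    0.168
#> 5 3D    VA             8 0.289    0.289
#> 6 3D    VAD            8 0.229    0.229
#> 7 3D    VS             8 0.273    0.273
#> 8 3D    VSD            8 0.186    0.186
```

Every 3D parameter changes by at least 10% per timepoint on average —
the 3D readouts are more sensitive to disease progression than their 2D
counterparts (0.289 vs 0.211 for VA).

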