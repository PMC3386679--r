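# SurfaceDP

Boundary detection for round, bright objects through whole image
sequences — built for quantifying the cross-sectional lumen area of an
artery (e.g., the superficial femoral artery in ECG-gated MRI cine
stacks) where single frames can have vague or invisible boundaries.
Instead of detecting each frame independently, the successive closed
contours are treated as one surface through a volumetric feature matrix
and extracted jointly, so frames without usable evidence are bridged by
their neighbours.

## The method

Each frame is resampled to polar coordinates around a supplied centre
(closed contour → left-to-right path), with the signed radial intensity
gradient as boundary evidence, bicubic upsampling by a resize factor to
refine the radial quantisation, and per-frame min–max normalisation so
the strongest boundary evidence maps to 0.  A two-pass dynamic
programme then extracts the minimal-cost height field *y(x, z)* (radius
per angle *x* and frame *z*) from the volume *R* (radius × angle ×
frame):

    C1(y, x, z) = min_{|i| ≤ d1} ( C1(y+i, x−1, z) + α1·|i| ) + R(y, x, z)
    C2(y, z, x) = min_{|i| ≤ d2} ( C2(y+i, z−1, x) + α2·|i| ) + C1(y, x, z)

The first pass links nodes along the angle axis within a frame, the
second along the frame axis at fixed angle on top of the first; the
surface is traced backwards per angle from the minima of the final
depth column of C2, which makes the frame-direction smoothness bound
`d2` hold by construction.  Tracing the first pass instead
(`traceC1 = TRUE`) reproduces the traditional per-frame 2D dynamic
programme, the baseline the joint search is compared against.  Areas
come from the shoelace formula on the back-transformed Cartesian
polygons; agreement against reference areas is summarised as relative
unsigned errors (|A_ref − A_auto| / A_ref × 100 %) and Bland–Altman
statistics (mean difference ± 1.96 SD limits of agreement).

A disc-phantom simulator (41×41 frames, foreground 1.0, background
0.4, radii 9→12→8, Gaussian σ = 0.5, zero-mean uniform noise calibrated
to a target per-pixel log-SNR) makes all accuracy experiments
self-contained; see the methods vignette
(`vignettes/optimal-surface-detection.Rmd`) for the model, parameter
semantics, numerical conventions and known limitations.

## Worked example

Generate a noisy phantom at 14 dB, detect all eight contours jointly,
and compare with the analytic disc areas:

```r
library(SurfaceDP)

spec   <- phantomSpec()                                  # 41x41, radii 9..12..8
nLevel <- calibrateNLevel(spec, targetSnrDb = 14, seed = 1)   # 0.2595
ph     <- addNoise(generatePhantom(spec), nLevel, seed = 1)
ph
#> PhantomSequence: 8 frames of 41x41, radii 9,10,11,12,11,10,9,8
#>   nLevel 0.2595, mean SNR 13.91 dB

det <- detectSequence(ph, s = 0.01, resizeFactor = 1.6, d1 = 1, d2 = 2)
cbind(det$areas, true = trueAreasPx2(ph),
      errorPct = relativeUnsignedError(det$areas$areaPx2, trueAreasPx2(ph)))
#>   frame areaPx2 areaMm2   true errorPct
#> 1     1  257.20  257.20 254.47     1.07
#> 2     2  308.37  308.37 314.16     1.84
#> 3     3  377.92  377.92 380.13     0.58
#> 4     4  428.21  428.21 452.39     5.35
#> 5     5  369.15  369.15 380.13     2.89
#> 6     6  309.97  309.97 314.16     1.33
#> 7     7  248.30  248.30 254.47     2.42
#> 8     8  197.43  197.43 201.06     1.81
```

The mean relative unsigned error of this run is 2.16 %; the largest
error sits on the largest disc (r = 12), whose hard-thresholded
rasterisation is ~2.5 % smaller than π·12² to begin with (the vignette
quantifies this rasterisation gap).  `blandAltman()` on the same pair
of area vectors reports a bias of −6.80 px² with limits of agreement
[−22.51, 8.91] px².

The same pipeline is scriptable from a shell via `exec/surfacedp`
(subcommands `phantom`, `detect`, `sweep`, `evaluate`), e.g.

```sh
surfacedp phantom --snr 14 --seed 1 -o seq.tif --truth truth.csv
surfacedp detect seq.tif --s 0.01 --resize 1.6 -o detected
surfacedp evaluate --auto detected_areas.csv --manual truth.csv -o eval.json
```

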