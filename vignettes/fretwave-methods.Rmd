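---
title: "Methods: sensitized-emission ratio imaging and wave analytics in fretwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitized-emission ratio imaging and wave analytics in fretwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Intermolecular FRET biosensors for small RhoGTPases report activation as
sensitized emission: on donor excitation, acceptor fluorescence rises where
the GTPase-donor chain binds its effector-acceptor chain. The raw acceptor
("FRET") channel of a dual-view acquisition is, however, contaminated by
optical nuisances that have nothing to do with GTPase activity: uneven
illumination (shading), camera background, donor emission bleeding through
the acceptor filter, photobleaching, and shot/read noise. `fretwave`
implements the standard two-image sensitized-emission correction chain and
the downstream analytics used to quantify growth-cone edge dynamics and
traveling activity waves, together with a forward simulator that makes every
stage testable by parameter recovery.

## Forward model

For pixel $x$ and frame time $t$, with sensor density $\rho(x)$ (intensity
units), dimensionless activity $a(x,t)$ ($a = 1$ at rest), unit-mean shading
fields $S_d, S_a$, backgrounds $b_d, b_a$, photobleach factors
$B_c(t) = e^{-k_c t}$ and donor bleedthrough $\alpha$:

$$D(x,t) = S_d(x)\,B_d(t)\,\rho(x) + b_d + \varepsilon$$
$$A(x,t) = S_a(x)\,B_a(t)\,\big(c\,\rho(x)\,a(x,t) + \alpha\,\rho(x) +
  \beta X_{acc}(x)\big) + b_a + \varepsilon$$

$c$ is a calibration constant and $\beta X_{acc}$ the direct
acceptor-excitation term, off by default because the modeled protocol
acquires only the donor and FRET channels through an image splitter (no
third image exists to correct with; the `correct_fret()` provenance records
when the $\beta$ term is omitted). Noise $\varepsilon$ is
$\mathrm{Poisson}(g\,\mu)/g + \mathcal{N}(0, \sigma_r)$ followed by 16-bit
quantization; with `noise = FALSE` the simulator returns the analytic,
unquantized movie, which serves as the exact oracle limit (this is also why
conservation tests hold to 1e-6 only in noise-free mode — quantization is
treated as part of the noise stage).

Note that the bleedthrough term is written on the sensor density, not on the
bleached donor signal: the donor bleedthrough photons traverse the acceptor
arm of the splitter and bleach with the acceptor-channel factor. This makes
the correction chain exactly invertible for any pair $(k_d, k_a)$, which is
what a linear two-image correction assumes.

## Correction chain

The order is fixed and recorded in provenance (shading and background do not
commute):

1. **Registration** — the image splitter produces a fixed offset; a rigid
   integer translation is estimated once by FFT cross-correlation of frame 0
   and applied to the whole acceptor stack. A normalized peak correlation
   below 0.5 aborts with an "unregistered channels" error.
2. **Shading + background** — $(I - b)/S$ per frame, clipped at 0. With
   `background = "auto"`, $b$ is the per-frame median outside a dilated
   provisional Otsu mask.
3. **Photobleach (optional)** — the in-mask mean is fit to
   $I_0 e^{-kt}$ by least squares on log means; the frame-wise division is
   applied only when the exponential fit reduces residual variance by more
   than 5% against a constant fit. The modeled acquisition protocol treats
   this correction as optional; the variance-reduction trigger is this
   package's operationalization. Per-channel correction (rather than correcting the
   final ratio) is adopted.
4. **Bleedthrough** — $\alpha$ is estimated from a donor-only control as
   the robust through-origin slope (Theil-Sen, median of pixel ratios) of
   FRET-channel vs donor-channel intensity, with a bootstrap SE; ordinary
   least squares on the same pixels is kept as an independent test oracle
   only. Corrected FRET $= A - \alpha D$ (minus $\beta X_{acc}$ when a
   direct-excitation image exists).
5. **Masking** — per-frame Otsu threshold on the corrected donor (the
   highest-SNR channel), then largest connected component and hole filling.
   Otsu was chosen because the protocol states only "thresholding" and the
   donor is strongly bimodal; it is parameter-free and monotone (raising
   the threshold never grows the mask).
6. **Ratio** — corrected FRET / corrected donor, defined only inside the
   mask where the donor exceeds `eps` (default 0.05) times the in-mask
   donor median. The floor suppresses ratio blow-up at the dim cell rim;
   because both channels scale with $\rho$, the ratio itself is
   density-independent and rim pixels that pass the floor are unbiased.

The Methods-style definition ratio = corrected FRET / donor is used
throughout (the narrative "GFP/mCherry ratio" phrasing in the source
experiments is interpreted as this operational definition).

## Edge dynamics

Edge ROIs are 10 x 20 um rectangles whose length axis (the scan axis) points
outward across the local edge. For each frame the corrected-donor intensity
is sampled by bilinear interpolation along the central line at quarter-pixel
steps; the edge is the outermost above-to-below-threshold crossing (using
that frame's mask threshold), linearly interpolated between the bounding
samples. Scanning from outside inward and keeping the outermost crossing
prevents filopodial gaps behind the rim from registering as the edge.
The rendered cell has a one-pixel anti-aliased rim, so the sub-pixel
estimator has real signal; on noise-free drifting edges its mean error is
below 0.25 px.

A section's **mean velocity** is net displacement over the trace span
(endpoints averaged over 5 frames), which is the time average of the
instantaneous velocity. Classification: $|\bar v| \le v_0$ stalling,
$\bar v > v_0$ protruding, $\bar v < -v_0$ retracting, with
$v_0 = 0.005$ um/s by default (about one pixel per 100 s at 0.5 um/px; the
source protocol never states its criterion, so $v_0$ is configuration with
this stated default — slow-motion presets set $v_0 = 0.002$). Traces shorter
than 60 s are left unclassified. Velocity traces use central differences on
a 5-frame moving average because 1 s sampling of um/min motions is
noise-dominated at the single-frame level.

Class quantification averages defined ratio pixels inside the rectangle that
lie within 5 um inward of the detected per-frame edge, restricted to a 6 um
central strip of the 10 um rectangle so that adjacent angular sections do not
cross-contaminate the per-section means. Class summaries are normalized by
the stalling-class mean, making the stalling mean exactly 1.

## Activity traces and waves

Trace ROIs are 4 um^2 squares placed in the cell interior so edge motion
cannot interfere (a warning fires if the ROI touches undefined pixels in
more than 5% of frames). $\Delta F/F_0 = (F - F_0)/F_0$ with $F_0$ the
first-frame value by default (`m = 1`; the reference protocol says "the
intensity at the first frame", and `m` is configurable because an
early-frame average is sometimes preferable for noisy traces).

Maxima detection smooths with a 5 s centered moving average and keeps local
maxima with prominence at least 0.5 standard deviations of the smoothed
series. These two numbers are this package's operationalization of reading
"the time between two maxima" off a plot; they are appropriate for the
high-SNR traces the pipeline produces (ROI-mean relative noise well below
1%). For low-SNR traces (SNR near 3) the prominence should be raised to
1 SD — the graceful-degradation property (period within 10% in at least 90%
of runs at SNR 3 with 5+ cycles) is tested at that setting. Missing samples
in gaps up to 3 s are linearly interpolated; longer gaps split the trace and
maxima are detected per segment.

The period is the arithmetic mean of consecutive maxima intervals with the
SEM computed over intervals (matching the "mean period ± SEM of 10 periods"
convention); the headline estimates pool the first 10 intervals. An
autocorrelation-peak oracle (first local ACF maximum beyond lag zero) is
used in tests only and agrees within one frame interval on clean traces.

Onset latency after a stimulus uses baseline mean + 3 SD sustained for 5 s,
with at least 30 s of pre-stimulus baseline. The threshold rule is this
package's choice; the reference experiments report latencies without stating
one.

## The synthetic world

The simulated cell is **star-convex**: a disk whose boundary radius per
angular edge section follows the configured velocity schedule exactly,
i.e. the section's boundary arc is offset along the radial normal with
sub-pixel ground-truth positions (`edge_um`). For a locally circular
boundary this radial offsetting is exactly the signed-distance normal
offsetting one would implement for general shapes, while keeping the ground
truth closed-form. What it does not emulate: filopodia, concave growth-cone
outlines, membrane ruffling texture, or section-to-section coupling; a green
recovery test therefore establishes correctness of the measurement chain,
not robustness to arbitrary morphology.

Activity is baseline 1 plus Gaussian hotspots, a traveling cosine wave
$A\cos(2\pi(t/T - x/\lambda))$ restricted to a region and start time,
per-section multiplicative bands hugging the moving edge (depth 5 um), and a
clipped linear ramp after a stimulus. Defaults $T = 70$ s, $\lambda = 5$ um,
$A = 0.2$: the period is a seeded experimental value, while wavelength and
amplitude are unreported in the source experiments and are stated here once
as config defaults of the right order for retrograde GTPase waves.

Acquisition defaults emulate the modeled setup (1 s frames, 16-bit, 4x4
binning at high NA, hence 0.5 um/px): quadratic-bowl shading with 10%
peak-to-edge variation and unit mean (the acceptor bowl laterally offset by
10% of the field so shading does not cancel in the ratio), backgrounds 100
ADU, $\alpha = 0.6$, per-channel bleach $2\times10^{-4}$/s, gain 0.5,
read noise 2 ADU, sensor intensity scale 8000 ADU. Presets seed the
reference conditions: wave periods 70 s (bead stimulation), 110 s
(spontaneous), 155 s (vesicle stimulation); retracting/protruding activity
ratios 1.109/0.831 (RhoA) and hotspot/non-protruding 1.061/0.938 (Cdc42)
over 24 edge sections; a central activity ramp starting 10 s after a
stimulus at 60 s with rate 0.02/s (saturating at +1), which the 3 SD rule
detects around 12-13 s latency. None of these values were adjusted after
seeing test outcomes.

## Numerical choices and degenerate inputs

* Pixels are 0-based row-major with physical positions at pixel centers;
  frames count from 0 in time units.
* Frames whose Otsu threshold is undefined (constant image) are flagged
  degenerate with an empty mask; the photobleach stage refuses empty masks.
* Ratio pixels with non-positive corrected FRET are flagged undefined so
  defined ratio values are always finite and positive.
* `estimate_period()` refuses fewer than two maxima ("insufficient
  oscillations"); `detect_maxima()` may legitimately return an empty set.
* TIFF I/O is implemented in-package (baseline little-endian, uncompressed,
  grayscale, 8/16-bit unsigned or 32-bit float, one strip per page) because
  no TIFF package is available in the target environment; files carry pixel
  size and frame interval as JSON in the ImageDescription tag plus standard
  resolution tags, and were validated against an external TIFF reader
  during development. Undefined ratio pixels are written as NaN sentinels
  in the float32 ratio export.
* Bootstrap SEs for bleedthrough, and every simulation, derive their RNG
  stream from the scenario seed, so identical (config, seed) inputs yield
  byte-identical reports.

## Known limitations

* Registration is integer-pixel rigid translation only, which matches the
  splitter geometry being modeled but not chromatic scaling or rotation.
* The donor channel of the forward model is activity-independent; real
  intermolecular sensors lose some donor signal under FRET. Because the
  ratio normalizes by the donor, this affects calibration only, and class
  summaries are additionally stalling-normalized.
* FRET efficiency, donor lifetime, and acceptor-photobleaching FRET are out
  of scope; the ratio is a relative activity measure.
* The wave-period estimator assumes a quasi-stationary oscillation; it
  reports the mean of the leading intervals rather than tracking period
  drift.
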