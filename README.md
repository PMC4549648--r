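# fretwave

Sensitized-emission FRET ratio imaging and traveling-wave analytics for
RhoGTPase (RhoA/Cdc42) activity in growth cones — as a tested, reusable R
pipeline with a forward simulator, so every stage is verifiable by parameter
recovery without any real microscopy data.

## What it is for

Dual-view FRET biosensor movies report GTPase activation as acceptor
("FRET"-channel) emission under donor excitation, contaminated by shading,
camera background, donor spectral bleedthrough, photobleaching and
Poisson–Gaussian noise. `fretwave` implements:

* the **ratiometric correction chain**: channel registration → shading →
  background → optional photobleach (mono-exponential fit, applied only when
  it beats a constant fit) → bleedthrough subtraction (α from donor-only
  controls, robust Theil–Sen slope) → donor-Otsu cell mask → ratio
  `R = corrected FRET / donor`, defined only in-mask above a donor floor;
* **edge dynamics**: sub-pixel edge detection along 10 × 20 µm ROI center
  lines, stalling/protruding/retracting classification by mean edge
  velocity (threshold `v0`), stalling-normalized class-wise ratio
  summaries, and montage images;
* **activity traces and waves**: ΔF/F₀ = (F − F₀)/F₀ traces in 4 µm²
  ROIs, smoothed-prominence maxima detection, wave period as the mean ±
  SEM of consecutive maxima intervals (10 pooled), and stimulus onset
  latency via a baseline + 3 SD sustained-crossing rule;
* a **synthetic two-channel movie generator** (star-convex cell, scheduled
  edge-section motion, hotspots, traveling cosine waves, stimulus ramps,
  full acquisition nuisances, 16-bit multi-page TIFF output with a
  ground-truth sidecar) plus a recovery scorecard, used as the oracle for
  the whole pipeline.

Bundled presets seed the reference experimental conditions: Cdc42 wave
periods 70 s (bead stimulation), 110 s (spontaneous) and 155 s (lipid
vesicles); RhoA edge-class activity ratios 1.109 (retracting) / 0.831
(protruding); Cdc42 1.061 (hotspot) / 0.938 (non-protruding); RhoA
activation within 30 s of a local stimulus.

## Worked example

Simulate the bead-stimulation preset, analyze it, and score recovery:

```r
library(fretwave)
fw_simulate("cdc42_beads", "scn", seed = 5)   # donor.tif, acceptor.tif, truth.json, ...
rep <- fw_analyze("scn", "out")               # report.json, edges.csv, mask.tif, ...
rep$waves$wave$period_s
#> [1] 69.6
rep$waves$wave$sem_s
#> [1] 0.4760952
sc <- fw_recover("scn", "out")
sc$checks$period$abs_error_s
#> [1] 0.4
sc$pass
#> [1] TRUE
```

The recovered period (69.6 ± 0.48 s SEM over 10 maxima intervals) matches
the seeded 70 s wave; the scorecard also checks edge-velocity recovery,
section-label agreement and mask Jaccard against the ground truth sidecar.
On the spontaneous-RhoA preset the class summary reads:

```
       class mean_ratio normalized_mean sem_normalized n_sections
1   stalling  1.0017910       1.0000000   5.111042e-05         12
2 protruding  0.8327526       0.8312639   8.121939e-05          6
3 retracting  1.1107497       1.1087640   4.653310e-05          6
```

i.e. the seeded 1.109 / 0.831 retracting/protruding activity ratios are
recovered to 0.03 % after the full correction chain (the estimated
bleedthrough was α = 0.600 for a seeded 0.6). On the stimulated preset the
detected onset latency was 13 s for a ramp starting 10 s post-stimulus.

## Command line

```sh
FW=$(Rscript -e 'cat(system.file("exec/fretwave", package="fretwave"))')
Rscript $FW simulate --preset cdc42_beads --seed 5 --out scn
Rscript $FW analyze  --in scn --out rep [--skip-photobleach]
Rscript $FW recover  --scenario scn --analysis rep
Rscript $FW report   --analysis rep
```

## Package layout

* `R/` — TIFF I/O, channel containers, scenario config + presets,
  simulator, correction chain, edge dynamics, wave analytics, pipeline +
  CLI.
* `inst/presets/*.yaml` — the five scenario presets.
* `vignettes/fretwave-methods.Rmd` — model, assumptions, parameter
  defaults and their rationale, numerical choices, limitations.
* `tests/testthat/` — unit + property tests per module and
  `test-acceptance.R` with the acceptance criteria.
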