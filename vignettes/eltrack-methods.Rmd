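---
title: "Methods: how eltrack measures endolysosome behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how eltrack measures endolysosome behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eltrack)
```

`eltrack` turns multi-channel microscopy of endolysosomes (ELs) and the
endoplasmic reticulum (ER) into a small set of biological statistics:
how ELs move, how often and how persistently they contact ER protein
accumulations, how dispersed they are toward the cell periphery, what
fraction of their membrane is apposed to ER in electron microscopy, and
how many proximity-ligation (PLA) dots mark ER-EL apposition per cell.
This vignette explains each model and procedure, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
validation does and does not establish.

## Motion model and the moment scaling spectrum

A trajectory of positions $r_i$ sampled at interval $\Delta t$ has
displacement moments over lag $\delta = k\,\Delta t$:

$$\mu_\nu(\delta) = \big\langle\, |r_{i+k} - r_i|^\nu \,\big\rangle_i,
  \qquad \nu = 0, 1, \ldots, 6 .$$

For self-similar motion $\mu_\nu \propto \delta^{\gamma_\nu}$, and the
slope $S$ of $\gamma_\nu$ versus $\nu$ - the moment scaling spectrum
(MSS) slope - summarizes the motion type: $S = 0$ for a stalled
particle, $S = 1/2$ for Brownian motion ($\gamma_\nu = \nu/2$), and
$S = 1$ for ballistic transport ($\gamma_\nu = \nu$). `compute_mss()`
estimates $\gamma_\nu$ by least squares on $\log \mu_\nu$ versus
$\log\delta$ and anchors the $S$ fit through $(\nu = 0, \gamma = 0)$,
which holds identically because $\mu_0 \equiv 1$. The diffusion
coefficient comes from the $\nu = 2$ intercept via
$\mu_2 = 4D\delta$.

Numerical choices:

* **Lags** run from $k = 1$ to a quarter of the track span
  (`max_lag_fraction = 0.25`): long lags average few displacement pairs
  and dominate the fit variance.
* **Moment orders** are fixed at 0-6, the canonical MSS range; higher
  orders are increasingly noise-sensitive without adding
  discrimination.
* **Degenerate tracks** (every displacement zero) short-circuit to
  $S = 0$ rather than attempting a log fit on zeros.
* **Gap frames** from gap-closed linking simply contribute no pairs at
  the affected lags.

### Classification thresholds are calibrated, not fixed

The sampling distribution of $S$ for a genuinely Brownian track depends
on track length, frame interval and localization noise, so no fixed
cutoff separates the classes across acquisitions.
`calibrate_mss_thresholds()` simulates Brownian tracks under the
acquisition at hand and takes the 2.5th/97.5th percentiles of their
$S$ distribution as `S_low`/`S_high`; a free track is then
misclassified at most ~5% of the time by construction, and
`classify_motion()` calls *confined* below `S_low` and *directed* above
`S_high`. At 300 frames and 10 fps the band is roughly
$S \in [0.33, 0.60]$.

A track is *unclassified* when it is shorter than `min_track_len`
(default 20 frames), has fewer than 3 usable lags, or - for a
provisional free/directed call - when the order-2 log-log fit has
$R^2 <$ `min_R2` (default 0.8). The $R^2$ gate deliberately does not
veto confined calls: a strongly confined particle has a *flat* moment
spectrum, for which $R^2$ of a power-law fit is ill-posed exactly when
the confined call is clearest. Mobile and immobile confined
sub-behaviours are reported as a single confined class. For population
summaries, `summarize_motion()` pools free and directed into one
"motile" proportion and reports its ratio to confined, flagged
undefined when the confined count is zero.

## Synthetic trajectories: what the generator emulates

`simulate_trajectory()` implements the three kinetic classes as
*free* Brownian motion (per-axis increments $N(0, 2D\Delta t)$),
*directed* Brownian motion plus a constant drift $v\Delta t$ in a fixed
random direction, and *confined* Brownian motion reflected at the wall
of a disc of radius $R_c$. Hard reflection was chosen over a soft
(Ornstein-Uhlenbeck) potential because it yields a clean MSS-slope
separation and a testable invariant - no true position ever exceeds
$R_c$. Localization noise is added after reflection, so *observed*
confined positions may slightly exceed $R_c$, as they do in real data.
Default class parameters for validation scenes
($D = 0.05\,\mu m^2/s$ free and confined, $R_c = 0.25\,\mu m$,
$v = 1\,\mu m/s$ directed at 10 fps) sit in the range typical of
endolysosome imaging; rendered scenes use a gentler directed speed
(0.13 µm/s) so one-minute paths stay inside a renderable field of
view.

## Rendering and detection

`render_movie()` draws each particle as an **integrated Gaussian**: the
PSF is integrated over each pixel with error functions rather than
point-sampled at pixel centers. Point sampling biases sub-pixel
centroids; the integrated model makes the renderer and the fitting
model consistent, so localization tests measure the detector, not a
rendering artifact. The reticular ER background is rendered as the
ridge set of a random Voronoi tessellation (the locus where the two
nearest seed distances coincide), blurred by the PSF - a structured,
network-like signal that the accumulation-thresholding stage must
reject. Shot noise is Poisson per pixel; read noise is Gaussian;
every generator is byte-reproducible under its seed.

`detect_spots()` band-pass filters each frame (difference of Gaussians
at the expected spot scale), takes local maxima above an amplitude
threshold (default: 5x the frame's robust background SD, since real
acquisitions publish no detector constants), and fits an integrated
2-D Gaussian on a window around each candidate with
Levenberg-Marquardt least squares. When the single fit leaves a
relative residual above `max_fit_residual` (default 0.15, comfortably
above the 1/SNR noise floor at SNR 10) the detector attempts a
two-Gaussian fit, started either at a secondary intensity maximum or,
for fully merged pairs, at points split along the window's principal
intensity axis. Fits are capped at two components per window: on a
7x7 window more components are not identifiable. Coordinates are
0-based with pixel centers at integer positions, and every physical
output also carries µm via the pixel size.

Accumulation thresholding (`threshold_accumulations()`) removes the
smooth background with a morphological opening and takes a percentile
(default 99) of the remaining structured intensity; Otsu and absolute
thresholds are available where a recording has been pre-scaled.
Raising the level can only remove mask pixels (tested as a
monotonicity property). Connected components are 8-connected
throughout.

## Linking

`link_detections()` performs per-frame-pair Hungarian assignment on
squared displacement, with a hard displacement gate (`max_disp_px`,
default 5 px = 0.5 µm per frame at defaults, capping speeds near
5 µm/s) and gap closing up to `max_gap_frames` with a proportionally
enlarged gate. Defaults are strict (no gaps); the end-to-end validation
scene uses `max_gap_frames = 2`, which heals the track fragmentation
caused by occasional missed detections without measurable purity cost.
Tracks shorter than `min_track_len` (20 frames) are discarded - MSS
exponent fits are unstable below that length. Assignment ties resolve
deterministically through the solver's canonical ordering.

## Contact persistence

`detect_contacts()` operationalizes "appearing together" as at least
one shared pixel between the thresholded accumulation mask and an EL
object - the underlying assay overlays thresholded masks with no
distance criterion, so none is invented here. Co-occurrences link
across frames by EL footprint overlap (ELs change shape, so overlap is
more stable than centroid distance), and an event's duration counts
both endpoint frames: a punctum visible in one frame has duration
$\Delta t$, not zero. The acceptance rule `duration >= 10 s` is the
assay's stated persistence criterion; at the 2.4 s frame interval of
association recordings, 4 co-occurring frames (9.6 s) are rejected and
5 (12.0 s) accepted. Whether brief dropouts within a contact should be
tolerated is not specified by the assay; the default is the strictest
reading (`max_gap_frames = 0`), exposed as a parameter. In fixed-cell
z-stacks, `detect_contacts_zstack()` replaces temporal persistence
with the requirement of at least 2 consecutive z slices.

`score_er_association()` is deliberately minimal - presence of
thresholded ER signal inside the EL mask, per frame, over 10 frames,
times 10 - because that is the entire published scoring rule.

## Dispersal shells

`build_shells()` bands the Euclidean distance transform of the cell
mask into five 2 µm shells (shell 5 at the outline, shell 1 absorbing
the remaining interior). The distance transform replaces iterated
morphological erosion: it gives sub-pixel-accurate band edges
independent of any structuring element. The peripheral statistic is
thresholded intensity in shells 3-5 over the whole cell; whether
"signal" meant integrated intensity or thresholded area is not fully
specified by the original protocol, so intensity is the default and
area is available (`measure = "area"`). Where the original analysis
excluded non-round cells by eye, `eltrack` instead emits QC flags
(`thin_cell`, empty shells) and leaves exclusion to explicit,
reproducible criteria. On a uniform disc of radius 10 µm the fraction
has the closed form $(10^2 - 4^2)/10^2 = 0.84$, reproduced to < 0.01
at 0.1 µm pixels; planted fractions from 0.1 to 0.9 are recovered
within 0.03 with 200 puncta.

## EM contact fraction

`measure_section()` resamples the traced EL polygon at ≤ 5 nm arc
steps and measures each sample's distance to the ER polylines
curve-to-curve, matching membrane-to-membrane apposition; boundary arcs
within 30 nm count toward contact length, with the crossing position
interpolated linearly in distance (step-size sensitivity is below 0.5%
when halving the step on smooth contours). Sections are independent:
per EL, perimeters and contact lengths are summed across sections
*before* dividing - percentages are never averaged across sections -
and cells average their ELs' percentages unweighted, as the assay
prescribes. Circle-and-line fixtures have closed-form contact
fractions (for a tangent line at cutoff $c$:
$\arccos((R-c)/R)/\pi$), which the measurement reproduces within 1%.

## PLA counting

`count_dots()` binarizes, splits touching dots with a watershed on the
distance transform (tolerance 0.3 px - small enough to separate dots
whose footprints merely touch), labels 8-connected, and keeps dots of
at least 5 px area. "5 pixels" is read as area (the particle-size
convention of the underlying tool), recorded as a config default. The
interactive threshold of the original workflow is replaced by an
absolute config value with an Otsu fallback for determinism. Cell
assignment uses containment when cytoplasmic masks exist and otherwise
nearest-nucleus (generalized Voronoi) assignment with ties to the
lower cell id, standing in for manual per-cell reading.

## Configuration and I/O

`default_config()` collects every tunable; the persistence (10 s),
shell (2 µm x 5, peripheral 3-5), EM (30 nm), PLA (5 px) and
association (10 frames at 2.4 s) constants default to the assay-stated
values. `load_config()` merges partial YAML over the defaults,
rejecting unknown keys by name. Stacks round-trip through 16-bit
multi-page TIFF with a JSON sidecar holding calibration and seed;
missing calibration is an explicit error, never a silent default. EM
contours exchange as a flat CSV (section, object type, object id,
vertex, x/y in nm) so traces from any annotation tool can be analyzed.
The package's functions are its interface; each stage writes plain
data.frames that `write.csv()` serializes directly.

## Validation scope and limitations

The test suite validates every stage against ground truth the
generators control: closed forms (ballistic $S = 1$, Brownian
$S = 0.5$, annulus areas, circle-line arcs), brute-force oracles
(boundary sampling, placement re-counts), and planted-truth recovery
(classification confusion, track purity, dwell plans, dot counts).
Standard problem sizes: 500-600 simulated tracks per Monte-Carlo
check, one 600-frame 30-particle rendered scene at peak SNR 10, 200
puncta per dispersal scene, 2x10^5-point sampling oracles.

What passing these tests does **not** show: the generators draw
diffraction-limited spots on smooth backgrounds, with motion models
that are idealizations of motor-driven transport (constant drift, hard
confinement). Real recordings add vesicle shape, fission/fusion
(merge/split events are out of scope for the linker), photobleaching
and blinking (not modeled), focus drift, and cell-to-cell variation in
background structure. Detector and linker constants are therefore
config-overridable rather than fixed, and the MSS thresholds are
recalibrated per acquisition by design. Pixel size (0.1 µm) and PSF
width (σ = 1.3 px) of the synthetic scenes are fixture choices, not
measured values. Three-dimensional fitting, deconvolution, SIM/CLEM
simulation and 3-D EM reconstruction are out of scope.
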