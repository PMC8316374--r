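# eltrack

Quantification of endolysosome (EL) behaviour from fluorescence and
electron microscopy: motility, ER contact sites, peripheral dispersal,
and proximity-ligation readouts.

Endolysosomes are positioned and restrained in cells partly through
membrane contact sites with the endoplasmic reticulum (ER). Measuring
that biology from microscopy requires a chain of quantitative steps -
finding vesicles, following them, classifying how they move, deciding
when an apparent contact is real - each with conventions that matter.
`eltrack` implements that chain as one tested R pipeline:

* **Sub-pixel spot detection** - band-pass filtering, local maxima, and
  integrated 2-D Gaussian fits (with a two-component branch for merged
  pairs) give detections with ~0.1 px precision at peak SNR 10.
* **Trajectory linking** - Hungarian frame-to-frame assignment
  minimizing summed squared displacement, with gap closing.
* **Moment scaling spectrum (MSS) motion classification** - for each
  track the displacement moments μ_ν(δ) = ⟨|r(t+δ) − r(t)|^ν⟩ are fit
  as μ_ν ∝ δ^γ_ν for ν = 0..6; the slope S of γ_ν versus ν is 0 for a
  stalled particle, 0.5 for Brownian motion and 1 for ballistic
  transport. Tracks are called *confined*, *free* or *directed* against
  thresholds calibrated by Brownian simulation at the acquisition's own
  track length and frame interval, and summarized as the pooled
  free-plus-directed (motile) proportion and its ratio to confined.
* **Contact calling with a persistence rule** - bright ER-protein
  accumulations overlaid with EL objects count as a true contact only
  when the pair co-occurs for at least 10 s (or, in fixed-cell
  z-stacks, in at least 2 consecutive slices).
* **ER association scoring** - presence of thresholded ER signal inside
  an EL mask over 10 followed frames, reported as a percentage.
* **Peripheral dispersal shells** - a cell mask is banded into five
  2 µm shells by a Euclidean distance transform from its outline; the
  dispersal statistic is the fraction of organelle signal in the outer
  three shells.
* **EM contact fraction** - from traced serial-section contours (nm),
  the arc length of EL membrane within 30 nm of ER membrane is summed
  across sections and divided by the summed EL perimeter, ×100, then
  averaged per cell.
* **PLA dot counting** - threshold, distance-transform watershed to
  split touching dots, and a ≥5 px size filter, with per-cell
  assignment by containment or nearest nucleus.
* **Synthetic scene generators** - every stage has a ground-truthed
  generator (trajectory simulators, an integrated-Gaussian movie
  renderer over a reticular Voronoi-edge background, dispersal stills
  with planted fractions, analytic EM geometries, planted PLA images),
  so the whole pipeline is verifiable without raw microscopy data.

## Worked example

Render the standard three-class movie (10 confined, 10 free, 10
directed particles; 600 frames at 10 fps; peak SNR 10), run the
pipeline, and compare with ground truth:

```r
library(eltrack)

scene  <- three_class_scene(n_per_class = 10, n_frames = 600, snr = 10,
                            seed = 42)
movie  <- render_movie(scene)
dets   <- detect_spots(movie$stack, "el",
                       params = list(expected_sigma_px = 1.3))
tracks <- link_detections(dets, max_disp_px = 5, max_gap_frames = 2,
                          min_track_len = 20, pixel_size_um = 0.1,
                          frame_interval_s = 0.1)
thr    <- calibrate_mss_thresholds(600, 0.1, n_sim = 300, seed = 5)
mss    <- analyze_tracks(tracks, dt = 0.1, thresholds = thr)
summarize_motion(mss)
#>   group n_confined n_free n_directed n_unclassified n_total p_confined
#> 1   all         10     11         16              0      37  0.2702703
#>      p_free p_directed p_unclassified p_free_directed ratio_fd_confined
#> 1 0.2972973  0.4324324              0       0.7297297               2.7

match <- match_tracks_to_truth(tracks, movie$truth$positions)
mean(match$purity)
#> [1] 0.9706854
```

37 tracks are reconstructed from the 30 planted particles (a directed
particle that is briefly lost restarts as a new track); every track
follows essentially one true particle (mean purity 0.97), and the
label mix reflects the planted 10/10/10 design with fragmented
directed tracks counted more than once.

The organelle-scale statistics work the same way from still inputs:

```r
mask <- rasterize_outline(list(center = c(11.5, 11.5), radius = 10),
                          c(230, 230), 0.1)
sh   <- build_shells(mask, pixel_size_um = 0.1)  # five 2-um shells
img  <- matrix(0, 230, 230); img[mask] <- 1
peripheral_fraction(img, sh)$fraction
#> [1] 0.8396524   # closed form for a uniform 10-um disc: 0.84

scene <- make_em_scene(list(center = c(0, 0), radius = 250),
                       list(rbind(c(-5000, 250), c(5000, 250))),
                       cutoff_nm = 30)   # tangent ER tubule
measure_contour_set(scene$contours)$percent
#> [1] 15.75378    # closed form: 100 * acos((250-30)/250) / pi = 15.75424
```

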