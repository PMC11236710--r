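# mcsgrad

Quantification of front-back ER-plasma-membrane (ER-PM) contact-site
gradients in migrating cells.

Cells migrating on micropatterned stripes polarize their cortical
ER-PM contacts: the reporter puncta marking them are sparse, small and
short-lived at the front and dense, large and stable at the back, and the
individual contacts stay fixed on the substrate while the cell moves over
them — from the cell's perspective they flow rearward. `mcsgrad` is the
image-quantification side of that biology, for microscopists and image
analysts working with multichannel time-lapse movies (PM marker, ER
marker, contact reporter, optionally nuclei and fixed-cell stains):

* **segmentation** — whole-cell masks from the PM marker (log-domain Otsu
  with a robust floor), Laplacian-of-Gaussian nuclei, peripheral ring
  masks of defined physical width;
* **tracking** — one nearest-neighbour linker for cells and puncta with a
  mass term for identity through crossings; speed, ensemble MSD
  (`MSD(t) = mean |x(t) − x(0)|²`), direction fits with reversal and
  stall calls;
* **puncta** — top-hat detection thresholded at the 40%-from-front band so
  dim front contacts survive, sub-pixel centroids, punctum mass
  (mean intensity × area), lifetimes with censoring, lab-frame versus
  cell-frame flow fields;
* **gradients** — automatic front detection (tip farthest from the
  centroid), 20 equal front-to-back segments, ratio profiles
  (reporter/PM, reporter/ER, pTyr/PM on the ring), kymographs, polarity
  steepness `score20 = |mean(front 20%) − mean(back 20%)| / mean(back 20%)`
  and `ratio50 = mean(front half) / mean(back half)`, and front/back
  growth-rate slopes from the retrograde sweep;
* **synthetic scenes** — a ground-truthed generator of stripe-migration
  movies (configurable birth/growth/death fields for the puncta, camera
  noise) so every stage is testable without real data.

## Worked example

Simulate a polarized scene and push it through the full pipeline:

```r
library(mcsgrad)

cfg   <- scene_config(seed = 42)       # 20 um stripe, 1 um/min, 15 frames
scene <- simulate_scene(cfg)           # masks + ground truth + movie
pc    <- pipeline_config(scene = cfg)

grad <- movie_gradient_analysis(scene$movie, pc)
grad$steepness
#> score20 = 0.972, ratio50 = 0.100 (log2 = -3.33)

pa <- movie_puncta_analysis(scene$movie, pc, grad)
pa$flow$summary[, 1:3]
#>   mean_lab_speed_um_min mean_cell_frame_speed_um_min cell_speed_um_min
#> 1                 0.107                        0.999             1.001
```

The default scene has a threefold back:front birth-rate gradient plus a
threefold growth-rate gradient with mass-stabilized contacts, so the
measured profile is strongly back-polarized: `score20 = 0.97` (front 20%
and back 20% differ by ~97% of the back level) and a back:front half
ratio of `1/ratio50 ≈ 10`. The 284 tracked puncta barely move on the
substrate (0.107 µm/min) while moving at the full cell speed
(0.999 ≈ 1 µm/min) in the cell frame — the retrograde flow signature.

The numbered scripts under `analysis/` run the same machinery as small
narrative studies (scene simulation, nuclear tracking and MSD, puncta
lifetimes and flow, gradient recovery across configured density ratios,
growth-rate slopes) and write their summary tables under
`results/analysis/`.

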