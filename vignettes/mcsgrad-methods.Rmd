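---
title: "Quantifying front-back contact-site gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying front-back contact-site gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsgrad)
```

## What this package measures

Migrating cells on micropatterned stripes polarize the density and size of
their ER-plasma-membrane contact sites: contacts are small, sparse and
short-lived at the front and large, dense and stable at the back, and the
individual contacts stay put on the substrate while the cell glides over
them ("retrograde flow" in the cell's own frame). `mcsgrad` is an
image-quantification pipeline for this phenomenology: it segments cells and
their contact-reporter puncta from multichannel time-lapse movies, tracks
both through time, and reduces them to the quantities used to describe the
polarity — 20-bin front-to-back gradient profiles and kymographs, polarity
steepness scores, punctum mass/lifetime statistics, cell-frame flow fields,
growth-rate slopes, and cell-motility metrics (speed, MSD, direction).

Because no public imaging data accompanies this problem at desk scale, the
package ships a first-class synthetic scene generator with exact ground
truth. Every stage of the pipeline is tested against scenes whose gradient,
flow, growth and lifetime structure is known by construction.

## The synthetic scene model

### Geometry

A cell is a capsule confined to a stripe of width 20 µm (the
micropattern width): a rectangle capped by a semicircular rear and a linear
cone at the front. The cone makes the tip the unique boundary point
farthest from the mask centroid, which is what the front-detection step
assumes; real polarized cells taper the same way. The capsule advances at a
constant configured speed along the stripe axis (towards $-x$ by default).
Default scene sizes (a 40 µm cell in a 26 × 88 µm field at 0.4 µm/px,
15 frames at 2 min) are deliberately compact so that whole simulation
studies run in seconds; they preserve the aspect ratios and sampling of the
imaging they emulate (spinning-disk confocal at 2-min intervals for
gradient work, 20-s intervals for puncta tracking).

### Puncta birth, growth and death

Puncta are born by a spatial Poisson process inside the cell footprint.
The birth-rate field is linear in the normalized front-to-back coordinate
$p \in [0,1]$ and is anchored at the *half centres* ($p = 0.25$ and
$p = 0.75$): the two configuration numbers are the mean birth rates of the
front and the back half, so their quotient is directly the configured
back:front density ratio that the recovery experiments ask the pipeline to
re-measure. Negative extrapolated rates are clamped to zero.

Each punctum is pinned to its lab-frame birth position forever — the
stationarity that produces retrograde flow is exact by construction. Its
mass $m$ grows at a rate that is piecewise constant by half
(`puncta_growth_rate_front` for $p < 0.5$, `puncta_growth_rate_back`
otherwise), so front/back slope ratios have an exact configured truth. It
dies with hazard

$$h(m) = s \cdot \max\!\left(0,\, 1 - m / m_\ast\right)$$

per minute (`death_rate_scale` $s$, `mass_stability_threshold` $m_\ast$):
small contacts turn over in minutes, contacts above the threshold are
near-immortal. With $m_\ast = \infty$ the hazard is constant and lifetimes
are exponential with mean $1/s$ — the null used to check that the
lifetime-mass analysis does not invent correlations. A punctum overtaken by
the rear of the moving cell also ends. Birth masses are log-normal around
`initial_mass`.

The simulation starts from an empty footprint rather than a steady-state
population; with ~2-min lifetimes the density equilibrates within about one
frame, and the profile averaging over 15 frames makes the residual
transient negligible.

### Rendering and noise

Channels: the PM marker is the mask fill plus a brighter one-pixel rim;
the ER marker is the fill minus a thin lamellipodial margin; the contact
reporter renders each punctum as an isotropic Gaussian spot whose
*integrated* intensity is proportional to its mass, using analytically
pixel-integrated Gaussians (differences of normal CDFs over each pixel
box) so sub-pixel centroids are unbiased for tracker tests. Optional
channels add a nuclear blob and a phosphotyrosine ramp that decreases
front to back. Spot size is mass-independent by default (σ = 0.25 µm);
real contacts also grow in area towards the back, and a configuration knob
exists, but the default keeps mean spot intensity proportional to mass so
growth-slope truths stay exact.

Noise is applied last: Poisson shot noise on the signal, a camera offset
(100 DN), Gaussian read noise (σ = 10 DN), then digitization to 16-bit
integers. Integer pixel values make TIFF round trips bit-exact. With both
noise knobs at zero the rendering is deterministic given the masks and
tables, and the whole scene — masks, tables, movie — is bit-reproducible
under a fixed seed.

### What the generator does not emulate

No ER network morphology or curvature, no photobleaching or illumination
drift, no cell shape fluctuation or turning, no neighbouring cells in the
same field, no focus drift, no spot-area growth by default. Passing the
package's tests therefore shows that the *computational* pipeline recovers
known structure through realistic segmentation, detection, tracking and
binning steps — it does not validate biological conclusions on real
microscopy, where these nuisances exist.

## Segmentation choices

**Whole-cell masks.** The PM channel is thresholded by Otsu's method
computed on log1p-transformed, background-mode-subtracted intensities of
the whole frame, combined with a robust floor (mode + 2 MAD). The log
transform compresses the bright cell interior so the split lands below dim
lamellipodia. An alternative — restricting Otsu to a coarse foreground —
degenerates on clean frames: when the coarse foreground is exactly the
cell, Otsu splits the fill from the rim and the mask collapses to the
boundary. Masks are hole-filled; objects below the minimum area, touching
the border, or within twice the isolation distance of another object are
discarded (only isolated single cells are analysed).

**Nuclei.** A Laplacian-of-Gaussian detector at σ matched to the expected
nuclear radius; one observation per response maximum; components with
multiple maxima, strong elongation, or twice the single-nucleus area are
flagged ambiguous rather than silently split or merged. Nuclear mass is
the background-subtracted integrated intensity (intensity × area).

**Peripheral ring.** A band of the stated physical width straddling the
mask boundary, half inward and half outward, computed from Euclidean
distance maps with a half-pixel convention (pixel centres sit half a pixel
from the mask edge; the boundary row counts towards the inner half). On a
discretized disk of radius 20 px the 3-px band lands within 3% of the
analytic annulus $\pi[(R+w/2)^2 - (R-w/2)^2]$. A width of one pixel
degenerates to the one-pixel inner boundary. The straddling choice keeps
membrane-proximal signal on both sides of the optical boundary in the
band, which is the point of using a ring for peripheral signals.

## Front detection and gradient profiles

The front is the boundary point farthest from the mask centroid; the back
is the boundary point farthest from the front; every mask pixel projects
onto the front-back axis to a clipped normalized coordinate $p$. Ties
(near-circular masks) are flagged ambiguous and broken deterministically
towards smaller $x$, or towards continuity with the previous frame's axis
when one is supplied. Projection, not geodesic distance, orders the
pixels: cells on stripes are nearly one-dimensional, and projection is
deterministic and cheap.

Profiles divide the mask (or ring) into 20 equal-width intervals of $p$
and average a per-pixel ratio image (reporter over PM or ER marker,
denominator floored) per bin. The partition is exact — every mask pixel
belongs to exactly one bin, and bin mean × valid-pixel count sums back to
the pixel total. Bins with pixels but no valid signal are linearly
interpolated from neighbours and flagged, keeping the 20-vector shape
stable for kymographs. Profiles are normalized per frame by the whole-cell
mean before averaging across frames and cells; this is the scale-free
choice consistent with ratio imaging, and all steepness scores are
invariant to global intensity rescaling either way.

Two steepness scores summarize a profile: `score20`
$= |\bar{f}_{20} - \bar{b}_{20}| / \bar{b}_{20}$ from the front/back 20%
bin means, and `ratio50` $= \bar{f}_{50} / \bar{b}_{50}$ from the halves
(reported also as log2). A uniform profile gives exactly 0 and 1; the
linear profile $1..20$ gives $16/18.5$ and $5.5/15.5$, which the tests pin
to twelve digits.

## Puncta detection and tracking

Detection white-top-hat filters the reporter with a 3-px disc, then
computes an Otsu threshold *only* from filtered pixels in a ±5% band
around the 40% axial position — calibrating on the mid-cell keeps the dim
front contacts detectable instead of letting the bright back set the bar.
The "modified" part of the Otsu step is a robust noise floor (median +
5 MAD of the filtered signal inside the cell): when the band happens to
hold few spots, a plain Otsu split lands inside the camera-noise
distribution and floods the frame with blinking false puncta. The floor is
inactive on noise-free images (the MAD is zero).

Components above threshold and ≥ 2 px are measured on an aperture grown
two pixels around each core (nearest core wins contested pixels), which
recovers the Gaussian tails cut off by the threshold — without it,
integrated masses are biased low by tens of percent at realistic
thresholds. Centroids are polished by iterative intensity-weighted
averaging in a fixed circular window, decoupling localization from
noise-driven flicker of the aperture boundary; on noisy scenes this cuts
the mean localization error by more than half, which is what keeps
apparent lab-frame speeds of stationary contacts far below the cell speed.
Punctum mass is mean filtered intensity × aperture area (equal to the
integrated filtered intensity).

Linking (cells and puncta share one linker) is greedy mutual nearest
neighbour on the cost $d / d_{\max} + w\,|\Delta m| / \bar{m}$: pairs are
taken in increasing cost order, never beyond the displacement gate, with
the mass term disambiguating crossings. Observations are canonically
ordered first, so linking is invariant to row permutations and ties break
deterministically. Lifetime is (last − first + 1) × interval, the
appearance-to-disappearance convention, and tracks touching either movie
end are censored and excluded from naive lifetime means (their count is
reported; no survival modelling is attempted). Lifetime-versus-mass
profiles bin by the mass at *first* observation: a long-lived punctum has
had more time to grow, so binning by mean or final mass would manufacture
a lifetime-mass correlation even under a constant hazard.

## Flow fields, growth slopes, and motility

The flow field decomposes each consecutive punctum displacement into the
lab frame and the cell frame (lab minus cell-centroid displacement); the
identity lab = cell-frame + cell displacement holds exactly per vector.
Per-movie summaries average both speeds, with log2 versions for plotting.

The growth-rate curve exploits stationarity: a punctum born near the front
sweeps backwards through $p$ as the cell migrates, so its signal traced
against $p$ is a readout of the local growth rate. The analysis keeps the
cohort of tracks first seen at $p \le 0.25$ *and* followed out to
$p \ge 0.85$: without the traversal requirement, observations at large $p$
come only from the earliest-born (longest-grown) puncta and the averaged
curve steepens at the back regardless of the true field. The curve is the
per-bin *median* of the per-punctum mass-to-PM ratio (a detection that
swallows a close neighbour carries an error proportional to the local
mass, which a mean would absorb into the back slope), and first-order
polynomials are fitted to the binned curve on $p \in [0.2, 0.5]$ and from
0.5 to the curve's argmax, weighted by bin counts. With a configured
threefold back growth rate the fitted slope ratio lands within 20% of 3 at
a thousand punctum observations.

Cell speed is total path length over elapsed time. MSD is the ensemble
average of $|x(t) - x(t_0)|^2$ from each track's own origin — not
time-averaged — matching the printed definition; ballistic tracks give
$(vt)^2$ to machine precision and 2D Gaussian random walks give
$2\sigma^2 k$ within Monte Carlo error. Migration direction is a
first-order polynomial fit of the (moving-average-smoothed) stripe
coordinate against time; the stall test uses the *unsmoothed* series
because smoothing inflates the slope test's false-positive rate, and
reversals require the new sign to persist five frames. Smoothing window
and persistence are both five frames — the smoothing is stated by the
quantification protocol, the window is this package's choice.

## Study conditions of the benchmark experiments

The packaged experiments (`experiment_*()`) fix their scene conditions;
the tests and the acceptance script only choose seeds.

* **Gradient recovery** uses *stationary* cells. With a migrating cell and
  ~2-min lifetimes, freshly swept territory at the tip sits below
  steady-state density (front depletion — the model reproducing the
  biology), so the realized density ratio deviates from the configured
  birth ratio by +10–15%. Only in a stationary scene does the steady-state
  density ratio equal the configured ratio at every time, which is what a
  recovery test must compare against. 20 cells per condition, ratios
  1, 2 and 4, with and without camera noise.
* **Tracking fidelity** uses 20-s intervals (the cadence of puncta-tracking
  acquisitions). At 2-min intervals half the population turns over per
  frame and death-to-birth misjoins dominate — a sampling-rate limit of
  nearest-neighbour linking, not a code defect.
* **Retrograde flow** uses sparse puncta (≈ 0.005/px²) so merge artifacts
  between neighbouring spots stay rare; four cells at 1 µm/min.
* **Growth slopes** seed puncta near the front only (births elsewhere zero)
  with no death, 14 cells of 24 frames, so enough tracks traverse the full
  coordinate range.
* **Lifetime-mass** draws 1000 tracks per arm directly from the death
  model with log-normal birth masses (σ = 0.6 log units), hazard either
  mass-dependent ($s = 1.2$/min, $m_\ast = 3$) or constant
  ($s = 0.5$/min).

## Numerical notes and degenerate inputs

All randomness flows from the scene seed (sub-stages use fixed small
offsets), so identical configurations produce byte-identical movies,
tables and pipeline outputs; every output table carries a hash of its
configuration. Uniform images yield empty segmentations with a warning,
not errors; an empty threshold band falls back to the whole mask with a
warning; circular masks flag front ambiguity; stationary cells make the
growth-rate analysis signal "insufficient range" rather than fit noise; a
zero back-segment mean makes `score20` error out rather than divide by
zero. The spot-rendering window truncates at 6σ (≤ 0.2% of the mass); the
99% confidence level for the flat-lifetime slope keeps that null check's
false-alarm rate at the percent level under reseeding.

## Known limitations

Linking has no gap closing or merge/split resolution; occlusion or
detection dropouts fragment tracks. The detector measures overlapping
spots as one punctum; density and spot brightness set the practical
resolution. Censored lifetimes are excluded, biasing naive mean lifetimes
downward when movies are short relative to contact stability. The ring and
axis conventions are half-pixel-exact only for the discretization used
here. And all validation is against the generative model above — real
microscopy adds nuisances the generator deliberately omits.
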