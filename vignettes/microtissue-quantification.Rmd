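---
title: "Quantifying fibrotic function in collagen microtissues: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrotic function in collagen microtissues: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtiss)
```

## The assay this package quantifies

Idiopathic pulmonary fibrosis (IPF) progresses through dysregulated
fibroblast function: excess extracellular-matrix deposition, cross-linking,
and cell-driven contraction of the tissue microenvironment. A scalable way
to measure these functions *in vitro* is to encapsulate lung fibroblasts in
collagen microspheres ("microtissues", ~300 µm at fabrication), push normal
cells toward the fibrotic phenotype with TGF-β1, and read out function from
fluorescence micrographs:

* **Compaction** — fibroblasts contract and remodel the collagen, shrinking
  the droplet. The 2D readout is the projected area of the droplet mask,
  converted to an equivalent diameter \(d = 2\sqrt{A/\pi}\) and, under a
  sphere assumption, to a volume fold-change \((d_0/d)^3\) against the
  300 µm starting construct.
* **Marker expression per cell** — mean fluorescence of a stained protein
  (e.g. αSMA, collagen cross-linkers, procollagen) across the microtissue,
  background-subtracted by the tissue's own 10th-percentile intensity and
  divided by the nuclear count:
  \(\mathrm{NI/cell} = \max(\bar I - P_{10}, 0)/n_\text{cells}\).
* **Viability** — calcein-positive cells over all cells per droplet.
* **Secreted protein** — media concentration × volume / cultured cell
  number (per-cell secretion).

Because such screens compare dozens of conditions with ~25–30 droplets
each, the package also implements the screen's statistical battery:
single-pass 3-SD outlier removal per (metric, group), carrier-control
normalization, paired and nested Student's t-tests, one-way ANOVA with
Tukey HSD, 95% confidence intervals of the mean, and the conventional star
codes (\*, \*\*, \*\*\*, \*\*\*\* for p below 0.05, 0.01, 0.001, 0.0001,
all strict).

No public image set accompanies the assay, so the package ships a
synthetic image generator with exact ground truth; every stage of the
pipeline is validated by recovery tests against scenes whose true values
are known.

## The synthetic generator

`generator_config()` holds the scene model. Its defaults are the assay
conditions the generator emulates, fixed once:

* **Geometry.** Droplets start at `droplet_d0 = 300` µm. Compaction follows
  exponential decay toward a plateau,
  \(d(t) = d_\infty + (d_0-d_\infty)e^{-t/\tau}\). Published work describes
  the kinetics only qualitatively — a sharp early decline that plateaus
  within roughly a week — so the simplest model with that shape is used,
  with \(\tau = 2\) days. The plateaus are *derived*, not asserted: the
  assay's headline volume folds of 37 (activated) and 18 (control) are
  inverted through \((300/d)^3 = \text{fold}\), giving
  \(d_\infty \approx 90.03\) and \(114.47\) µm.
* **Cells.** Counts per droplet are negative binomial (mean 25, size 60,
  i.e. ~10–40 cells), placed uniformly in the disk by random sequential
  adsorption with a hard minimum separation of \(4\sigma_\text{nuc}\)
  (8 px), which keeps the counting ground truth unambiguous. Requests
  beyond the jamming limit of that hard-core process are rejected (or, in
  cohort generation, capped and flagged) with the achievable maximum.
* **Stains.** Nuclei are Gaussian blobs (\(\sigma = 2\) px, peak 8000
  counts). The marker channel is a diffuse level (1500 counts) over the
  collagen disk plus wider cytoplasmic per-cell blobs
  (\(\sigma = 5\) px, peak 4000), both multiplied by the condition's marker
  fold; activation multiplies marker signal by `activated_fold`
  (default 2.2). The live stain places nuclear-width blobs at cells drawn
  alive with probability `live_fraction` (default 0.95). Marker signal is
  restricted to the disk, so at zero noise and background the channel is
  exactly zero outside the tissue.
* **Background and noise.** Every channel receives an additive offset
  (300 counts) plus a linear gradient (0.5 counts/px — a visible flat-field
  residual), then mixed Poisson–Gaussian noise with variance
  \(s\cdot\text{signal} + \sigma_r^2\) (shot scale 1, read noise 10 counts,
  a modern sCMOS scale), and clipping to the bit depth (16-bit default;
  clipping events raise a warning).
* **Dose-response.** Drugs attenuate activation through a Hill multiplier
  \(m(c) = 1 - E_\text{max} c^h/(c^h + \mathrm{IC}_{50}^h)\in[0,1]\); the
  residual activation interpolates both the marker fold and the compaction
  plateau between the control and activated values.
* **Heterogeneity.** Fabrication size dispersion is lognormal
  (CV 0.05; droplet fabrication is close to monodisperse, and the
  dispersion is exposed as a parameter rather than asserted), droplet-level
  marker variability lognormal (CV 0.15), and patients carry a lognormal
  random effect (SD 0.15) on marker amplitude and compaction depth, drawn
  once per patient — this is what gives nested designs their patient-level
  variance component. Cohorts that emulate single-cell-line experiments
  (the NHLF activation and compaction studies) are generated with
  `patient_sd = 0`, since a single line has no patient-level variation.

Determinism is strict: a cohort is a pure function of (config, design,
seed), with per-droplet substream seeds so any one droplet can be
regenerated alone.

```{r compaction-curve}
cfg <- generator_config()
t <- seq(0, 14, by = 0.5)
plot(t, simulate_compaction(cfg, t, activated = TRUE), type = "l",
     ylim = c(80, 300), xlab = "days", ylab = "equivalent diameter (um)")
lines(t, simulate_compaction(cfg, t, activated = FALSE), lty = 2)
legend("topright", c("activated", "control"), lty = 1:2, bty = "n")
```

### What the generator does and does not emulate

The scenes reproduce the *statistical structure* of the assay — effect
sizes, nesting, noise character, background drift, compaction geometry —
but not real microscopy texture: collagen fibrils, out-of-focus light,
uneven staining penetration, touching debris, or irregular (non-circular)
tissue outlines. Passing recovery tests therefore demonstrates that the
measurement chain is unbiased and correctly calibrated under the stated
scene model; it does not certify segmentation performance on arbitrary
real micrographs, where parameter overrides (fixed thresholds, different
area filters) may be needed.

## The imaging chain and its numerical choices

`preprocess()` estimates the large-scale background as a **linear plane
fitted to the dim (below-median) pixels** and subtracts it, then rescales
between robust percentiles (1% / 99.9%) to `[0, 1]`. A plane fit is used
rather than heavy smoothing because a microtissue can occupy most of the
field of view: no smoothing scale is simultaneously much larger than the
droplet and smaller than the image, and feasible blur scales absorb the
droplet itself into the "background". The plane is exact for
offset-plus-gradient backgrounds, makes masks invariant to global additive
offsets, and the percentile stretch makes the automatic threshold
invariant to global gain. Intensity quantification always uses the raw
channel — preprocessing exists only to find masks, and the per-construct
\(P_{10}\) subtraction handles offsets on the raw scale.

`segment_droplets()` smooths lightly (\(\sigma = 2\) px; larger smoothing
would bias small-droplet areas through curvature shrinkage), then picks a
global threshold in three automatic stages:

1. **Otsu on log-intensity.** Fluorescence histograms are trimodal
   (background, diffuse tissue, bright puncta); on the raw scale Otsu can
   lock onto the puncta/tissue split. The log compresses the bright tail
   so the background/tissue gap dominates.
2. **Midpoint re-threshold.** The threshold is moved to the midpoint
   between the background level and the near-edge tissue level, sampled on
   a thin erosion ring just inside the mask — inside the smoothed edge
   ramp but outside the puncta-rich interior.
3. **Gradient-optimal edge.** Among candidate levels between background
   and that tissue level, the threshold whose mask contour has the
   steepest mean intensity gradient is kept. For a smoothed step edge the
   gradient peaks at the 50% crossing regardless of how bright the tissue
   is further in, which removes the boundary bias that center-bright,
   rim-dim compacted tissues otherwise induce.

Masks are hole-filled and labeled; components under `min_area_px`
(default 1000 px², debris) and components touching the border (censored
projected area) are excluded and counted in the QC attributes. Circularity
uses a staircase-corrected perimeter (4-connected boundary edge count
scaled by π/4), so a digital disk scores ≈ 1. Coordinates are (row, col)
from the top-left; areas and diameters are always reported in physical
units via the pixel size. On noiseless disks of radius ≥ 20 px the
measured area is within 0.5% of truth; at the generator's default noise,
cohort mean area error is ~0.1–0.5%.

`count_nuclei()` smooths at the expected nucleus scale, takes local maxima
(grayscale dilation equality) above a prominence threshold — 30% of the
in-mask dynamic range over the in-mask 10th-percentile background — and
applies greedy minimum-separation suppression ordered by intensity, ties
broken lexicographically by (row, col) so counting is deterministic. The
default separation is \(3\sigma\), deliberately below the generator's
\(4\sigma\) placement floor so that grid discretization of two minimally
separated peaks cannot merge them; blobs truly closer than the separation
are merged and counted once, which is the documented behavior.

`classify_viability()` averages the live channel in a fixed-radius disk
(3 px) at each cell and splits live/dead by Otsu on the per-cell means.
Otsu assumes bimodality, but many healthy droplets have *no* dead cells;
a separation guard (dim class more than half as bright as the bright
class) detects unimodal populations and assigns the whole droplet by an
absolute fallback threshold (100 counts, above read noise and background,
below any genuine stain). All-equal means fall back with a warning.

## Statistics: units of analysis and filtering order

* The **3-SD outlier filter** is computed once on the full sample
  (n−1 SD), per metric and group, before any normalization or testing —
  it is not iterated.
* The **paired t** pairs *replicate experiments*: droplet values are
  collapsed to per-replicate condition means first. Points in screen
  figures are droplets, but the repeated unit across an experiment series
  is the replicate.
* The **nested t** collapses droplets to per-patient means and runs an
  equal-variance two-sample t on patients — the experimental unit is the
  patient, so droplet-level pseudo-replication cannot inflate
  significance (duplicating every droplet leaves p unchanged, which the
  test suite asserts). For balanced designs this equals the nested mixed
  model; unbalanced designs are handled by unweighted patient means.
* **ANOVA + Tukey HSD** runs on droplet-level values per metric (figure
  points are droplets), after normalizing each droplet to the mean of the
  carrier/control group within its replicate. Equal-variance (Student)
  forms are used throughout, matching the named tests; no cross-metric
  multiplicity adjustment is applied.
* Type-I error of the paired and nested tests is verified by simulation
  under the null generator (1000 datasets each; rejection within
  5% ± 2%).

## Problem sizes used in the shipped analyses

The analysis scripts and validation suite use 24–30 droplets per arm
(matching the screen's ">25 per condition" scale), two-week compaction
cohorts for the volume-fold recovery, matched-size 30/arm cohorts for
marker-fold recovery, a 24-droplet (~600-cell) cohort for viability, and
1000-replicate null simulations for test calibration. Marker-fold
recovery deserves a note: per-cell normalized intensity scales inversely
with droplet area, so arms at different compaction states confound
staining with geometry. The recovery checks therefore use matched-size
arms (a design-level diameter override) to isolate the staining fold;
mixed-geometry cohorts are validated against the geometry-inclusive true
fold instead.

## Known limitations

* Segmentation is threshold-based and tuned for bright-on-dark convex
  tissues; no learned models, no splitting of touching droplets.
* The 10th-percentile background subtraction is slightly upward-biased
  under noise (the percentile of a noisy sample sits below its mean);
  with the default scene brightness this bias is a few percent of the
  per-cell signal and cancels almost entirely in condition folds.
* Droplets are independent; there is no tracking across timepoints, as in
  endpoint imaging.
* Dose-response is simulated and analyzed, but IC50 *estimation* (curve
  fitting) is out of scope, as are power/z′-factor tooling and 3D
  reconstruction.
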