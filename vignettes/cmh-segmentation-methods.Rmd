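---
title: "Spectroscopic segmentation of Prussian blue-stained microhemorrhages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic segmentation of Prussian blue-stained microhemorrhages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmhseg)
```

## The problem

Cerebral microhemorrhages (CMHs) are small brain bleeds whose iron residue
(hemosiderin) is revealed in histological sections by Perl's Prussian blue,
against a Nuclear Fast Red pink counterstain. Quantifying CMH burden means
finding the blue deposits in RGB brightfield micrographs and measuring their
area in physical units. Done by hand this is slow and subjective; `cmhseg`
implements two automatic colour-based segmentation methods, the shared
post-processing chain that cleans up their raw output, consensus
ground-truthing from several human annotators, the data-driven selection of
each method's operating parameter, and the agreement statistics used to
judge the result.

## The two segmentation statistics

**Ratiometric.** Each pixel is scored with the segmentation ratio
$$ r = \frac{I_{red}\, I_{green}}{I_{blue}^2}, $$
and pixels *below* a threshold are segmented. Prussian blue pixels have high
blue and suppressed red/green intensity, so they score well below 1; the
pink counterstain scores above 1; achromatic pixels score exactly 1. The
ratio is invariant to a common scaling of all three channels, so exposure
and bit depth do not matter. Zero-blue pixels carry no Prussian blue signal;
they are mapped to a large finite sentinel so they can never be segmented
(`compute_ratio()` documents this choice; a pure-black pixel is treated the
same way).

**Spectral phasor.** Each pixel's three intensities are projected onto the
first Fourier harmonic across the channel index $l = 1,2,3$ (red, green,
blue):
$$ H = \sum_{l=1}^{3} I_l \cos\frac{2\pi l}{3}, \qquad
   S = \sum_{l=1}^{3} I_l \sin\frac{2\pi l}{3}. $$
Pure red, green and blue map to the vertices of an equilateral triangle on
the unit circle and greys map to the origin, so chromaticity clusters in a
bounded 2-D space. By default intensities are first divided by their
per-pixel sum. The sums as written scale with brightness, which would make a
fixed-radius circular gate meaningless; the bounded phasor plane and the
circular gating both presuppose intensity-normalised coordinates, and the
spectral-phasor literature this method descends from normalises the same
way. `compute_phasor(..., normalize = FALSE)` gives the literal unnormalised
sums for completeness.

The per-image gating procedure is: build a 2-D histogram of (H, S); find
the "bluest" occupied bin by minimising the index ratio `x/y` (row over
column); centre a circular gate of radius `r` at that bin's centre; remap
every pixel whose phasor lies inside the circle back to image space.

### Phasor histogram conventions

The histogram orientation is a genuine design choice: the index-ratio
search only means something once the axis order is fixed. We use a
display-matrix layout with rows running from $S = +1$ (row 1) down to
$S = -1$ and columns from $H = -1$ up to $H = +1$. Under this layout,
minimising `x/y` favours large-$H$ columns and penalises the high-$S$ rows
where the red counterstain lives, which is exactly the "bluest corner"
heuristic. Ties break toward the larger column (bluer), then the smaller
row. The grid is 256 x 256 over $[-1,1]^2$; bins are square so a circle in
phasor units is also a circle in bin units. The gate boundary is inclusive.

## Post-processing chain

All segmentations - including the consensus ground truth - pass through an
ordered clean-up chain with physical-area thresholds (strict inequalities
throughout):

1. remove regions smaller than 5 µm²;
2. remove regions smaller than 50 µm² whose nearest other region is more
   than 50 µm away (scattered speckle far from any deposit);
3. ratiometric/phasor only: remove regions larger than 6000 µm²;
4. phasor only: fill enclosed holes smaller than 1.73 µm²;
5. ratiometric/phasor only, when supplied: intersect with a coarse
   manually-drawn ROI.

Step 2 needs a notion of "distance to the closest spot". We measure the
minimum Euclidean distance between boundary-pixel centres, which is
conservative against centroid distance for large neighbours. A mask with a
single region keeps it: there is no other spot to be far from, and deleting
the only detection would zero every single-CMH image. Foreground regions
use 8-connectivity and holes 4-connectivity (the standard duality that
avoids a pixel path crossing itself); hole filling never touches
background connected to the image border.

## Consensus ground truth and parameter selection

Ground truth is built by majority voting: a pixel is positive when at least
2 of the K annotators marked it (`majority_vote()`), then the truth-tagged
chain (steps 1-2) is applied. Voting precedes post-processing so the chain
sees one consensus mask rather than K noisy ones.

Each method has one free parameter. For a dataset with ground truth,
`select_optimal_threshold()` sweeps a grid (default: 101 geometric points on
[0.05, 5]), applies the full chain to every candidate segmentation, and per
image picks the threshold minimising the absolute percent area error
$|A_{seg} - A_{gt}|/A_{gt}$; the dataset optimum is the **median** of the
per-image bests. `select_optimal_radius()` does the same over 40 radii on
(0, 0.5] but returns the **mean**, the two deliberately different summaries
this workflow uses for its two parameters. Ties within an image
resolve to the smallest parameter (the conservative segmentation); images
with zero ground-truth area are excluded with a warning since percent error
is undefined there.

## Evaluation

`roc_sweep()` computes pixel-pooled sensitivity/specificity across the
dataset at every grid value, applying only chain steps 1-2 in-sweep (the
large-area removal, hole filling and ROI check are operating-point
decisions, not part of the detector). Pooling all pixels of all images
yields the single dataset-level confusion table that a single reported
sensitivity/specificity pair implies; per-image averaging is available via
`pool = FALSE`. AUC is the trapezoid integral with (0,0) and (1,1) anchors.

Area agreement uses the single-measure two-way random-effects
absolute-agreement ICC - ICC(A,1) in the McGraw & Wong taxonomy - computed
from the two-way ANOVA mean squares, with the F-based 95% CI. The
absolute-agreement form is the right one here because a method that
systematically over- or under-segments should be penalised even if it ranks
images perfectly. Single-measure is appropriate since each method
contributes one area per image. Bland-Altman analysis reports the mean and
95% limits of agreement of the pairwise differences expressed as a
percentage of the pair mean - the standard percent Bland-Altman, consistent
with plotting differences against pair means.

## What the synthetic generator emulates

No public CMH histology set accompanies this package, so
`generate_image()`/`generate_dataset()` produce calibrated fixtures that
emulate the relevant structure of the real data:

* irregular compact deposits (random ellipses deformed by low-frequency
  radial noise, 1.5-px anti-aliased edges) with log-uniform areas spanning
  5-6000 µm², straddling every filter bound;
* a blue-dominant deposit colour, mean RGB (50, 50, 210), over a pink
  background, mean (220, 140, 170), with Gaussian channel noise
  (sd 8 counts). These means put the deposit ratio near 0.06 and the
  background near 1.07, and separate the deposit phasor cluster from the
  achromatic origin by about 0.52 - enough that both methods succeed while
  edge-blend pixels keep the boundaries imperfect and the agreement
  statistics non-trivial;
* optional near-achromatic shadow patches (mean (120, 120, 120)) that no
  correctly calibrated method should segment: their ratio sits at 1 and
  their phasor at the origin;
* K = 4 simulated annotators, each redrawing every region with a
  morphological boundary jitter of up to 1 px and a 10% chance of missing
  regions under 20 µm², emulating careful but imperfect human outlining.
  Although each annotator's jitter is unbiased, the 2-of-4 consensus is an
  order statistic and inherits a slight dilation bias — much like human
  raters, who tend to draw around a deposit rather than on its exact
  border. The area-matching calibration absorbs this bias by nudging the
  threshold or radius upward, and on some datasets the nudged threshold
  approaches the achromatic ratio of 1 closely enough that fragments of a
  shadow patch survive; this is a property of the area-matching calibration
  rule itself, not of the implementation.

Defaults are 256 x 256 px at 0.75 µm/px (a 192-µm field, the scale at which
a 20x objective frames one CMH); deposits are placed without overlap, since
real deposits are distinct objects and merged draws would exceed the
large-area bound by construction. All randomness flows through one seed:
the same seed reproduces a dataset byte-for-byte.

What the generator does *not* model: optical vignetting and chromatic
aberration, staining batch variation, tissue texture, out-of-focus blur,
and annotators with systematic (rather than random) bias. Passing the
pipeline's recovery tests on these fixtures therefore demonstrates the
correctness of the implementation and the internal consistency of the
calibration/evaluation machinery - not the clinical performance of the
stains or methods on real slides.

## Numerical choices and degenerate inputs

* Ratio at `I_blue = 0`: large finite sentinel (1e12), never segmented.
* Phasor at zero total intensity: mapped to the origin.
* `find_bluest_bin()` ties: larger column, then smaller row.
* Per-image argmin ties in calibration: smallest grid value.
* Dice of two empty masks: 1 (perfect agreement of nothing).
* ICC with zero variance everywhere: an error, not a number.
* Bland-Altman pairs with zero mean: excluded with a warning in percent
  mode.
* Percent error with zero ground-truth area: an error; calibration excludes
  such images.
* The empty-histogram, empty-grid and empty-dataset cases all error with
  messages naming the problem.

## Problem sizes

The bundled analyses run at desk scale by design: 20 synthetic images of
256 x 256 px with 4 annotators for the end-to-end recovery study (the
acceptance script), 101 threshold and 40 radius grid points for
calibration and ROC sweeps, and 96 x 96 px fixtures for the faster unit
tests. These sizes exercise every code path - multi-region images, border
cases at each filter bound, shadow decoys - while a full calibration plus
evaluation completes in a few minutes on one core.

## A worked example

```{r example, eval = FALSE}
library(cmhseg)

spec <- synthetic_spec(n_shadows = 1)
data <- generate_dataset(20, spec, seed = 1) |>
  consensus_truth(min_votes = 2)

sel <- select_optimal_threshold(data)
ev  <- evaluate_segmentation(data, "ratiometric", sel$optimal_threshold)
glance(ev)

roc <- roc_sweep(data, ratio_segmenter(), ratio_threshold_grid())
autoplot(roc)
autoplot(ev$bland_altman)
```

## Known limitations

* The phasor gate centre is located per image from the single bluest
  occupied histogram bin; on noisy images this bin can be an outlier pixel
  rather than the cluster mode, which the radius sweep then compensates
  for. A density-weighted centre would be more stable but would change the
  procedure as defined, so it is left to the radius sweep.
* The isolation rule's 50-µm distance is boundary-to-boundary by our
  choice; a centroid-based reading of "distance to the closest spot" would
  remove slightly more speckle near large regions.
* White balance is taken as-is; no cross-microscope normalisation is
  attempted.
* Whole-slide formats and tiling are out of scope; inputs are single
  field-of-view TIFF/PNG images with a known pixel size, which must be
  supplied by the user (there is no safe default for µm/px).
```
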