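---
title: "Blending, sampling and refinement: how chromablend composes its data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blending, sampling and refinement: how chromablend composes its data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromablend)
```

## The problem and the model

Binary instrument/background segmentation of endoscopic frames needs large
pixel-accurate training sets that do not exist. `chromablend` composes them
semi-synthetically from two kinds of *source image* whose labelling is
cheap: instruments recorded over a green chroma key (the mask is a colour
threshold away) and instrument-free tissue frames (all background by
construction).

The key modelling decision concerns the blending step. Write a composite as
$x = \phi(x_f, x_b)$, $y = y_f$: whatever $\phi$ does to pixels, the label
is the foreground mask. Since the *ideal* $\phi$ is unknown, and any fixed
choice imprints learnable artifacts along the pasted boundary, $\phi$ is
randomized over the convex hull of a small basis $\{\phi_m\}_{m=1}^{M}$,
$M = 3$:

1. **trivial** — copy foreground pixels where $y_f = 1$;
2. **Gaussian feathering** — soft mask $m =
   \mathrm{blur}_{k_b}(\mathrm{erode}_{k_e}(y_f))$ with $k_e = 3$,
   $k_b = 5$, composite $m\,x_f + (1-m)\,x_b$;
3. **Laplacian pyramid blending** — band-pass pyramids of both images
   combined level-wise with the Gaussian pyramid of $y_f$ as weights, then
   collapsed.

A *mix-blend* sample is $x = \sum_m \lambda_m\,\phi_m(x_f, x_b)$ with
$\lambda \sim \mathrm{Dir}(\alpha)$, $\alpha = (1,1,1)$ by default: every
visit of a foreground/background pair yields a fresh point in the simplex
of blends, so no single boundary statistic is a reliable foreground cue.
*Multi-blend* (one composite per basis function, per pair) is the corner
regime of the same model: with $\alpha = (0.001, 0.001, 0.001)$, more than
99 % of draws place over 0.99 of the mass on one $\phi_m$ — the package
verifies this by simulation.

Two assumptions are worth making explicit. Foreground and background
sources are treated as independent, and any pairing is considered equally
plausible — the sampler draws pairs uniformly with replacement. And one
foreground sample contributes per composite (source images themselves hold
one to three instruments).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | `(1, 1, 1)` | — | Uniform over the blend simplex; one entry per basis function. |
| `blend$erosion_kernel`, `blur_kernel` | 3, 5 | px | Feathering kernels; blur sigma follows `0.3((k-1)/2 - 1) + 0.8`, the conventional kernel-to-sigma rule. |
| `blend$pyramid_levels` | 4 | levels | Seam blending scale ~`2^L` px; inputs are reflect-padded to multiples of `2^L` and cropped after collapse. |
| `chroma$hue_low/high` | 80–160 | degrees | Covers commodity green chroma fabric; tune per recording session. |
| `chroma$min_saturation/min_value` | 0.25 / 0.15 | — | Dark or washed-out pixels never count as chroma green. |
| `chroma$sure_fg_erosion` | 5 | px | The candidate eroded by a disc seeds sure-foreground; guards halo pixels from poisoning the colour model. |
| `bands$low/high` | 0.2 / 0.8 | prob. | Certainty bands for refinement: `< low` sure background (strict), `>= high` sure foreground. |
| `standard_width` | 640 | px | All pairs are resized to this width (aspect preserved) and height-matched by a random crop of the taller element before blending. |

Augmentation magnitudes (zoom 0.7–1.3, rotation ±90°, shift ≤ 0.2·W,
brightness ≤ 0.2, droplets ~ Poisson(3) with radius 2–15 px, distractor
count 0–3, padding width ≤ 0.1·W or disc radius 0.45–0.55·min(H,W), each
photometric op with probability 0.3) are package choices, selected once so
tools stay recognizable; all are configurable under `augment`.

## What the fixtures emulate — and what they do not

`make_foreground_fixture()` produces a green field (hue around 120°,
illumination gradient, Gaussian pixel noise) with 1–3 elongated articulated
capsules shaded metallic gray with a specular ridge, each touching an image
border, plus a soft shadow drawn *into the green field but excluded from
the mask* — the hard case a chroma threshold must survive. Masks are exact
by construction, so the extraction pipeline can be scored against real
ground truth. `make_background_fixture()` maps multi-octave value noise
onto a red/pink tissue palette with specular spots and a vignette, and
contains no chroma-green pixels. `make_probmap_fixture()` corrupts a truth
mask by blurring and by pushing a fraction of pixels into the uncertain
band.

These fixtures validate *masks and blending arithmetic*, not realism: no
specular metal reflections of tissue, no motion blur from real optics, no
true endoscope colour response, no tool–tissue interaction. A pipeline that
passes every test here can still meet a domain gap on clinical data — which
is precisely the gap the certainty-band refinement stage exists to bridge,
and why nothing in the test suite claims clinical-level accuracy.

## Numerical choices

* **Pixels** are doubles in `[0,1]` internally; 8-bit only at file
  boundaries (PNG for images and `{0,255}` masks, 32-bit float TIFF for
  probability maps, because PNG cannot hold floats).
* **Dirichlet sampling** uses normalized Gamma draws computed on the log
  scale with the small-shape boost `G_a = G_{a+1} U^{1/a}`; without it,
  `alpha = 0.001` underflows to exact zeros about half the time.
  Components are floored at `1e-15` and renormalized so weights stay
  strictly positive.
* **GrabCut** is implemented as iterative energy minimization: 5
  full-covariance Gaussian mixture components per class (k-means hard
  assignment), 8-connected contrast-sensitive edges
  `gamma * exp(-beta * ||z_i - z_j||^2) / dist` with `gamma = 50` and
  `beta` set to the reciprocal of twice the mean squared neighbour
  difference, exact s-t min-cut per iteration, 5 iterations with early
  exit on a fixed point. Two details matter in practice: the *first*
  round's mixtures are fit on the sure (scribble-equivalent) pixels only,
  so corrupted probable seeds cannot poison the colour models; and
  covariances get a `1e-3` floor (sensor-noise scale) so smoothly shaded
  clusters cannot produce data terms that swamp the smoothness energy.
  Sure-seeded pixels are pinned with large terminal capacities and
  re-asserted after every cut. Probable pixels inside the uncertain band
  initialize as foreground when the probability is `>= 0.5` (the band
  semantics are strict-less / greater-or-equal, matching the band
  definition).
* **Pyramids** use the 5-tap binomial kernel `(1,4,6,4,1)/16` with
  reflect-101 borders; upsampling doubles the kernel to compensate the
  zero fill. Erosion and min-filters use replicate borders so constant
  masks are fixed points (an all-ones mask must reproduce the foreground
  exactly).
* **Clipping, not renormalizing**: feathered and Laplacian outputs, and
  the mix-blend sum, are clipped to `[0,1]`. Clipping is local and cannot
  violate label invariance; only the Laplacian basis can overshoot.
* **IoU** is epsilon-stabilized with the machine epsilon so two empty
  masks score 1, and uses the Jaccard union denominator
  `|A| + |B| - |A ∩ B|`. A `denominator = "sum"` switch preserves the
  plain-sum variant (which scores identical masks at 0.5) for comparison
  with formulations stated that way. Cross-entropy uses natural logs with
  a `1e-12` probability floor.
* **Component labelling** is 8-connected, numbered by raster-scan first
  occurrence so equal-area ties in the largest-N filter break
  deterministically.

## Open design points, resolved

* **Stage order in extraction** is threshold → largest-`N_i` filter →
  GrabCut: the component filter is noise reduction on the thresholded
  mask, so it precedes refinement.
* **Distractors under mix-blend** use the *same* lambda draw as the true
  tools in that iteration — under mix-blend "the same blending function"
  is the lambda-weighted sum itself.
* **Precomputed datasets** store the `M` per-basis blends plus one mask
  per sample and defer the Dirichlet sum to load time, so one fixed
  dataset supports unlimited lambda resampling. Since lambda is unknown at
  precompute time, flying distractors are applied per basis mode: stored
  image `m` is internally consistent with `phi_m` throughout.
* **Tools overlapping endoscopic padding**: padding is applied to the
  background before blending, so a tool may cover the black border. A
  `repad_after_blend` flag re-applies padding afterwards; it is off by
  default and the label is never silently edited.
* **Cutouts never modify labels**, even when they cover tool pixels —
  standard cutout semantics.
* **QC failures are flagged, not dropped**: exclusion is the caller's
  decision, via the report.

## Problem sizes

The test suite and the acceptance script run entirely on procedural
fixtures: 96×96 (64×64 for convexity checks) images for unit and property
tests, 50 seeds for the extraction and refinement recovery properties, 500
random masks against the flood-fill labelling oracle, 10,000 Dirichlet
draws for the moment and corner checks, and one end-to-end run at the full
640-pixel standard width (10 foregrounds, 10 backgrounds, 100 mix-blend
composites). The acceptance script scales the per-quantity replication to
20 seeds, which is enough for the medians and rates it reports to be
stable across seeds at the tolerances of interest.

## Known limitations

GrabCut refinement presumes colour separability between instrument and
tissue in the target image; it cannot rescue predictions where the classes
share a palette, and with no sure-foreground pixels it deliberately falls
back to plain binarization with a warning. The Laplacian basis blends
globally at coarse scales, so its output differs slightly from copy-paste
even ~2·2^L pixels from a mask edge — locality claims about blending hold
exactly for feathering but only asymptotically for pyramids. JPEG
augmentation inherits the encoder's 4:2:0 chroma subsampling; even at
quality 100 sharp colour edges are not preserved bit-exactly (the
augmentation wants artifacts, so this is harmless, but it is not a
lossless path). Finally, non-square backgrounds restrict the 90°-rotation
augmentation to 180° to preserve the frame extent.
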