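---
title: "Methods: automated 3D scoring of break-apart FISH z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated 3D scoring of break-apart FISH z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring problem

Break-apart FISH probes flank a gene locus with two fluorophores (FITC,
green; TRITC, red). In an intact locus the two half-probes hybridize a few
hundred nanometres apart and appear as a fused ("co-localized") signal; a
rearrangement separates the colors. A case is scored by counting, nucleus
by nucleus, how many fusion signals and how many separated green/red
signals are present, and diagnosing the case from the fraction of nuclei
with abnormal (break-apart) patterns.

Gene signals occupy tiny volumes distributed in three dimensions inside
each nucleus, so single-plane imaging misjudges distances between signals.
`fish3d` therefore scores confocal z-stacks: multi-layer acquisitions
(by default 7 layers at 0.6 µm spacing, 0.16 µm/pixel in-plane) with a DAPI
nuclear counterstain plus the FITC and TRITC probe channels. The pipeline
is:

1. **Preprocess** — per-layer Gaussian filtering on all channels;
   grayscale morphological opening then closing on DAPI only.
2. **Segment** — ellipse template matching on each DAPI layer; peaks
   passing a score threshold, after greedy non-maximum suppression, paint
   nucleus footprints that are clipped by the layer's Otsu foreground.
3. **Label and link** — 8-connected component labeling per layer, removal
   of too-small components, and linking of components across adjacent
   layers (overlap > 0.5 of the smaller) into 3D nuclei, followed by QC:
   border-touching, mutually overlapping, or out-of-size-range nuclei are
   discarded and only "clear individual" nuclei are counted.
4. **Detect spots** — per clear nucleus and channel, local 3D intensity
   maxima: a voxel whose intensity is ≥ its up-to-24 in-plane neighbours
   (5×5 window minus centre) and above an intensity floor; candidates
   within one spot diameter of each other merge to the single
   highest-intensity coordinate.
5. **Pair** — all FITC×TRITC distances inside a nucleus form a weighted
   network; pairs are selected by ranked greedy choice (shortest first,
   removing every candidate sharing a spot) and called co-localized below
   1.2 µm and break-apart at or beyond it.
6. **Classify and report** — each nucleus pattern is a function of the
   fusion count and the separated signal counts; the case diagnosis is
   negative iff the abnormal fraction is at most 10% of counted nuclei.

## Template matching

A template $T$ ($h \times w$) slides over the source image $I$
($H \times W$), producing a score matrix $R$ of size
$(H-h+1) \times (W-w+1)$. Six scores are implemented:

$$R_{SD}(x,y) = \sum_{u,v} \left(T(u,v) - I(x+u, y+v)\right)^2$$

$$R_{NSD} = \frac{R_{SD}}{\sqrt{\sum T^2 \cdot \sum I^2}}, \qquad
  R_{C} = \sum_{u,v} T \cdot I, \qquad
  R_{NC} = \frac{R_C}{\sqrt{\sum T^2 \cdot \sum I^2}}$$

$$R_{CC} = \sum_{u,v} T'(u,v)\, I'(x+u,y+v), \qquad
  R_{NcC} = \frac{R_{CC}}{\sqrt{\sum T'^2 \cdot \sum I'^2}}$$

where $T'$ and $I'$ subtract the template mean and the per-window mean.
Two readings here are the package's own:

* The Gaussian filter is implemented as the standard normalized density
  $\exp(-(x-\mu)^2 / 2\sigma^2)$ with $\sigma$ the standard deviation in
  pixels; a Gaussian written with a positive exponent diverges and cannot
  act as a low-pass filter, so the conventional negative exponent is used.
* $R_{NcC}$ is implemented as the mean-subtracted normalized form (the
  Pearson correlation of template and window, in $[-1, 1]$), the standard
  meaning of a "normalized correlation coefficient" and the form that
  makes NcC distinct from NC.

All six scores are evaluated by FFT cross-correlation (windows sums of
$I$ and $I^2$ come from correlation with a ones-kernel), which agrees with
direct summation to ~1e-12 relative error; the test suite pins every
method to a direct-summation oracle at 1e-9. Windows with vanishing energy
under a normalized score receive the method's worst value (NSD: `Inf`,
NC: 0, NcC: −1). Note the $[0,2]$ range sometimes quoted for normalized
square difference only holds for energy-matched template/window pairs; it
is not asserted.

The default score is NcC with acceptance threshold 0.6 — on clean
renderings the six methods select the same peaks (asserted in the tests),
and NcC's intensity invariance makes the threshold portable across
exposure settings.

## Template bank and footprints

Template matching needs nucleus templates from somewhere; rather than
requiring example images, the package ships a parametric bank: filled
ellipses with semi-major axes 3–8 µm, aspect ratios 1 and 1.5, rendered at
the configured pixel size on a shared canvas, with elongated templates
rotated in 30° steps. At aspect ≤ 1.5 the normalized correlation of an
ellipse changes little under sub-30° rotation, so the coarser step (rather
than, say, 15°) halves matching cost without changing selected peaks;
users can supply their own template images (`config$templates`) or widen
the grids.

An accepted peak paints the matched ellipse scaled by
`footprint_scale = 1.3` into the layer mask before intersection with the
Otsu foreground: a slightly-undersized best-matching template then still
covers the whole nucleus cross-section, while the Otsu clip removes the
overshoot. Non-maximum suppression uses the unscaled-by-overlap rule: a
peak is dropped when its footprint overlaps an accepted one by more than
30% of the smaller footprint.

Because nuclei shrink toward their axial poles, outer layers may fall
below the match threshold; linking tolerates gaps in the sense that a
nucleus's layer span is whatever was actually matched, and spots are only
sought within that span.

## Decision constants

| Parameter | Default | Meaning |
|---|---|---|
| `spot_diameter_um` | 0.6 µm | nominal gene-signal size; also the 3D merge radius |
| `breakapart_cutoff_um` | 1.2 µm | pairs at/beyond this distance are break-apart (twice-or-more the spot diameter, hence the inclusive boundary) |
| `abnormal_fraction_cutoff` | 10% | negative diagnosis iff abnormal ≤ 10% of counted nuclei |
| `match_threshold` | 0.6 | NcC peak acceptance |
| `gaussian_sigma` | 1 px | noise reduction |
| `morphology_radius` | 2 px disk | opening/closing element |
| `min_component_px` | area of a 2 µm disk | isolated-vertex removal |
| `nucleus_volume_um3` | (15, 130) µm³ | QC size gate; the ceiling sits ~10% above the largest single nucleus the default geometry produces, so merged (non-individual) blobs fall outside it |
| `spot_floor_k` | 3 | candidates must exceed mean + k·sd inside the nucleus |

The split-signal accounting reconciles the greedy matcher with pattern
definitions phrased in separate signals: a matched pair called break-apart
contributes one separated FITC and one separated TRITC signal, so a
one-allele-split nucleus (one fusion plus one matched-but-distant pair)
classifies as the typical rearrangement `(C, G, R) = (1, 1, 1)`. The
pattern map is total on `(C, G, R)`: `normal` = (2, 0, 0);
`multiple_copy` = (>2, 0, 0); `typical_break` = (1, 1, 1);
`nontypical_break` = any other combination with separated signals in both
channels; `other` = any remaining non-empty combination; empty nuclei are
discarded from counting. Nuclei with the `other` pattern are reported but
do not enter the abnormal fraction by default — the diagnosis hinges on
rearrangement patterns — and `abnormal_includes_other = TRUE` flips that
choice.

## The synthetic generator

`generate_case()` exists so every stage is testable without clinical
slides. It emulates the target acquisition geometry — 7 layers, 0.6 µm
interval, 0.16 µm/pixel — and renders:

* ellipsoidal nuclei (in-plane semi-axes drawn from 3.2–4.2 µm, axial
  semi-axis 1.6 µm, centred mid-stack), placed fully inside the field and
  mutually separated by at least the sum of semi-axes + 2 µm, by rejection
  sampling;
* gene signals as Gaussian blobs, isotropic in µm (σ = 0.3 µm, half the
  nominal spot diameter, so rendered spots have ≈ 0.6 µm apparent size)
  sampled on the anisotropic voxel grid;
* per-nucleus patterns drawn from a configurable mix (default 55% normal,
  15% multiple copy, 10% typical break, 10% non-typical break, 10% other).

Signal sites are placed on a circle of radius `0.55 · min(a, b)` inside
the nucleus with equal angular spacing: this keeps same-channel spots more
than two spot diameters apart (resolvable) and separated opposite-channel
signals at 2.3–4 µm, far above the 1.2 µm decision boundary, so
ground-truth labels are unambiguous. Co-localized partners are offset
in-plane by a distance drawn from [0, 0.6] µm. All positions are snapped
to the voxel grid, so in the noise-free default the detected coordinates
equal the true ones exactly; the boundary behaviour of the cutoff itself
is tested separately with exact-geometry fixtures, not with rendered
images. Split-partner separations arise from the anchor geometry rather
than being sampled from a band; they land in roughly [1.8, 4] µm, which
serves the same purpose (staying away from the boundary).

What the generator does **not** emulate: optics beyond a Gaussian PSF (no
Airy rings or depth-dependent aberration), autofluorescence texture,
tissue-section truncation of nuclei, chromatic shift between channels, or
densely touching nuclei (a dedicated `include_unclear` flag deliberately
overlaps two nuclei to exercise QC). Passing the recovery suite therefore
demonstrates the correctness of the algorithmic chain under the stated
geometry, not robustness to every artifact of clinical material.

## Numerical choices

* All intensities are floating point in [0, 1]; 8- and 16-bit TIFF input
  is accepted. Generated stacks are quantized to the 16-bit grid so file
  round trips are bit-exact.
* Pixel indices are 0-based in every exported table; µm positions are
  `(x_px, y_px, layer) · (0.16, 0.16, 0.6)` and the conversion happens
  once, at spot extraction.
* Morphology ignores out-of-image pixels (erosion pads +∞, dilation −∞),
  which preserves anti-extensivity/extensivity and binary duality exactly.
* Component labels are assigned in column-major scan order of each
  component's first pixel, making labeling permutation-stable.
* The 3D merge radius carries a 1e-9 µm tolerance so grid arithmetic
  cannot split a candidate pair exactly one layer apart.
* Ties: spot plateaus keep all members as candidates and the merge picks
  the lowest `(layer, y, x)`; equal pair distances break by spot id;
  template peaks of equal score break by template index then position.
  Every tie-break is deterministic, so repeated runs are byte-identical.
* Greedy pairing is the ranked rule, not minimum-total assignment; the
  optimal assignment exists in the tests only, as an oracle for the
  mutually-nearest special case where the two coincide.

## Problem sizes in the test suite

The recovery suites run on 192×192-pixel fields (≈ 31 µm) with 4 nuclei
per case, 20 seeded cases end-to-end, plus brute-force oracle sweeps on
small random instances (images ≤ 12×12 for matching scores, ≤ 6 spots per
channel for pairing). These sizes were chosen so the whole suite exercises
every stage — including 3D linking across all 7 layers — while any single
case stays in the seconds range; nothing in the method depends on the
field being small, and the pipeline is routinely run on larger stacks via
the CLI.

## Known limitations

* Touching nuclei are not split (no watershed); they are discarded as not
  "clear individual" nuclei, which matches the counting convention but
  reduces yield in dense tissue.
* Spot centres are voxel-resolution (no sub-pixel Gaussian fitting), so
  distances carry up to half a voxel diagonal (≈ 0.32 µm) of quantization
  error; the 1.2 µm cutoff is four times that, and both the cutoff and
  the spot diameter are configurable where assays differ.
* The intensity floor (mean + 3·sd inside the nucleus) is a pragmatic
  guard against noise-driven local maxima; heavily textured backgrounds
  may need a different `spot_floor_k`.
* The diagnosis is a single-threshold rule on one case; no cohort
  statistics, probe-specific interpretation, or tumor-area detection is
  included.
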