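---
title: "Bilateral differential thermography: method, phantom model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral differential thermography: method, phantom model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem and the method

Lateral odontogenic facial cellulitis produces a localized inflammatory
focus whose skin surface is measurably warmer than the corresponding region
of the healthy side of the face. Under healthy conditions the two hemifaces
are thermally near-symmetric about the sagittal plane, so the healthy
hemiface can serve as a subject-specific thermal reference for the diseased
one. `hemitherm` implements this bilateral differential procedure on
calibrated skin-temperature rasters:

1. **ROI extraction.** Two rectangular regions of interest of identical size
   $(m, n)$ are taken from the healthy and diseased hemifaces, giving the
   temperature matrices $\langle H\rangle = (h_{ij})$ and
   $\langle D\rangle = (d_{ij})$.
2. **Mirror transform.** The healthy matrix is mirrored across its vertical
   axis, $\langle H^{*}\rangle = (h_{i,\,n+1-j})$ in 1-based notation, so
   that each pixel faces its contralateral counterpart.
3. **Differential map.** $\langle R\rangle = \langle D\rangle - \langle
   H^{*}\rangle$ is the pixel-wise thermal gradient attributable to
   inflammation.
4. **Severity thresholding.** Entries with $R_{ij} < \Delta T_{\mathrm{thr}}$
   are set to zero. The cut-off depends on the clinical severity grade:
   $3\,^\circ$C for severe and $2\,^\circ$C for moderate inflammation
   (`threshold_for_grade()`). A value *exactly equal* to the cut-off
   survives — the zeroing condition is a strict inequality, and the boundary
   case is tested explicitly. Because the cut-off is positive, negative
   differentials (diseased side cooler) are always zeroed; the signed map is
   retained pre-threshold for diagnostics (`asymmetry_summary()`).
5. **Hotspot segmentation.** The surviving suprathreshold pixels are grouped
   into connected components (`segment_hotspots()`); the largest is reported
   as the main inflammation site and repositioned into full-frame
   coordinates (`map_region_to_frame()`) for overlay display.

Steps 1–4 are the published procedure; step 5 is this package's
formalization of "the suprathreshold region": the source material displays
the surviving set but does not define how a discrete region is delineated,
so component labeling with a minimum-area filter is our explicit, tested
choice and is documented as such.

## Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `delta_t` (severe) | 3.0 | °C | cut-off for severe-grade inflammation |
| `delta_t` (moderate) | 2.0 | °C | cut-off for moderate-grade inflammation |
| `connectivity` | 8 | – | pixel adjacency for component labeling |
| `min_region_area` | 5 | px | smallest component kept |
| plausibility band | [15, 45] | °C | admissible finite temperatures |
| `emissivity` | 0.98 | – | skin emissivity, carried as metadata |

*Connectivity* defaults to 8 because inflammation contours are smooth and
the clinically reported morphologies ("elongated island", "comma-shaped")
are single diagonally-coherent blobs; 4-connectivity is available.
*`min_region_area` = 5* suppresses single-pixel noise survivors; the
published procedure performs no explicit despeckling, so `0` disables it.
Ties in the main-site choice are broken by higher maximum ΔT, then by the
top-left-most centroid, purely to make the ordering deterministic.

*Emissivity is metadata only.* Radiometric cameras apply the emissivity
correction internally before exporting temperatures; re-applying it would
require a radiative physics model that is out of scope. The affine
`radiometric_calibration()` (`T = gain · DN + offset`) supports raw
16-bit rasters from workflows that export digital numbers.

## Coordinate conventions

All public pixel coordinates are **0-based, row-major, origin at the image
top-left, with half-open ranges**. This matches raster conventions and
makes the hemiface split unambiguous: `axis_col` names the mirror line at
the *left edge* of column `axis_col`, so the two ROIs cover
`[axis_col - w, axis_col)` and `[axis_col, axis_col + w)` and no pixel
belongs to both. The 1-based matrix notation of the method description is
translated at the package boundary. ROI sizes are stated rows × columns;
the published 350 × 250 analysis ROI is adopted as rows × columns.

ROI pairing assumes pixel correspondence between the two hemiface ROIs is
given by acquisition geometry; no image registration is performed (the
method's own stated limitation), and midline/landmark detection is a
non-goal — the symmetry axis is always user-supplied.

## The thermal phantom

No patient thermograms are distributable, so validation uses a synthetic
phantom (`phantom_spec()`, `generate_case()`) that emulates the *statistical
premises* of the method rather than facial anatomy:

- a shared smooth physiologic texture (standard deviation
  `texture_amplitude`, default 1 °C), mirror-symmetric between hemifaces —
  healthy facial skin temperature is non-uniform (vascular patterning) but
  contralaterally symmetric;
- a smooth contralateral **asymmetry field** (`asymmetry_sigma`, default
  0.3 °C) — residual physiologic departure from perfect symmetry. The
  default is deliberately well below the 2 °C moderate cut-off so that
  healthy phantom pairs yield empty detections; it is a package calibration,
  not a literature value, as no quantitative healthy-face asymmetry
  distribution is published;
- independent per-pixel sensor noise (`noise_sigma`, default 0.1 °C);
- an injected elliptical inflammation focus (`hotspot_spec()`) with plateau
  or Gaussian profile and known ground-truth mask.

Smooth fields are low-pass-filtered white noise: white noise is generated on
a grid extended by three correlation lengths on every side, convolved with a
Gaussian kernel by FFT, and cropped, so the retained field is stationary
(no edge-variance artifacts). `texture_scale` (default 40 px) is the
Gaussian kernel sigma; at the scale of a 350 × 250 hemiface ROI this
corresponds to vascular-territory-sized structures (~1.5 cm), which is also
used for the asymmetry field. The field is standardized to unit sample
standard deviation before scaling, so the generative closed form
$\mathrm{sd}(R) = \sqrt{\sigma_{\mathrm{asym}}^2 + 2\sigma_{\mathrm{noise}}^2}$
holds exactly in expectation and is verified by simulation.

The ground-truth mask is the set of pixels whose *injected increment*
reaches the severity cut-off in use — this makes recovery well-posed: with
all noise terms zero and a plateau profile, the pipeline must return the
truth mask pixel-for-pixel (Dice = 1), which is asserted in the tests. A
half-maximum truth definition is available via `truth_rule = "half_max"`.
The default validation focus is a plateau-profile ellipse of amplitude
3.5 °C against the 3 °C severe cut-off: with a plateau, the truth boundary
is the ellipse itself and recovery measures the method, whereas a Gaussian
profile places the truth boundary on the flat flank of the profile, where
it is dominated by noise geometry rather than by the procedure under test.

What the phantom does *not* emulate: facial anatomy and landmark structure,
perspective/pose differences between the two profile acquisitions,
emissivity-angle errors on strongly convex swollen surfaces, and subsurface
heat diffusion (no bioheat PDE). Passing phantom tests therefore
demonstrates correctness of the matrix procedure and detection logic under
the stated statistical premises — not clinical performance on real faces.

## Numerical choices and degenerate inputs

- Temperature grids are written at 17 significant digits, so write → read
  is exact for doubles; dialects cover comma/semicolon/tab delimiters and
  decimal commas (common in European thermography exports).
- Invalid pixels are non-finite, propagate through arithmetic, and are
  excluded from every statistic; an all-invalid map is an error, not a NaN.
- Component labeling builds a pixel-adjacency graph and takes its connected
  components (igraph); an independent brute-force flood fill in the test
  suite verifies it on random matrices for both connectivities.
- Elongation is the major/minor axis ratio from the pixel-set inertia
  tensor with a 1/12 per-pixel (unit-square) correction, so a single pixel
  has elongation 1 and an $a \times b$ rectangle exactly $a/b$.
- Dice/Jaccard are defined as 1 when both masks are empty; centroid
  distance is NA when exactly one mask is empty.
- A constant matrix renders as a flat surface by expanding the degenerate
  z-range by ±0.5 °C for display only.
- Rendering avoids device state where determinism matters: overlays and
  label images are composed as pixel arrays and written directly, so fixed
  inputs give byte-identical files.

## Problem sizes used in the shipped checks

Validation simulations use hemiface frames of 350 × 250 px (the published
ROI size) with 20 seeds for the severe-grade recovery and healthy-pair
specificity studies, 50 seeds for the differential-spread closed form, and
200-case property suites for the algebraic invariants — sizes chosen to
make the statistical assertions sharp while keeping the whole suite fast on
a laptop.

## Longitudinal comparison

`compare_sessions()` compares two analyses of identical ROI geometry and
cut-off (e.g. admission vs a 48-hour control under antibiotics) and labels
the course `regressing` / `progressing` / `stable` / `mixed` from the joint
movement of maximum ΔT and main-region area. The label is descriptive
bookkeeping for monitoring, not a clinical judgement; hospitalization
scoring is explicitly out of scope.

## Known limitations

- Median and paramedian cellulitis cannot be analyzed: the method requires
  a healthy contralateral reference.
- No thermal-to-photograph or thermal-to-CT registration: overlays are in
  thermal-frame coordinates only.
- No atmospheric, distance or emissivity-angle corrections; strongly convex
  swollen surfaces bias the reference juxtaposition.
- Deep-space infections are outside the physical reach of surface
  thermography; the package makes no claim about them.
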