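---
title: "Scoring human and AI-assisted sella annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring human and AI-assisted sella annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sellabench)
```

## The problem

In endoscopic transsphenoidal pituitary surgery the sella turcica is the safe
entry zone: the surgeon must recognise its extent on a cluttered endoscopic
view before opening it. A natural way to measure how well clinicians do this —
and whether an AI segmentation overlay helps — is a two-round annotation
study: participants of different expertise levels outline the sella on a set
of still frames, first unassisted (round `PRE`), then with the AI's predicted
outline overlaid, free to keep or revise their annotation (round `POST`).
Every outline is scored against a multi-round expert-consensus ground truth.

`sellabench` implements the full analysis for such a study: rasterization of
polygon annotations, per-annotation metrics, subgroup summary tables with
exact paired statistics, multi-rater agreement heat maps, and a synthetic
study generator that emulates the design (4 expertise groups × 6 annotators ×
6 images × 2 rounds) so that every stage is testable without access to any
study's raw annotations.

## Metrics

All scoring operates on binary masks on the image pixel grid. A polygon with
vertices in continuous pixel coordinates (origin top-left, y downward) is
rasterized by the pixel-centre rule: pixel $(r,c)$ is labelled iff its centre
$(c+0.5,\, r+0.5)$ lies inside the ring under the even-odd rule. This makes
integer-cornered rectangles rasterize to their exact geometric area and is
deterministic; it is this package's convention — annotation platforms do not
document theirs.

For a ground-truth mask $G$ and participant mask $P$, with
$\mathrm{tp}=|G\cap P|$, $\mathrm{fp}=|P\setminus G|$,
$\mathrm{fn}=|G\setminus P|$:

* **DICE score** $= 2\,\mathrm{tp}/(2\,\mathrm{tp}+\mathrm{fp}+\mathrm{fn})$,
  reported as a percentage. Both masks empty scores 1 (perfect agreement on
  absence); exactly one empty scores 0. These conventions never arise in a
  realistic study but make the function total.
* **False-positive / false-negative fractions**: fp and fn each divided by
  the *union* area $\mathrm{tp}+\mathrm{fp}+\mathrm{fn}$. With this
  denominator the DICE score is recovered exactly from the error fractions:
  $$\mathrm{DICE} = \frac{2(1-\mathrm{fp}_u-\mathrm{fn}_u)}{2-\mathrm{fp}_u-\mathrm{fn}_u}.$$
  The identity is property-tested on random masks, and is also how the union
  reading of the published tables was confirmed: plugging the published
  overall error means (24.6%/20.7% pre, 19.8%/17.0% post) into it reproduces
  the published overall DICE means (70.7%, 77.5%) at printed precision.
* **Centroid inclusion**: whether the pixel containing the area centroid of
  $G$ is labelled in $P$ — a proxy for having recognised the middle of the
  sella at all. The test is run on the rasterized mask, not by
  point-in-polygon on the ring, because the analysis elsewhere operates on
  masks. Note the centroid of a non-convex mask can fall outside the mask
  itself (an annulus is the canonical counterexample, and is in the tests).
* **Change classification**: an annotation counts as changed after AI
  assistance if *any* pixel differs between the two rasterized masks — the
  most conservative reading. Its DICE outcome (improved / worsened /
  unchanged) compares scores with tolerance $\tau = 10^{-9}$, i.e.
  effectively exactly; a changed annotation with equal DICE (possible, e.g.
  mirrored offsets) is classified unchanged in performance.

## Statistics

Subgroup summaries aggregate over all participant-image records in a stratum
(36 per group, 144 overall in the full design), because the paired test is
defined at participant-image granularity. SDs use the sample ($n-1$)
denominator. Differences are computed from unrounded means.

* **Wilcoxon signed-rank** (DICE pre vs post): zero differences dropped
  (classic reduction, not Pratt), mid-ranks for ties. For $n \le 25$
  effective pairs the two-sided p is exact over all $2^n$ sign assignments,
  computed by generating-function convolution over doubled mid-ranks (valid
  under ties, identical to enumeration); above that, a normal approximation
  with tie and continuity correction. Two-sided p is
  $2\min(P(W\le w), P(W\ge w))$ clamped to 1.
* **Fisher's exact test** (centroid-inclusion proportions pre vs post):
  two-sided by minimum-likelihood summation — the sum of hypergeometric
  probabilities not exceeding the observed table's (relative tolerance
  $10^{-7}$).
* **Exact McNemar** (per-participant "centroid hit on all images" paired
  indicator): $p = \min(1,\, 2 P(X \le \min(b,c)))$,
  $X \sim \mathrm{Bin}(b+c, \tfrac12)$; degenerate (p = 1) with no
  discordant pairs.

The centroid analysis deliberately runs at both granularities — per
annotation (Fisher) and per participant across all images (McNemar) — since
the study design uses both without reconciling them. No multiple-testing
correction is applied and no confidence intervals are produced, matching the
reporting style being emulated.

## Agreement heat maps

For each (group, image, round) the per-pixel count of annotators labelling
that pixel is computed and normalized by the subgroup size (not the global
maximum), so the pre and post maps of one subgroup share a scale. The map is
rendered through a pinned sequential palette (`hcl.colors`, default
"viridis") with the ground-truth ring overlaid in white and the AI ring in
black, drawn from the cleaned polygon rather than the raster for crisp
contours. Rendering is deterministic: identical inputs give byte-identical
PNGs. Raw normalized counts are used — no smoothing.

## The synthetic study generator

The generator emulates the *statistical structure* of a two-round study, not
endoscopic image appearance. Its stated world:

* **Ground truth**: a star-convex radial shape
  $r(\theta) = r_{\mathrm{ellipse}}(\theta)\,(1+\sum_k a_k\cos(k\theta+\varphi_k))$
  sampled at 360 equal angles on a 720×576 frame (PAL video geometry),
  semi-axes ~13–21% of the frame, harmonic amplitudes bounded (total
  ≤ 0.12) so the ring stays star-convex and contains its centroid pixel.
* **AI prediction**: the ground-truth radial profile perturbed by a smooth
  harmonic noise shape whose amplitude is bisected until the rasterized DICE
  hits 0.85 ± 0.02 — the configurable stand-in for a trained model of known
  quality.
* **Round 1**: each annotator's ring is the ground-truth profile times
  $1+g(\theta)$, with $g$ a smooth 4-harmonic noise field of pointwise SD
  `boundary_noise_sd`, plus a Gaussian placement offset
  (`center_offset_sd` px).
* **Round 2**: with probability `adoption_prob` the radial profiles of the
  pre annotation and the AI ring are blended
  ($w\cdot\mathrm{AI} + (1-w)\cdot\mathrm{pre}$) about a common centre;
  otherwise the pre annotation is kept verbatim.

Default profiles (noise SD / offset px / adoption / blend):
students 0.40/22/0.90/0.85, junior 0.32/16/0.75/0.75, intermediate
0.30/14/0.50/0.65, experts 0.26/10/0.30/0.50. Adoption endpoints (0.9, 0.3)
and the AI quality (0.85) are the stated behavioural conditions; the noise
scales are this package's single a-priori calibration, chosen so unassisted
group means land in the 66–78% DICE band reported for studies of this kind,
monotone in expertise, and were not revisited after the acceptance
replicates were first run.

Numerical details worth knowing:

* Blending needs a centre interior to both rings. The pre centroid is used
  when valid; otherwise a pixel of the rasterized intersection of the two
  rings (whose membership rule is exactly "centre inside both") is used; for
  disjoint rings the annotator keeps their outline if $w<0.5$ and takes the
  AI outline otherwise. The fallbacks are exercised mainly at small test
  frames, where absolute placement noise is large relative to ring radius.
* Radii are clamped to stay ≥ 1 px and ≥ 1 px inside the frame, so generated
  rings are always simple and in-frame; no rejection sampling is needed.
* Every generator output is a pure function of `study_config$seed`;
  `generate_study()` restores the caller's RNG stream.

**What a green test establishes — and what it does not.** The synthetic
world reproduces the design's *qualitative* signature: expertise-ordered
unassisted accuracy, expertise-ordered AI uptake, and therefore improvement
monotone decreasing from students to experts, with centroid-hit proportions
non-decreasing after assistance. It does not reproduce — and the tests never
assert — any particular published DICE mean. Two realism gaps are known:
smooth radial blending toward a good AI essentially never *worsens* an
annotation, whereas real annotators redrawing by hand sometimes do (the
study being emulated saw ~17–22% worsened); and annotation error here is
smooth and star-convex, whereas real errors include occlusion-driven,
locally catastrophic mistakes.

## Degenerate inputs and tie-breaks

* Rings: consecutive duplicate vertices dropped, unclosed rings closed
  implicitly, self-intersecting rings rejected with an error (silent repair
  would change areas invisibly); out-of-frame vertices clipped with a
  warning; a ring rasterizing to zero area raises a degenerate-annotation
  error naming annotator and image.
* A pixel centre exactly on a span boundary is resolved half-open
  (`[enter, exit)`), which is what makes integer rectangles exact.
* Missing PRE/POST partners never fail a load; they are listed in the
  dataset's completeness report and excluded from paired analyses with a
  logged count.
* All-zero paired differences and empty discordant sets give degenerate
  p = 1 results carrying a flag rather than errors.

## Limitations

Only single-ring polygons without holes are supported; boundary-distance
metrics (Hausdorff, surface DICE) are out of scope, as are video decoding
and any attempt to replicate a specific annotation platform's rasterizer.
The PNG codec reads the subset of PNG it needs (8-bit non-interlaced
greyscale), by design.
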