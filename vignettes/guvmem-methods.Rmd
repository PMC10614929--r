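---
title: "Methods: quantifying Ca2+-dependent membrane recruitment with guvmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Ca2+-dependent membrane recruitment with guvmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvmem)
```

## The scientific setting

Penta-EF-hand Ca2+ sensors such as ALG-2 are recruited to acidic membranes
when calcium binding flips the electrostatic character of their EF-hand
face. Two complementary read-outs quantify this recruitment. In a
reconstitution assay, giant unilamellar vesicles (GUVs) containing
phosphatidylserine (PS) are imaged by multi-channel confocal microscopy:
the lipid dye channel shows each vesicle as a bright ring, and a
fluorescently labeled protein appears as discrete puncta on the ring when
it binds. The headline statistic is the proportion of GUVs carrying at
least one punctum, optionally combined with bounding-box colocalization
between two protein channels. In all-atom molecular dynamics simulations
of the protein above a PS/PC bilayer, recruitment is quantified as
per-residue lipid-contact frequencies, the number of residues in membrane
contact over time, and direct Ca2+-lipid coordination events.

`guvmem` implements both arms as a tested, seedable pipeline, together
with the Kabsch superposition RMSD used to verify that charge-reversal
mutations leave a model structurally unperturbed, and the Student t /
one-way ANOVA tests used on the assay read-outs.

## The puncta-calling pipeline

For every recognized GUV, the protein-channel crop (the GUV bounding box
padded by `crop_pad`, default 4 px) is processed independently, in this
fixed order:

1. **Background estimate and subtraction.** `compute_li_threshold()`
   finds the minimum-cross-entropy (Li) background/foreground split by
   exhaustive search over the intensity levels present. Every level in
   the gap between the optimal background and foreground classes
   minimizes the cross entropy equally; the class-boundary midpoint is
   returned as the canonical threshold. The crop minus this background is
   clipped at zero.
2. **Non-local-means denoising** (`nl_means_denoise()`), patchwise with
   weights `exp(-d2/h^2)`; defaults `nl_h = 10`, `nl_patch = 7`,
   `nl_search = 21`.
3. **Gaussian blur** (`blur_sigma = 1` px) to regularize spot shape.
4. **8-bit quantization, contrast guard, histogram equalization.** The
   crop is mapped to 0..255 at the image bit depth and the classic
   CDF-based global equalization is applied per crop.
5. **Otsu mask.** `compute_otsu_threshold()` minimizes the within-class
   intensity variance by exhaustive search over all 255 candidate levels
   (smallest level on ties); the mask is all pixels strictly above it.
6. **Connected components.** Components larger than 5 pixels (area >= 6;
   a strict reading of "larger than 5") under 8-connectivity (default;
   4 available) become puncta.

The proportion of GUVs with puncta is the number of GUVs with at least
one punctum over all recognized GUVs. Two puncta from different channels
colocalize when their half-open bounding boxes intersect; the reported
proportion divides the colocalized count in the channel with more puncta
by that channel's count (on ties, the larger of the two colocalized
counts, which makes the measure symmetric under channel swap).

### Choices behind the unstated parameters

The assay fixes only the component-size rule. The filter parameters above
are package defaults, exposed in `pipeline_params()`; planted-truth
recovery is stable under ±50% changes of each (this is tested). Two
numerical choices deserve explanation:

* **Integer arithmetic.** Every stage operates on quantized 8-bit
  integers, as in the uint8 image pipelines this emulates. This matters
  for specificity: in a structure-free crop the denoised residual
  flattens to a span of 2-3 grey levels, and keeping the arithmetic
  continuous would let the later equalization stretch that residual into
  large spurious foreground components.
* **Contrast guard (`min_contrast = 8`).** A crop whose denoised dynamic
  range is within 8 grey levels is treated as structure-free background
  and yields no foreground. The bound sits well above the quantization
  floor (2-3 levels) and far below any spot with usable signal-to-noise
  (a spot at 10x the noise SD spans > 50 levels after the chain), so it
  acts as a degenerate-input guard, not a sensitivity dial.

## GUV recognition

The study this pipeline emulates used a trained object detector for GUV
recognition. A trained network is not reproducible from a text
description, so `detect_guvs()` is a deterministic gradient-vote circle
transform: central-difference gradients after a light separable Gaussian
smoothing (`smooth_sigma = 1`; a direct spatial convolution, so detection
is exactly translation-equivariant away from the borders), votes cast a
radius away along each strong gradient line for all integer radii in
`[r_min, r_max]`, candidates ranked by circumference-normalized pooled
votes, non-maximum suppression at half the radius sum, and a final radius
refinement as the background-subtracted, circumference-corrected
intensity centroid of pixel distances in an annulus (the rendered and the
physical ring profile are symmetric about the crest, so this centroid
recovers the crest radius). On noiseless planted scenes recall and
precision are 1.0 with centers within 2 px and radii within 10%.
Detections from any external detector can be substituted through
`import_detections()` and the JSON detection format; both paths share
sorting and the edge policy (`exclude` drops circles whose box exits the
frame).

## Trajectory analytics

Distances use the minimum-image convention in an orthorhombic box; atoms
whose names begin with H are excluded by default (heavy-atom convention).
A residue is in contact in a frame when any of its atoms lies within the
contact cutoff of any lipid atom. The cutoff behind the published contact
figures is not stated; the package default is 0.40 nm, a common
heavy-atom minimum-distance convention, and it is configuration-exposed.
The synthetic tests are cutoff-agnostic by construction (planted
distances sit at 0.70-0.95x and 1.5-3x the cutoff), so they validate the
analytics rather than that choice. Frequencies are percentages of
analyzed frames over the trailing analysis window (default: final
1000 ns, sampled at 2 ns), with splits for PS lipids, PC lipids and
acyl-region atoms. `aggregate_replicates()` requires identical time
grids (no interpolation), returns the pointwise mean ± SE across
replicates, and time-averaged per-replicate contacts ± SD over the
window; `compare_conditions()` is the one-tailed pooled t-test for
reduced binding (p = 0.5 by convention when both groups are constant and
equal).

Ca2+ coordination events are maximal runs of consecutive sampled frames
in which an ion sits below 0.35 nm from the phosphate oxygens (default
names O13/O14/O11/O12) of one lipid molecule; duration is the run length
times the frame spacing, so a 3-frame run at 2 ns spacing is a 6 ns
event. Events are counted per ion-lipid pair: one ion bridging two lipids
simultaneously yields two events. The per-ion distance to the nearest
lipid atom of any type is returned alongside, supporting summaries of
ions held away (> 0.5 nm) from the membrane.

## Synthetic data with planted truth

Both generators are deterministic under their spec's seed and emit the
exact ground truth of what they plant.

**Scenes** (`generate_guv_scene()`): each GUV is an annular Gaussian ring
in the lipid channel; each punctum a 2-D Gaussian spot centered on the
ring in a protein channel; plus a constant background offset and additive
Gaussian noise clipped to the bit-depth range (Poisson/shot noise, PSF
convolution, bleaching and vesicle deformation are deliberately out of
scope). `sample_scene_spec()` drafts a typical field of view: 10 GUVs of
radius 10-15 px on a jittered grid with center separation at least twice
the maximum radius, ring amplitude 140, background 20, noise SD 6 and
spot amplitude 120 (spot SNR 20) on an 8-bit range - values chosen once
as representative of a well-exposed confocal field. Planted
colocalization pairs two channels' spots at the same ring position;
the truth proportion uses the same counting rule as the measurement.

**Trajectories** (`generate_trajectory()`): the membrane is a static
schematic slab of one-atom lipid sites on a 1 nm lateral grid (30% PS,
70% PC, matching the reconstitution composition), each tagged headgroup
or acyl. A scheduled residue is placed directly above a site of the
scheduled class/region at a distance drawn within the cutoff; since the
grid spacing exceeds every cutoff, the nearest lipid atom is always the
designated site and the schedule *is* the truth, with guaranteed margins
on both sides. This deliberately ignores lipid dynamics - only distances
matter to the analytics under test. Consequently, passing tests show the
measurement chain is exact given coordinates; they do not validate force
fields, sampling, or the contact-cutoff choice on real trajectories.

## Superposition

`kabsch_superpose()` is the closed-form least-squares rigid alignment
(SVD of the cross-covariance with the determinant sign correction, so the
returned rotation is always proper). `backbone_rmsd()` pairs N/CA/C/O
atoms (or CA only) by author residue number over an inclusive range -
appropriate for comparing a predicted mutant model against a crystal
structure of the same protein with the same numbering - and errors
listing any gaps. Collinear point sets are rejected since the optimal
rotation is then not unique.

## Statistics

`unpaired_t_test()` is the pooled-variance Student test (`df = n1+n2-2`),
as cited for the assays, with Welch behind a flag; `one_way_anova()` the
classic fixed-effects F-test. Degenerate inputs follow documented
conventions: identical constant groups give p = 1 (two-tailed t and
ANOVA), p = 0.5 for the one-tailed comparison. Both delegate to the
standard distribution implementations; tests verify the closed forms and
the two-group identity F = t².

## Problem sizes and reproducibility

The shipped tests validate thresholds and component labelling against
exhaustive per-pixel oracles (200 and 100 random crops/masks), scene
recovery on 50 seeded two-channel scenes (pooled recovered proportions
within ±0.05 of truth; the ±50% parameter sweep uses 10 scenes per
setting), contact analytics on 151-501 frame trajectories with six
replicates, event scanning against a run-length oracle on 1000 random
series, and superposition against a numerical rotation-space minimizer.
`scripts/acceptance.R` re-runs the same measurements from scratch under a
caller-supplied seed. All randomness flows through explicit seeds; fixed
inputs produce byte-identical CSV outputs.

## Known limitations

* The default detector assumes approximately circular, non-adhered
  vesicles; overlapping clusters are out of scope (use the import path
  with a specialized detector).
* The noise model is additive Gaussian; strongly Poisson-limited images
  may need different filter strengths.
* Colocalization is bounding-box overlap, not intensity correlation;
  sub-pixel localization and 3-D stacks are out of scope.
* The contact cutoff and the heavy-atom convention are defaults, not
  facts about the emulated study; report them with any result.
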