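---
title: "Structure-aware synthetic data for leaf instance segmentation"
author: "leafgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware synthetic data for leaf instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgen)
```

## The problem

Training an instance segmentation network to delineate individual leaves
requires many images annotated with one pixel mask per leaf. Manual
annotation is the bottleneck: leaves repeat similar textures and occlude
each other heavily, which is also why zero-shot foundation segmenters
underperform on plants. leafgen takes the opposite route: it *generates*
annotated data. Because every plant is built from an explicit structural
model, the per-leaf masks are exact by construction — including the
occluded parts — and an arbitrary number of image-mask pairs can be
produced from one grammar.

The pipeline is:

1. **Grammar** — a hierarchical L-system: a leaf grammar `G_l` derives a
   string `s_l` describing one leaf; a plant grammar `G_p` derives the
   whole-plant string `s_p`, with `s_l` embedded at placeholder positions.
   Each embedding is wrapped in organ-span markers, so the final string
   decomposes into `K` leaf organs plus a stem/branch skeleton.
2. **Geometry** — a 3D turtle interprets the string into triangle meshes,
   one mesh per organ (`M = T(s, d(v, t))` in the classic turtle-graphics
   formulation: each symbol `v` or `t` has a drawing action `d`).
3. **Masks** — a software z-buffer rasterizer projects the model under a
   camera and labels each pixel with the frontmost leaf instance. Visible
   masks are the label level sets; amodal masks rasterize each leaf alone,
   ignoring occluders.
4. **Textures** — each per-leaf mask patch (tight bounding box, padded) is
   mapped to an RGB texture. The contract is simply `P_s = G(P_m)`: any
   function from mask patch to equally-shaped texture patch. The default
   `G` is a deterministic procedural generator; a trained image-to-image
   network (e.g. a pix2pix-style conditional GAN) plugs in through the
   same `texture_generator()` interface.
5. **Composition** — cut-and-paste: textured patches are pasted
   back-to-front onto a background, replacing only pixels where the mask
   is 1 (the generated patch includes its own background, which is masked
   out). An optional pluggable refiner then maps the composed image to a
   more natural-looking one; the default refiner is the identity.
6. **Export and evaluation** — COCO instance JSON (plus a parallel amodal
   file), AP at an IoU threshold, and foreground mean absolute error.

## Grammars and derivation

A grammar is `{V, T, ω, P}`: nonterminals, terminals, axiom, and
productions. Productions are parametric (`A(n)` with arithmetic
expressions over `n` in the successors), conditional (`A(n) : n > 0 ->
...`), and stochastic (weighted alternatives `-> (0.7) X | (0.3) Y`).
Rewriting is parallel and context-free (D0L/stochastic 0L semantics);
nothing in the pipeline needs context-sensitive rules, so they are not
supported.

Two numerical choices matter for reproducibility:

* **Counter-based stochastic draws.** The successor chosen at string
  position `p` in iteration `i` comes from a stateless hash of
  `(seed, i, p)`, not from a sequential RNG stream. Editing an unrelated
  rule therefore cannot shift the draws of other positions, and a
  `(grammar, n, seed)` triple always reproduces the same string, bitwise.
* **Seed splitting.** Hierarchical expansion derives the k-th embedded
  organ with a child seed hashed from `(seed, k)`; dataset generation
  derives record `i` from `(master seed, i)`. All derived seeds stay below
  2^31.

The rule expression language is deliberately tiny — arithmetic,
comparisons, `sin`/`cos` (degrees) and `pow` — and is validated against the
rule's formal parameters at parse time, then evaluated in a sealed
environment.

`derive(g, 0, seed)` returns the axiom for every grammar, and for the
textbook two-symbol expansion grammar (`A -> AB`, `B -> A`) the derived
string length follows the Fibonacci law `|s_n| = Fib(n + 2)`; the test
suite checks both against an independent character-level rewriter.

## Turtle interpretation

The command table is the classic bracketed-L-system alphabet
(`F f + - & ^ \ / | [ ] { . } ! '`), with an optional numeric parameter
overriding the default angle or step. The turtle starts at the origin
heading +Z with left +X and up +Y (right-handed), so a top-down camera on
the −Z axis sees a rosette as an overhead photograph would. Stems are
drawn as quadrilateral ribbons of the current width rather than true
cylinders, and leaf blades are polygon fans (`{ . }` capture, fan from the
first vertex, non-planar polygons allowed, zero-area triangles dropped):
the product of this renderer is masks, not shading, so silhouette
fidelity is what matters. Rotations are applied by Rodrigues' formula and
the frame is re-orthonormalized after every turn, keeping `G Gᵀ − I`
below 1e−8 even after 10⁴ random rotations.

Geometry emitted inside an organ span goes to that organ's mesh; leaves
are renumbered 1..K in order of first emission (branches after, stem is
instance 0), so mesh decomposition mirrors string decomposition exactly.

## Mask rendering

The rasterizer projects every triangle (orthographic by default;
perspective available) and scanline-fills it against one z-buffer spanning
all organs, testing pixel centres at `(col + 0.5, row + 0.5)` with an
inclusive barycentric tolerance of 1e−9. Design choices, made where the
rendering pipeline is genuinely open:

* **Visible vs amodal.** The label image stores the frontmost *leaf* per
  pixel; stems and branches occlude but label 0. Amodal masks rasterize
  each leaf with no depth test against other organs, so
  `amodal ⊇ visible` per instance and `visibility = |visible| / |amodal|`
  quantifies occlusion. Training exports default to visible masks (what a
  photograph shows); amodal export is explicit, for amodal-segmentation
  training data.
* **Depth ties.** Coplanar overlapping leaves are resolved to the lower
  instance id — arbitrary but deterministic, and mirrored by the
  brute-force ray-sort oracle in the tests.
* **No anti-aliasing.** Masks are hard binary labels; annotation formats
  require it.
* **Minimum instance area.** `crop_patches()` skips instances under 16
  visible pixels by default: sub-pixel slivers produce degenerate texture
  patches and poison AP evaluation.

The rasterizer is validated exactly — per-pixel — against a brute-force
"collect all ray hits, sort by depth" oracle on random triangle models,
and the visible masks are checked to partition the rendered foreground.

## Procedural textures and backgrounds

The default texture generator is deterministic given `(mask, style,
seed)`: base colour with per-patch jitter, shading by normalized distance
to the mask boundary (`rim_darkening`), a midrib along the mask's
principal axis with paired secondary veins (`vein_density` per midrib
pixel), and uniform speckle noise. Outside the mask the patch is filled
with a background colour, mimicking generated patches that contain their
own background; composition masks it out again. Backgrounds are
multi-octave value noise through a soil colour ramp. Distance transforms
come from EBImage; everything else is base R.

These procedural components are stand-ins with the same interfaces as
learned models, which keeps the pipeline self-contained and exactly
reproducible. The adversarial (`cgan_loss`) and reconstruction
(`l1_loss`) objectives used to train such models are implemented as pure
functions on given arrays — `mean(log d_real) + mean(log(1 − d_fake))`
and mean absolute difference — with the conventional weights 0.01 and 1
in `total_objective()`; no network is instantiated here.

## Composition and refinement pairs

Pasting is back-to-front by the camera depth of each leaf's centroid.
Hard blending replaces mask pixels verbatim; feathered blending
alpha-blends within a distance band inside the mask boundary. In both
modes pixels outside every mask are bit-identical to the input
background — the conservation property the acceptance tests assert over
random layouts.

Cut-and-paste seams are the known artifact of this composition. The
package therefore constructs *refinement pairs*: given an archive of
mask patches extracted from real images (the on-disk schema matches what
a text-prompted zero-shot segmenter produces: per-image mask/texture
patch PNGs with bbox, prompt and score), `build_refinement_pairs()`
overwrites each real leaf region with the generator's texture, yielding
aligned (leaf-replaced, original) image pairs on which an image refiner
can be trained self-supervised. The refiner itself is out of scope; it
plugs in as any `function(image) -> image`, identity by default.

## Evaluation metrics

`ap_at_iou()` implements two readings of AP, because "percentage of
correctly predicted instances" and COCO's interpolated AP are different
quantities: the `"precision"` variant (default) is 100 × matched
predictions / total predictions after greedy score-ordered matching at
IoU ≥ τ, with recall reported alongside; the `"coco"` variant is the
101-point interpolated average precision over the pooled ranked list.
Matching is greedy and deterministic (score ties to the lower prediction
index, IoU ties to the lower ground-truth id); the suite compares its
match counts against exhaustive optimal assignment on small instance
sets, where greedy agrees in ≥ 95% of random cases. Instances are pooled
across images; per-image counts are reported in `eval_report()`.
`foreground_mae()` restricts the mean absolute image difference to a
ground-truth foreground mask — foreground always comes from ground
truth, never from predictions.

## Presets and the synthetic study conditions

Two toy grammars ship as fixtures. `rosette` places exactly 8 equal
leaves on pitched petioles at golden-angle azimuths — deterministic, so
its leaf count is grammar-implied and every record must contain exactly 8
instances. `shoot` is a stochastic branching shoot whose leaf count
varies with the seed. They demonstrate the dialect and drive the tests;
they are the package's own constructions, not reproductions of any
published species grammar (such grammars are typically species-specific
and tuned by hand). Default working sizes — 512² images for end-to-end
checks, 384² for the acceptance script, 20–48 px oracles for the
rasterizer — were chosen once so the full suite runs comfortably on a
laptop-class single core.

What the synthetic data does *not* emulate: photographic texture
statistics (the procedural generator is far simpler than a trained GAN),
leaf bending and curvature (blades are flat fans; a 3D modeller would
bend them), soil clutter, shadows, and camera noise. Passing tests
therefore certify the *structural* contracts — mask correctness,
occlusion handling, determinism, format round-trips, metric definitions —
not photorealism; closing the sim-to-real gap is exactly the role of the
pluggable texture generator and refiner.

## Known limitations

* Context-sensitive and environmental L-systems are not supported.
* Perspective rendering interpolates depth affinely across triangles
  (exact for the orthographic default; a small approximation for
  perspective at steep depth gradients).
* COCO polygon segmentation encodes holes via even-odd filling across a
  single annotation's polygons, which decodes exactly here but is
  stricter than some third-party COCO readers; RLE (the default) is
  fully standard.
* The 16-bit label-image PNG supports at most 65535 instances per image;
  COCO export is unaffected.

## A worked example

```{r example, eval = FALSE}
cfg <- generation_config(preset_grammar("rosette"), iterations = 8,
                         count = 2, seed = 7, image_size = c(256, 256))
records <- generate_dataset(cfg)
records[[1]]
#> dataset record img_0001 : 256x256 px, 8 leaf instances
round(unlist(records[[1]]$masks$visibility), 3)
#>     1     2     3     4     5     6     7     8
#> 0.936 0.937 0.936 0.992 0.992 0.992 0.992 0.993
write_coco(records, "rosette_dataset")
```
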