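---
title: "Achromatic contrast-preserving daltonization: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Achromatic contrast-preserving daltonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daltonize)
```

## The model

A red–green dichromat cannot distinguish colors that differ along a single
direction of color space — the confusion direction. We model dichromat
perception with the Viénot linear projection: in scene-linear RGB (sRGB
primaries), the simulated color is `c_s = D̂ c`, where `D̂` is a 3×3 rank-2
idempotent matrix whose rows each sum to one. Those algebraic properties are
not incidental: idempotence means simulating a simulated image changes
nothing (a dichromat and a trichromat agree on what the simulated image looks
like), and unit row sums mean the whole gray axis — and with it blue and
yellow, which have equal R and G — passes through untouched. The kernel of
`D̂` is the confusion direction: `kernelDirection()` returns it, and the
synthetic fixtures step a base color along it to build images whose contrast
is *exactly* invisible to the target observer.

The daltonization idea is a constraint, not a preference: the output image is

$$u = w \odot u_0,$$

a per-pixel scalar weight times the original. Scaling an RGB vector leaves
its chromaticity unchanged (CIE xy, and the proLab chromaticity used by our
naturalness metric, are ratios that cancel the scale), so *no choice of `w`
can alter any hue*. All the freedom — and all the risk — lives in the
achromatic component. The optimization then asks: choose `w` so that the
local contrasts of the simulated output match the local contrasts of the
original.

Local contrast is pairwise: for every horizontal and vertical neighbor pair
$(p, q)$ we want

$$\left\| \hat D (w_p u_p) - \hat D (w_q u_q) \right\|_2 \;=\;
  \left\| u_p - u_q \right\|_2 .$$

Substituting the pair difference $\Delta w = w_p - w_q$ and mean
$\bar w = (w_p + w_q)/2$, and treating $\bar w$ as a constant across the
pair, squaring both sides gives a scalar quadratic in $\Delta w$:

$$a\,\Delta w^2 + b\,\Delta w + c = 0,\qquad
  a = \|\hat D \bar u\|_2^2,\quad
  b = 2\bar w\,(\hat D \bar u)\cdot(\hat D \Delta u),\quad
  c = \bar w^2\|\hat D \Delta u\|_2^2 - \|\Delta u\|_2^2 .$$

`solvePairQuadratic()` solves it for every pair. Between the two roots, the
sign of the *guiding difference* — the difference of the channel-sum image at
p and q — selects one: a positive guide (p brighter) takes the larger root,
a negative guide the smaller. This consistently pushes the already-brighter
side of an invisible edge brighter, rather than letting adjacent pairs pull
in contradictory directions.

The per-pair targets $\Delta w_{p,q}$ generally disagree (the field is not
curl-free), so the mask is recovered by gradient-domain least squares with a
perceptually motivated normalization:

$$w^* = \arg\min_w \sum_{p,q}
  \frac{\bigl((w_p - w_q) - \Delta w_{p,q}\bigr)^2}{\Delta w_{p,q}^2 + \epsilon^2}.$$

Dividing each residual by the target magnitude implements a Weber-like
weighting: an absolute error matters more across a flat region than across a
strong intended edge, which suppresses halo artifacts that a plain
least-squares integration produces.

Finally the weighted image can exceed the display range, so `toneMap()`
divides by the 0.98 quantile of per-pixel channel maxima (never by less than
1) and clips. The divisor is global and shared by all channels, so it, too,
preserves chromaticity; the only pixels whose chromaticity can change at all
are the roughly 2 % that clip.

## Parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `epsilon` | 0.01 | mask units | Regularizes the reconstruction denominators; small relative to the O(0.1–1) weight steps the quadratic produces. Shared by the diagnostic functional (`evaluateFunctional()`) and the reconstruction. |
| `wbar` | 1 | mask units | Assumed pair-mean mask value in the quadratic; 1 is the no-modification baseline around which the linearization is taken. |
| `iters` | 10000 | iterations | Adam iteration count; convergence is effectively complete on 128×128 images (see below). |
| `step` | 0.01 | mask units / iteration | Adam base step, decayed linearly to zero over the run. |
| `tonemapQuantile` | 0.98 | quantile | Fraction of pixels guaranteed unclipped by the display mapping. |
| `pairDistance` | 1 | pixels | Neighbor offset. Distances > 1 are exposed as an experimental knob; they enlarge the contrast neighborhood but can produce ridge artifacts. |

The RMS metric's sampling scheme (`rmsSamplingSpec()`) uses a 10-pixel
anchor grid, 1000 neighbors per anchor drawn from an isotropic normal with
σ = 0.25·min(H, W) (out-of-bounds draws rejected and redrawn, anchor
excluded, duplicates allowed), and a fixed 160 normalizer that keeps values
in [0, 1] for 8-bit material. "Linear size" is read as min(H, W) so the
neighborhood is isotropic on non-square images.

## Numerical choices

* **Degenerate quadratics.** If the discriminant is negative the original
  contrast is unreachable by any weight step; we return the vertex
  −b/(2a), the least-squares minimizer of the residual, instead of failing.
  If a = 0 (both pixels black — the only in-gamut case) the step is 0. A
  guiding tie (equal channel sums) takes the root of smaller magnitude:
  minimal modification.
* **Optimizer.** Adam from the deterministic initializer w ≡ 1, no
  minibatching, so runs are bit-reproducible without seeds. Two refinements
  matter in practice. First, the step decays linearly to zero: constant-step
  Adam orbits the minimum without settling (on 1-D consistent chains its
  recovery error plateaus near 1e-3; with decay it reaches machine
  precision, and the 2-D objective on a 128×128 fixture ends ~50× lower).
  Second, the objective is evaluated every 100 iterations and the best
  iterate seen (the incumbent) is the one returned — Adam itself is not
  monotone, the incumbent is, so the logged trace is non-increasing by
  construction and the returned mask is never worse than the flat mask.
* **Gauge fixing.** The objective only sees differences of w, so the
  optimum is defined up to an additive constant. We anchor mean(w) = 1
  (preserves overall brightness and leaves range handling to the tone map),
  then floor at 0.01 to keep the image non-negative.
* **Finite differences.** The structure-tensor Jacobian uses central
  differences in the interior and one-sided differences at borders; its 2×2
  eigenproblem is solved in closed form, picking the numerically stabler of
  the two equivalent eigenvector expressions. These operations are
  diagnostics: the daltonization path itself uses exact pairwise
  differences, which need no stencil choice.
* **proLab constants.** The projective transform is compiled in from the
  proLab publication (Konovalenko et al., IEEE Access 9, 2021), acting on
  white-normalized XYZ with the sRGB D65 white taken from the row sums of
  the sRGB RGB→XYZ matrix itself, which makes the gray axis map to zero
  chroma exactly. Black (L⁺ = 0) is assigned chromaticity (0, 0) by
  convention, avoiding a 0/0 in the CD metric.
* **Clipping discipline.** Simulated linear values may leave [0, 1] slightly
  (the matrices have small negative entries); they are clipped only at
  encode time so the optimizer always sees the exact linear model.

## What the synthetic generator emulates — and what it does not

`makeConfusionImage()` produces the canonical hard case: two colors at
`base ± (amplitude/2)·n` along the confusion kernel `n`, arranged as a
checkerboard, two regions, or a ramp. By construction the simulated image is
*uniform* — contrast loss is total, which real photographs rarely exhibit.
`makeControlImage()` produces grayscale, blue–yellow and noise controls that
simulation must leave (near-)unchanged. Passing tests on these fixtures
demonstrates the machinery: exact chromaticity preservation, correct root
selection, genuine contrast restoration under simulation, and fixed-point
behavior on unaffected content. They do not demonstrate perceptual quality
on natural images — natural scenes mix confusable and unconfusable contrast,
have texture at many scales, and their restored lightness edges compete with
existing luminance structure. Quantitative table-level evaluation on the
10-photograph benchmark requires that external dataset (see
`?datasetDirectory`); the unit and acceptance fixtures here are 32–128 px
squares chosen so the full 10,000-iteration pipeline and the metric suite
run in seconds on one CPU.

## Design decisions that were genuinely open

* The guiding "integral image" is read as the per-pixel channel-sum scalar
  image, not a summed-area table — a summed-area table has no meaningful
  per-pair sign, while the channel sum is exactly the quantity whose
  gradient orients pseudo-gradients in the contrast-preserving literature.
* ε is shared between the diagnostic functional and the reconstruction
  objective (both are exposed; nothing in the method requires them equal,
  but one regularization scale keeps the two objectives comparable).
* The tone map only scales *down* (divisor ≥ 1). An autocontrast that also
  stretched dark images would modify images that need no correction;
  scale-down-only makes daltonization the exact identity on in-range
  achromatic content — grayscale inputs round-trip to the byte.
* Mean-1 anchoring of the mask (rather than leaving the gauge to the tone
  map) keeps average brightness stable and makes masks comparable across
  configurations.

## Known limitations

* Contrast is assessed only between distance-`pairDistance` neighbors;
  structures separated by more than a few pixels of gradual transition can
  remain under-restored (the ramp fixture shows this mildly). Larger
  neighborhoods are exposed but experimental.
* The restored contrast is achromatic by design; an edge that is invisible
  to the dichromat *and* sits between equal-lightness regions for the
  trichromat gains a lightness difference visible to both. That is the
  intended trade.
* Tone-mapped (clipped) pixels — the top ~2 % — are the one place
  chromaticity can drift; `attr(out, "clipFraction")` reports the exposure.
* CIELAB values feeding the RMS metric assume the sRGB D65 viewing
  conditions; no chromatic adaptation or ICC handling is attempted.

## Reproducibility

`daltonize()` is deterministic given its configuration; only the RMS
metric samples, and it takes an explicit seed (`rmsSamplingSpec(seed = )`)
and restores the caller's RNG state. `scripts/acceptance.R --seed S --out F`
recomputes every headline number of the README from scratch under seed `S`.
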