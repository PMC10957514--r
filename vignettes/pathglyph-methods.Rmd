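---
title: "Methods: distribution-aware overlays on metabolic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distribution-aware overlays on metabolic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathglyph)
```

## The problem and the model of the figure

A metabolic map is a laid-out graph: metabolite nodes, reaction edges drawn
as chains of straight or cubic-Bezier segments, in map units with y
increasing downward (the screen convention used by Escher). pathglyph takes
such a map plus a *data specification* — values bound to reaction and
metabolite identifiers under named experimental conditions — and composes a
static SVG in a fixed z-order: canvas, edges (with arrowheads on product
ends), nodes, labels, box points, distribution glyphs, legend.

The data specification is produced by a small grammar of graphics. A
**layer** binds one column of a tidy table to a **geom** through an
**aesthetic**:

| geom         | entity                  | aesthetics   | side        | values per (id, condition) |
|--------------|-------------------------|--------------|-------------|----------------------------|
| `arrow`      | reaction edge           | color, size  | —           | 1 (mean-aggregated)        |
| `metabolite` | node                    | color, size  | —           | 1 (mean-aggregated)        |
| `box`        | stacked square          | color        | left/right/hover | 1 (mean-aggregated)   |
| `hist`       | histogram on an axis    | y            | left/right/hover | all values kept       |
| `kde`        | density curve on an axis| y            | left/right/hover | all values kept       |

Point-valued geoms aggregate repeated measurements by the arithmetic mean —
a deterministic, permutation-free default; callers wanting medians or log
transforms pre-transform their table. Distribution geoms refuse series with
fewer than two values. Rows with no condition are assigned `"default"`, and
the condition order of the figure is the order of first appearance in the
table: that order is what the box stacks display top to bottom.

Identifier matching against the map is exact on BiGG ids — reaction
`bigg_id` for edge-associated geoms, metabolite node `bigg_id` for node
geoms. Unmatched data identifiers warn and are skipped; a metabolite id
that occurs at several node positions (currency metabolites) styles every
instance.

## Statistical glyphs

**Shared limits.** Every distribution glyph of a layer (one geom + side)
uses one x-domain: the global minimum and maximum over all matched series
of that layer across all reactions and all *selected* conditions. This is
deliberately per-layer rather than global — different layers show different
variables with incomparable units. A degenerate domain (all values equal)
expands by 0.5 on each side.

**Histograms.** Bins partition the shared `[lo, hi]` into equal half-open
intervals `[e_i, e_{i+1})`, the last bin closed so the maximum is counted.
The default bin count is Freedman–Diaconis on the series values
(`width = 2·IQR·n^{-1/3}`), clamped to [5, 50] so extreme IQRs still give a
readable glyph, with a `⌈√n⌉` fallback when the IQR collapses to zero.
Values outside the shared domain are excluded and reported, never silently
dropped.

**Kernel densities.** A Gaussian KDE
`f(x) = (n·h)^{-1} Σ_i φ((x − x_i)/h)` with Silverman's rule
`h = 0.9·min(s, IQR/1.34)·n^{-1/5}` (falling back to the standard deviation
when the IQR is zero) evaluated on 128 equally spaced points. The grid
spans the union of the shared domain and `data ± 3h`, which keeps the
trapezoidal integral of the curve within [0.99, 1.001] regardless of where
the shared limits fall; the tests verify this and the exact agreement of
the vectorized evaluation with a naive double-loop sum. Zero-variance
series are rejected (the renderer falls back to a histogram for them).

## Scales

Continuous color scales interpolate componentwise in sRGB between ordered
stops, with channels rounded half-up; size scales interpolate linearly.
Both clamp to the domain and support absolute-value semantics (`|v|`), the
conventional display for signed fluxes where magnitude matters and the
arrowhead already shows direction. Scale domains default to the layer's
shared limits, so edge and node encodings are cross-reaction comparable in
the same way the distribution axes are. sRGB interpolation was chosen over
a perceptual space for determinism and portability; the default palettes
(blue→red for signed data, white→green for box points) are plain arguments
and fully overridable.

## Placement

Each reaction's segments are walked from the substrate side (metabolite
nodes with negative stoichiometric coefficient) to the product side;
curved segments contribute a fixed 10-point polyline (endpoints plus 8
interior Bezier evaluations) — deterministic and resolution-independent.
The axis anchor is the **midpoint of the longest straight chord** of that
polyline: simple, deterministic, and usually the stretch of edge with the
most free space. Placement heuristics cannot be perfect on complex
reactions, so every placement can be overridden by an overlay file of saved
transforms (`{reaction_id, side, origin, rotation, scale}`), the static
replacement for dragging axes interactively.

The axis is rotated to the local chord tangent and flipped into
`(-π/2, π/2]` so its text is never upside-down. "Left" is the direction
rotated by −90° in y-down coordinates — above a left-to-right edge — and
the axis sits at a perpendicular clearance of 1.2 glyph heights; left and
right placements are exact mirror images across the edge. The third
position, `hover`, renders as a static axis at the reaction label (there is
no pointer in an SVG file), preserving three distributional variables per
reaction.

Box points stack vertically centered on their side anchor with a pitch of
1.25 box sizes (a 0.25-box gap). Slot positions are computed over the
*full* condition list, not the selection, so narrowing the selection
removes squares without moving the survivors — which also makes the
legend/selection invariant testable element-by-element. The clearance and
pitch constants are exposed in `render_settings()`; they are layout
choices, not statistics.

## Condition selection and the legend

Either all conditions or exactly one may be selected. Distribution glyphs
of all selected conditions share one axis, distinguished by condition hue;
each curve or bar group is normalized to the glyph height independently, so
a condition's glyph is unaffected by which other conditions are shown (the
shared x-domain, recomputed over the selection, is what carries the
cross-reaction comparison). Edge and node aesthetics can only display one
value at a time; under "all" they show the first condition — multi-condition
point data belongs in box points, which is exactly what they are for. The
legend holds one entry per mapped layer × selected condition present in
that layer, with the layer's shared limits printed to 3 significant digits
on distribution entries.

## Determinism and serialization

Rendering the same inputs twice yields byte-identical SVG: elements are
emitted in sorted reaction/node id order, coordinates are formatted with a
fixed 4-decimal trimmed format, and all randomness lives in the fixture
generator behind explicit seeds. Escher maps are written with header keys
in their original order, body keys sorted, and unknown keys preserved
verbatim, so a round-tripped map remains usable in other Escher consumers;
serialization is idempotent after one parse/write cycle. Only the
two-element `[header, body]` Escher dialect (schema 1-0-4, the form of
publicly circulated maps) is supported.

## The synthetic case-study generator

`toy_map()` builds chains (optionally branched, curved, or with duplicated
metabolite nodes) on a 150-unit grid; `synthetic_case_study()` emulates a
combined proteomics / metabolomics / flux-sampling study: per reaction and
condition, 200 normal flux draws by default (location 2, scale 1, with a
+0.5 shift per successive condition, standing in for posterior or
flux-sampling draws); lognormal enzyme levels (meanlog 0, sdlog 0.5) for
box color; lognormal metabolite concentrations (meanlog 0, sdlog 0.8) for
node color and size. Three conditions get the gas-mixture names `CO`,
`H2-High CO`, `Syngas`. These defaults are plausible magnitudes for
log-scale omics data, chosen once; the generator makes no attempt to
reproduce any published organism's numbers. What passing tests on this
synthetic data shows is that the *pipeline* — parsing, statistics, layout,
rendering, selection — behaves correctly; it says nothing about the
biological plausibility of real inputs, which carry multimodality,
missingness patterns and inter-variable correlations the generator does not
emulate.

Test problem sizes (up to 8 reactions, 60–5000 draws, 200 random histogram
inputs) were chosen as the smallest sizes at which each property is
non-trivially exercised.

## Numerical notes and limitations

- The parameter-recovery check (KDE mode of 5000 normal(2, 1) draws within
  0.15 of 2) is asserted on the mean mode over five replicate series: the
  argmax of a KDE is itself a noisy statistic — its asymptotic standard
  deviation at the Silverman bandwidth is ≈ 0.13 here — so a single series
  would fail by chance roughly a quarter of the time while five replicates
  bound the failure probability below 1%.
- Ties in `which.max` (flat density maxima) resolve to the lowest grid
  index; bin edges use `findInterval`, so values exactly on an inner edge
  go to the right bin.
- No collision avoidance between glyphs of *different* reactions; dense
  maps may need overlay adjustments.
- Discrete/categorical scales, log axes, violin plots and 2-D densities are
  out of scope; callers pre-transform.
- Interchange compatibility is defined by this package's `pathglyph-1`
  schema; byte-compatibility with other tools' `metabolism.json` files is
  not guaranteed.
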