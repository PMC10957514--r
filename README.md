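# pathglyph

Static, publication-ready overlays of multi-condition, multi-omics data on
**Escher-format metabolic maps**, rendered to SVG from R.

Metabolic maps are laid-out graphs in which nodes are metabolites and edges
are the reactions connecting them. Color and size of an edge or node can
carry one continuous value per reaction or metabolite — but much modern data
is *distributional* (posterior draws from Bayesian kinetic models, flux
samples from constraint-based models) and *multi-condition* (differential
omics). pathglyph addresses both:

- **Distributions on the map.** Histograms and Gaussian kernel-density
  curves are anchored beside reaction edges, on the left side, the right
  side, or at the reaction label, so each edge can carry up to three
  distributional variables.
- **Shared axis limits.** All distribution glyphs of one layer share a
  single x-domain — the global minimum and maximum over every reaction and
  selected condition — so the same variable is directly comparable across
  the map. The shared limits are printed in the legend.
- **Conditions side by side.** Box points (small colored squares beside an
  edge) stack vertically, one per condition in first-appearance order, and
  distribution glyphs of all selected conditions are drawn on one shared
  axis with per-condition colors. One condition, or all, can be selected.
- **Automatic legend.** Entries appear only for layers that actually have
  matched data, crossed with the selected conditions.

Statistics used by the glyphs: histogram bin count defaults to the
Freedman–Diaconis rule `h = 2·IQR·n^(-1/3)` clamped to [5, 50] bins; the
kernel density estimate is `f(x) = (n·h)^(-1) Σᵢ φ((x − xᵢ)/h)` with
Silverman's bandwidth `h = 0.9·min(s, IQR/1.34)·n^(-1/5)`. Continuous color
and size scales interpolate linearly (componentwise in sRGB), with optional
absolute-value semantics for signed fluxes.

A grammar-of-graphics front end binds a tidy table of measurements to
*geoms* (`arrow`, `metabolite`, `box`, `hist`, `kde`) through *aesthetics*
(`color`, `size`, `y`) and serializes the `pathglyph-1` JSON interchange
format (files ending `metabolism.json`; schema in
`inst/extdata/interchange.schema.json`).

## Worked example

```r
library(pathglyph)

# a toy 5-reaction chain with one branch, plus a synthetic 3-condition
# case study: flux draws (kde, left), enzyme levels (box color, right),
# metabolite concentrations (node color and size)
map <- toy_map(5, branch = TRUE)
cs  <- synthetic_case_study(map, synthetic_scenario(n_conditions = 3,
                                                    n_draws = 200, seed = 42))
spec <- build_dataspec(cs$table, cs$layers)
spec$conditions
#> [1] "CO"         "H2-High CO" "Syngas"

print(match_to_map(spec, map))
#> pathglyph match report: 13 matched, 0 unmatched data ids, 0 data-less map entities

svg <- render_svg(map, spec)
writeLines(svg, "overlay.svg", sep = "")
```

The resulting figure draws the six reaction edges, metabolite nodes colored
and sized by concentration, a stack of three enzyme box points per reaction
(CO on top, then H2-High CO, then Syngas), one kernel-density axis per
reaction with three per-condition curves on identical x-limits, and a
12-entry legend (4 mapped layers × 3 conditions). Restricting the view to
one condition:

```r
svg_co <- render_svg(map, spec, render_settings(selected_conditions = "CO"))
```

removes exactly the other two conditions' curves, boxes and legend entries.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/pathglyph fixtures --out demo
Rscript inst/cli/pathglyph validate --data demo/toy.metabolism.json --map demo/toy_map.json
Rscript inst/cli/pathglyph render --map demo/toy_map.json \
    --data demo/toy.metabolism.json --out demo/overlay.svg --conditions all
```

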