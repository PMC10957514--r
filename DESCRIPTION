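Package: pathglyph
Title: Static Multi-Omics Overlays on Escher Metabolic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Renders multi-condition, multi-omics data onto Escher-format
    metabolic maps as publication-ready SVG. Continuous values map to the
    color and size of reaction edges and metabolite nodes, to stacked box
    points (one colored square per experimental condition), and full value
    distributions are drawn as histograms or Gaussian kernel density curves
    anchored to reaction edges, with axis limits shared across all reactions
    of a layer so distributions are directly comparable. A grammar-of-graphics
    front end binds tidy tables of measurements to geoms and aesthetics and
    serializes a JSON interchange format; a fixture generator produces toy
    maps and synthetic multi-condition datasets; a command-line interface
    ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
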