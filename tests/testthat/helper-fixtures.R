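# Shared fixture builders and independent oracles.

# A minimal map with one reaction M1 -> M2 drawn as a single segment
# (optionally a cubic Bezier). Coefficients can be flipped to swap
# substrate/product roles.
single_segment_map <- function(p0 = c(0, 0), p3 = c(100, 0),
                               b1 = NULL, b2 = NULL, flip = FALSE) {
  seg <- list(from_node_id = "n1", to_node_id = "n2",
              b1 = if (is.null(b1)) NULL else list(x = b1[1], y = b1[2]),
              b2 = if (is.null(b2)) NULL else list(x = b2[1], y = b2[2]))
  coef <- if (flip) c(1, -1) else c(-1, 1)
  body <- list(
    canvas = list(x = -50, y = -100, width = 300, height = 300),
    nodes = list(
      n1 = list(node_type = "metabolite", x = p0[1], y = p0[2],
                bigg_id = "M1", name = "M1", label_x = p0[1], label_y = p0[2] - 20,
                node_is_primary = TRUE),
      n2 = list(node_type = "metabolite", x = p3[1], y = p3[2],
                bigg_id = "M2", name = "M2", label_x = p3[1], label_y = p3[2] - 20,
                node_is_primary = TRUE)),
    reactions = list(
      r1 = list(bigg_id = "R1", name = "R1",
                label_x = (p0[1] + p3[1]) / 2, label_y = (p0[2] + p3[2]) / 2 + 40,
                reversibility = FALSE,
                segments = list(s1 = seg),
                metabolites = list(list(bigg_id = "M1", coefficient = coef[1]),
                                   list(bigg_id = "M2", coefficient = coef[2])))),
    text_labels = structure(list(), names = character(0)))
  header <- list(map_name = "single segment fixture", map_id = "fix-1",
                 schema = "https://escher.github.io/escher/jsonschema/1-0-4#")
  structure(list(header = header, body = body), class = "escher_map")
}

# Independent scalar cubic Bezier, written against the closed form rather
# than the package's matrix version.
bezier_oracle <- function(p0, p1, p2, p3, t) {
  sapply(t, function(tt) {
    u <- 1 - tt
    c(u^3 * p0[1] + 3 * u^2 * tt * p1[1] + 3 * u * tt^2 * p2[1] + tt^3 * p3[1],
      u^3 * p0[2] + 3 * u^2 * tt * p1[2] + 3 * u * tt^2 * p2[2] + tt^3 * p3[2])
  })
}

# Naive O(n*m) Gaussian KDE double loop (the independent oracle).
kde_oracle <- function(values, grid, h) {
  n <- length(values)
  out <- numeric(length(grid))
  for (j in seq_along(grid)) {
    acc <- 0
    for (i in seq_len(n)) {
      z <- (grid[j] - values[i]) / h
      acc <- acc + exp(-z^2 / 2) / sqrt(2 * pi)
    }
    out[j] <- acc / (n * h)
  }
  out
}

trapz_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# Tidy two-condition table for grammar tests.
two_condition_table <- function() {
  data.frame(
    identifier = c("R1", "R1", "R1", "R1", "M1"),
    condition = c("condA", "condA", "condB", "condB", "condA"),
    value = c(1, 3, 2, 6, NA),
    met = c(NA, NA, NA, NA, 10),
    stringsAsFactors = FALSE)
}

svg_attr_all <- function(svg, xpath, attr) {
  doc <- xml2::read_xml(svg)
  xml2::xml_attr(xml2::xml_find_all(doc, xpath), attr)
}
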