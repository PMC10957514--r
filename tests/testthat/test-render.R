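test_that("a bare map renders every segment and metabolite with no legend", {
  m <- toy_map(2)
  svg <- render_svg(m)
  doc <- xml2::read_xml(svg)
  n_paths <- length(xml2::xml_find_all(doc, "//*[local-name()='path']"))
  n_segs <- sum(sapply(m$body$reactions, function(r) length(r$segments)))
  expect_equal(n_paths, n_segs)
  n_circ <- length(xml2::xml_find_all(doc, "//*[@class='metabolite']"))
  n_mets <- sum(sapply(m$body$nodes, function(n) n$node_type == "metabolite"))
  expect_equal(n_circ, n_mets)
  expect_length(xml2::xml_find_all(doc, "//*[@class='legend-swatch']"), 0)
})

test_that("mapped aesthetics stay scoped to their reaction", {
  m <- toy_map(3)
  tab <- data.frame(identifier = "R1", condition = "A", value = 2)
  spec <- build_dataspec(tab, layer_spec("arrow", "color"))
  svg <- render_svg(m, spec)
  doc <- xml2::read_xml(svg)
  for (rid in c("R1", "R2", "R3")) {
    strokes <- xml2::xml_attr(xml2::xml_find_all(
      doc, sprintf("//*[@data-reaction='%s']//*[local-name()='path']", rid)),
      "stroke")
    if (rid == "R1") expect_true(all(strokes != "#B0B0B0"))
    else expect_true(all(strokes == "#B0B0B0"))
  }
})

test_that("all-condition selection groups per-condition glyphs on one shared axis", {
  m <- toy_map(4)
  set.seed(13)
  tab <- do.call(rbind, lapply(c("A", "B"), function(cd)
    do.call(rbind, lapply(paste0("R", 1:4), function(r)
      data.frame(identifier = r, condition = cd,
                 value = rnorm(40, mean = if (cd == "A") 0 else 2))))))
  spec <- build_dataspec(tab, layer_spec("hist", "y", side = "left"))
  svg <- render_svg(m, spec)
  doc <- xml2::read_xml(svg)
  axes <- xml2::xml_find_all(doc, "//*[@class='glyph-axis']")
  expect_length(axes, 4)
  for (ax in axes) {
    conds <- xml2::xml_attr(
      xml2::xml_find_all(ax, ".//*[@class='glyph']"), "data-condition")
    expect_equal(sort(conds), c("A", "B"))
  }
  los <- unique(xml2::xml_attr(axes, "data-domain-lo"))
  his <- unique(xml2::xml_attr(axes, "data-domain-hi"))
  expect_length(los, 1)
  expect_length(his, 1)
})

test_that("legend entries are the product of mapped layers and selected conditions", {
  m <- toy_map(2)
  set.seed(4)
  tab <- do.call(rbind, lapply(c("A", "B"), function(cd) rbind(
    data.frame(identifier = "R1", condition = cd, value = rnorm(20),
               enz = NA),
    data.frame(identifier = "R1", condition = cd, value = NA,
               enz = runif(1)))))
  layers <- list(layer_spec("hist", "y", side = "left"),
                 layer_spec("box", "color", side = "right", column = "enz"))
  spec <- build_dataspec(tab, layers)

  leg_all <- build_legend(spec, render_settings(), list(c(-2, 5), c(0, 1)))
  expect_length(leg_all$entries, 4)  # 2 layers x 2 conditions
  leg_one <- build_legend(spec, render_settings(selected_conditions = "B"),
                          list(c(-2, 5), c(0, 1)))
  expect_length(leg_one$entries, 2)
  expect_true(all(sapply(leg_one$entries, function(e) e$condition) == "B"))

  # distribution entries carry the layer's shared limits at 3 significant digits
  hist_entries <- Filter(function(e) e$geom == "hist", leg_all$entries)
  expect_true(all(sapply(hist_entries, function(e) e$domain_text) == "[-2, 5]"))

  empty <- build_dataspec(data.frame(identifier = "R1", condition = "A",
                                     value = 1)[0, ], list())
  expect_length(build_legend(empty, render_settings(), list())$entries, 0)

  # layers whose identifiers miss the map get no legend entry
  leg_matched <- build_legend(spec, render_settings(), list(c(-2, 5), c(0, 1)),
                              matched_ids = character(0))
  expect_length(leg_matched$entries, 0)
})

test_that("unknown selected conditions raise a config error listing options", {
  m <- toy_map(1)
  tab <- data.frame(identifier = "R1", condition = c("A", "B"), value = 1:2)
  spec <- build_dataspec(tab, layer_spec("arrow", "size"))
  err <- tryCatch(render_svg(m, spec, render_settings(selected_conditions = "Zzz")),
                  pg_config_error = function(e) e)
  expect_s3_class(err, "pg_config_error")
  expect_match(conditionMessage(err), "A, B")
})

test_that("deselecting a condition removes exactly its glyphs and legend entries", {
  m <- toy_map(3)
  set.seed(8)
  tab <- do.call(rbind, lapply(c("A", "B"), function(cd)
    do.call(rbind, lapply(paste0("R", 1:3), function(r) rbind(
      data.frame(identifier = r, condition = cd, value = rnorm(30),
                 enz = NA),
      data.frame(identifier = r, condition = cd, value = NA,
                 enz = runif(1)))))))
  layers <- list(layer_spec("kde", "y", side = "left"),
                 layer_spec("box", "color", side = "right", column = "enz"))
  spec <- build_dataspec(tab, layers)

  count <- function(svg, xpath) length(xml2::xml_find_all(xml2::read_xml(svg), xpath))
  svg_all <- render_svg(m, spec)
  svg_a <- render_svg(m, spec, render_settings(selected_conditions = "A"))

  expect_equal(count(svg_all, "//*[@class='glyph'][@data-condition='B']"), 3)
  expect_equal(count(svg_a, "//*[@class='glyph'][@data-condition='B']"), 0)
  expect_equal(count(svg_a, "//*[@class='glyph'][@data-condition='A']"),
               count(svg_all, "//*[@class='glyph'][@data-condition='A']"))
  expect_equal(count(svg_a, "//*[@class='boxpoint'][@data-condition='B']"), 0)
  expect_equal(count(svg_a, "//*[@class='boxpoint'][@data-condition='A']"),
               count(svg_all, "//*[@class='boxpoint'][@data-condition='A']"))
  # box slots are computed over the full condition list, so the remaining
  # squares do not move when the selection narrows
  ya <- sort(as.numeric(svg_attr_all(
    svg_a, "//*[@class='boxpoint'][@data-condition='A']", "y")))
  yall <- sort(as.numeric(svg_attr_all(
    svg_all, "//*[@class='boxpoint'][@data-condition='A']", "y")))
  expect_equal(ya, yall)
  expect_equal(count(svg_a, "//*[@class='legend-swatch']"),
               count(svg_all, "//*[@class='legend-swatch']") / 2)
})

test_that("overlay transforms carry through rendering", {
  m <- toy_map(2)
  set.seed(2)
  tab <- data.frame(identifier = rep(c("R1", "R2"), each = 25),
                    condition = "A", value = rnorm(50))
  spec <- build_dataspec(tab, layer_spec("kde", "y", side = "left"))
  ov <- list(structure(list(origin = c(500, 500), rotation = 0.3, scale = 1,
                            side = "left", reaction_id = "R1"),
                       class = "axis_transform"))
  svg <- render_svg(m, spec, render_settings(), overlay = ov)
  doc <- xml2::read_xml(svg)
  tr <- xml2::xml_attr(xml2::xml_find_all(
    doc, "//*[@class='glyph-axis'][@data-reaction='R1']"), "transform")
  expect_match(tr, "rotate\\(17\\.1887")  # 0.3 rad in degrees
})

test_that("rendering is deterministic and well-formed", {
  m <- toy_map(3, branch = TRUE, curved = TRUE)
  cs <- synthetic_case_study(m, synthetic_scenario(seed = 5, n_draws = 50))
  spec <- build_dataspec(cs$table, cs$layers)
  svg1 <- render_svg(m, spec)
  svg2 <- render_svg(m, spec)
  expect_identical(svg1, svg2)
  expect_silent(xml2::read_xml(svg1))
})
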