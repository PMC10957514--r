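test_that("layer_spec enforces the geom/aesthetic/side compatibility rules", {
  expect_s3_class(layer_spec("arrow", "color"), "layer_spec")
  expect_s3_class(layer_spec("hist", "y", side = "left"), "layer_spec")
  expect_s3_class(layer_spec("box", "color", side = "hover"), "layer_spec")

  expect_error(layer_spec("violin", "y", side = "left"), class = "pg_schema_error")
  expect_error(layer_spec("hist", "color", side = "left"), class = "pg_schema_error")
  expect_error(layer_spec("box", "size", side = "left"), class = "pg_schema_error")
  expect_error(layer_spec("arrow", "y"), class = "pg_schema_error")
  expect_error(layer_spec("arrow", "color", side = "left"), class = "pg_schema_error")
  expect_error(layer_spec("kde", "y"), class = "pg_schema_error")
})

test_that("point geoms aggregate by mean while distribution geoms keep all values", {
  tab <- data.frame(identifier = c("R1", "R1"), condition = c("condA", "condA"),
                    value = c(1, 3))
  point <- build_dataspec(tab, layer_spec("arrow", "color"))
  expect_length(point$series, 1)
  expect_equal(point$series[[1]]$values, 2.0)

  dist <- build_dataspec(tab, layer_spec("hist", "y", side = "left"))
  expect_equal(dist$series[[1]]$values, c(1, 3))

  single <- data.frame(identifier = "R1", condition = "condA", value = 5)
  expect_error(build_dataspec(single, layer_spec("kde", "y", side = "left")),
               regexp = "R1", class = "pg_insufficient_data")
  expect_error(build_dataspec(tab, list(layer_spec("arrow", "color",
                                                   column = "missing"))),
               class = "pg_schema_error")
})

test_that("conditions keep first-appearance order and missing conditions default", {
  tab <- data.frame(
    identifier = rep("R1", 6),
    condition = rep(c("CO", "H2-High CO", "Syngas"), each = 2),
    value = 1:6)
  spec <- build_dataspec(tab, layer_spec("kde", "y", side = "left"))
  expect_equal(spec$conditions, c("CO", "H2-High CO", "Syngas"))

  no_cond <- data.frame(identifier = "R1", value = 7)
  spec2 <- build_dataspec(no_cond, layer_spec("box", "color", side = "left"))
  expect_equal(spec2$conditions, "default")
  expect_equal(spec2$series[[1]]$condition, "default")
})

test_that("row permutation never changes series value sets", {
  tab <- two_condition_table()
  spec <- build_dataspec(tab, list(layer_spec("hist", "y", side = "left"),
                                   layer_spec("arrow", "size")))
  set.seed(99)
  for (i in 1:10) {
    perm <- tab[sample(nrow(tab)), , drop = FALSE]
    spec_p <- build_dataspec(perm, list(layer_spec("hist", "y", side = "left"),
                                        layer_spec("arrow", "size")))
    key <- function(s) paste(s$layer, s$identifier, s$condition)
    for (s in spec$series) {
      match_s <- Filter(function(q) key(q) == key(s), spec_p$series)
      expect_length(match_s, 1)
      expect_equal(sort(match_s[[1]]$values), sort(s$values))
    }
  }
})

test_that("interchange files round-trip and enforce naming and schema", {
  tab <- two_condition_table()
  spec <- build_dataspec(tab, list(layer_spec("hist", "y", side = "left"),
                                   layer_spec("metabolite", "color",
                                              column = "met")))
  path <- file.path(withr::local_tempdir(), "toy.metabolism.json")
  write_interchange(spec, path)
  back <- read_interchange(path)
  expect_equal(back$conditions, spec$conditions)
  expect_equal(length(back$series), length(spec$series))
  for (i in seq_along(spec$series)) {
    expect_equal(back$series[[i]]$values, as.numeric(spec$series[[i]]$values))
    expect_equal(back$series[[i]]$identifier, spec$series[[i]]$identifier)
  }
  # write(read(x)) is stable
  path2 <- file.path(withr::local_tempdir(), "again.metabolism.json")
  write_interchange(back, path2)
  expect_identical(readLines(path), readLines(path2))

  expect_error(write_interchange(spec, "data.json"), class = "pg_naming_error")
  expect_silent(write_interchange(spec, file.path(withr::local_tempdir(),
                                                  "other.json"), force = TRUE))
})

test_that("schema violations are reported with JSON pointer paths", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "bad.metabolism.json")
  writeLines(paste0(
    '{"version":"pathglyph-1","conditions":["A"],',
    '"layers":[{"geom":"violin","aesthetic":"y","side":"left","column":"v"}],',
    '"series":[]}'), bad)
  err <- tryCatch(read_interchange(bad), pg_validation_error = function(e) e)
  expect_s3_class(err, "pg_validation_error")
  expect_match(conditionMessage(err), "/layers/0/geom")

  empty <- file.path(tmp, "empty.metabolism.json")
  writeLines('{"version":"pathglyph-1","conditions":[],"layers":[{"geom":"hist","aesthetic":"y","side":"left","column":"v"}],"series":[]}',
             empty)
  spec <- read_interchange(empty)
  expect_length(spec$series, 0)

  short <- file.path(tmp, "short.metabolism.json")
  writeLines(paste0(
    '{"version":"pathglyph-1","conditions":["A"],',
    '"layers":[{"geom":"kde","aesthetic":"y","side":"left","column":"v"}],',
    '"series":[{"layer":1,"identifier":"R1","condition":"A","values":[1]}]}'),
    short)
  err2 <- tryCatch(read_interchange(short), pg_validation_error = function(e) e)
  expect_match(conditionMessage(err2), "/series/0/values")
})

test_that("match_to_map partitions identifiers by exact bigg_id", {
  map <- toy_map(2)  # reactions R1, R2; metabolites M1..M3
  tab <- data.frame(identifier = c("R1", "R1", "R9", "R9"),
                    condition = "A", value = c(1, 2, 3, 4))
  spec <- build_dataspec(tab, layer_spec("hist", "y", side = "left"))
  rep <- match_to_map(spec, map)
  expect_equal(rep$matched, "R1")
  expect_equal(rep$unmatched_data, "R9")
  expect_true(all(c("R2", "M1", "M2", "M3") %in% rep$dataless_map))
})

test_that("duplicated metabolite nodes both match one data series", {
  map <- toy_map(2, duplicate_met = TRUE)
  dup_nodes <- Filter(function(n) identical(n$node_type, "metabolite") &&
                        identical(n$bigg_id, "M1"), map$body$nodes)
  expect_length(dup_nodes, 2)  # fixture scan: M1 occurs at two positions

  tab <- data.frame(identifier = "M1", condition = "A", value = 4)
  spec <- build_dataspec(tab, layer_spec("metabolite", "color"))
  expect_equal(match_to_map(spec, map)$matched, "M1")
  svg <- suppressWarnings(render_svg(map, spec))
  fills <- svg_attr_all(svg, "//*[@class='metabolite'][@data-bigg='M1']", "fill")
  expect_length(fills, 2)
  expect_equal(length(unique(fills)), 1)  # both instances share the mapped color
})
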