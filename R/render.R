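# Static SVG composition: map geometry, scale-mapped aesthetics, box points,
# distribution glyphs on their axis transforms, and the automatic legend.

#' Rendering settings
#'
#' @param selected_conditions `"all"` or the name of a single condition.
#' @param figure_width Output width in pixels; height follows the canvas
#'   aspect ratio.
#' @param background Canvas fill color.
#' @param font_family,font_size Label font.
#' @param arrow_width Default edge stroke width (map units).
#' @param node_radius Default metabolite node radius (map units).
#' @param axis_length Distribution-axis length (map units).
#' @param glyph_height Distribution-glyph height (map units); also sets the
#'   perpendicular clearance of the axis from the edge.
#' @param box_size Box-point side length (map units).
#' @param clearance Axis clearance in glyph heights (default 1.2).
#' @param condition_palette Colors cycled over conditions for distribution
#'   glyphs and condition legend swatches.
#' @param absolute Named logical vector: use absolute-value scales for geoms
#'   `arrow`, `metabolite`, `box`.
#' @return A `render_settings` list.
#' @export
render_settings <- function(selected_conditions = "all",
                            figure_width = 900,
                            background = "#FFFFFF",
                            font_family = "Helvetica, Arial, sans-serif",
                            font_size = 12,
                            arrow_width = 4,
                            node_radius = 12,
                            axis_length = 70,
                            glyph_height = 30,
                            box_size = 10,
                            clearance = 1.2,
                            condition_palette = c("#1B9E77", "#D95F02",
                                                  "#7570B3", "#E7298A",
                                                  "#66A61E", "#E6AB02"),
                            absolute = c(arrow = FALSE, metabolite = FALSE,
                                         box = FALSE)) {
  stopifnot(figure_width > 0, arrow_width > 0, node_radius > 0,
            axis_length > 0, glyph_height > 0, box_size > 0, clearance > 0,
            font_size > 0)
  structure(list(selected_conditions = selected_conditions,
                 figure_width = figure_width, background = background,
                 font_family = font_family, font_size = font_size,
                 arrow_width = arrow_width, node_radius = node_radius,
                 axis_length = axis_length, glyph_height = glyph_height,
                 box_size = box_size, clearance = clearance,
                 condition_palette = condition_palette, absolute = absolute),
            class = "render_settings")
}

fmt_num <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  s[s == "-0"] <- "0"
  s
}

escape_xml <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

svg_el <- function(tag, attrs = list(), children = character(0), text = NULL) {
  a <- ""
  if (length(attrs)) {
    vals <- vapply(attrs, function(v) {
      if (is.numeric(v)) fmt_num(v) else escape_xml(as.character(v))
    }, character(1))
    a <- paste0(" ", paste0(names(attrs), "=\"", vals, "\"", collapse = " "))
  }
  if (is.null(text) && length(children) == 0) {
    paste0("<", tag, a, "/>")
  } else if (!is.null(text)) {
    paste0("<", tag, a, ">", escape_xml(text), "</", tag, ">")
  } else {
    paste0("<", tag, a, ">", paste0(children, collapse = ""), "</", tag, ">")
  }
}

condition_color <- function(settings, spec, condition) {
  idx <- match(condition, spec$conditions)
  pal <- settings$condition_palette
  pal[((idx - 1) %% length(pal)) + 1]
}

# which conditions are displayed
selected_conditions_of <- function(spec, settings) {
  sel <- settings$selected_conditions
  if (identical(sel, "all")) return(spec$conditions)
  if (!sel %in% spec$conditions) {
    stop(pg_error("pg_config_error",
                  sprintf("condition '%s' not present in data; available: %s",
                          sel, paste(spec$conditions, collapse = ", "))))
  }
  sel
}

# point-geom value lookup: series of layer li for identifier id, per condition
point_values <- function(spec, li, id) {
  out <- numeric(0)
  for (s in spec$series) {
    if (s$layer == li && s$identifier == id) out[s$condition] <- s$values[1]
  }
  out
}

# shared limits of a layer, restricted to matched ids and selected conditions
layer_shared_limits <- function(spec, li, matched_ids, selected) {
  vals <- lapply(spec$series, function(s) {
    if (s$layer == li && s$identifier %in% matched_ids &&
        s$condition %in% selected) s$values else NULL
  })
  vals <- Filter(Negate(is.null), vals)
  if (length(vals) == 0) return(NULL)
  shared_limits(vals)
}

#' Automatically generated legend
#'
#' One entry per layer that has at least one matched series, crossed with the
#' selected conditions that actually occur in that layer — entities without
#' data or outside the selection get no entry. Distribution entries carry
#' their layer's shared x-limits formatted to 3 significant digits.
#'
#' @param spec A `dataspec`.
#' @param settings A [render_settings()].
#' @param layer_domains List indexed by layer of `c(lo, hi)` shared limits
#'   (entries may be `NULL` for layers without matched data).
#' @param matched_ids Identifiers that matched the map; `NULL` means all
#'   series count as matched.
#' @return A `legend` object: list of entries `{geom, aesthetic, side,
#'   condition, color, domain, domain_text}`.
#' @export
build_legend <- function(spec, settings, layer_domains, matched_ids = NULL) {
  selected <- selected_conditions_of(spec, settings)
  entries <- list()
  for (li in seq_along(spec$layers)) {
    ly <- spec$layers[[li]]
    ser <- Filter(function(s) s$layer == li &&
                    (is.null(matched_ids) || s$identifier %in% matched_ids),
                  spec$series)
    if (length(ser) == 0) next
    layer_conds <- unique(vapply(ser, function(s) s$condition, character(1)))
    dom <- if (li <= length(layer_domains)) layer_domains[[li]] else NULL
    dom_text <- if (!is.null(dom))
      sprintf("[%s, %s]", format(signif(dom[1], 3)), format(signif(dom[2], 3)))
    else ""
    for (cd in selected[selected %in% layer_conds]) {
      entries[[length(entries) + 1]] <- list(
        geom = ly$geom, aesthetic = ly$aesthetic, side = ly$side,
        condition = cd, color = condition_color(settings, spec, cd),
        domain = dom, domain_text = dom_text)
    }
  }
  structure(list(entries = entries), class = "legend")
}

# -- internal drawing helpers -------------------------------------------------

draw_segment_path <- function(map, seg, stroke, width) {
  p0 <- node_xy(map, seg$from_node_id)
  p3 <- node_xy(map, seg$to_node_id)
  d <- if (!is.null(seg$b1)) {
    sprintf("M %s %s C %s %s, %s %s, %s %s",
            fmt_num(p0[1]), fmt_num(p0[2]),
            fmt_num(seg$b1$x), fmt_num(seg$b1$y),
            fmt_num(seg$b2$x), fmt_num(seg$b2$y),
            fmt_num(p3[1]), fmt_num(p3[2]))
  } else {
    sprintf("M %s %s L %s %s",
            fmt_num(p0[1]), fmt_num(p0[2]), fmt_num(p3[1]), fmt_num(p3[2]))
  }
  svg_el("path", list(d = d, fill = "none", stroke = stroke,
                      `stroke-width` = width, `stroke-linecap` = "round"))
}

# arrowheads on segments whose endpoint is a primary product metabolite node
draw_arrowheads <- function(map, rxn, stroke, width) {
  prods <- vapply(Filter(function(m) (m$coefficient %||% 0) > 0,
                         rxn$metabolites),
                  function(m) m$bigg_id, character(1))
  if (length(prods) == 0) return(character(0))
  out <- character(0)
  for (sid in sort(names(rxn$segments))) {
    seg <- rxn$segments[[sid]]
    for (endp in c("to_node_id", "from_node_id")) {
      nd <- map$body$nodes[[seg[[endp]]]]
      if (!identical(nd$node_type, "metabolite")) next
      if (!(nd$bigg_id %in% prods)) next
      if (!isTRUE(nd$node_is_primary %||% TRUE)) next
      tip <- c(nd$x, nd$y)
      other <- if (endp == "to_node_id") {
        if (!is.null(seg$b2)) c(seg$b2$x, seg$b2$y) else node_xy(map, seg$from_node_id)
      } else {
        if (!is.null(seg$b1)) c(seg$b1$x, seg$b1$y) else node_xy(map, seg$to_node_id)
      }
      v <- tip - other
      len <- sqrt(sum(v^2))
      if (len < 1e-9) next
      v <- v / len
      n <- left_normal(v)
      sz <- max(3 * width, 9)
      b1 <- tip - sz * v + 0.5 * sz * n
      b2 <- tip - sz * v - 0.5 * sz * n
      out <- c(out, svg_el("polygon", list(
        class = "arrowhead",
        points = paste(fmt_num(c(tip[1], b1[1], b2[1])),
                       fmt_num(c(tip[2], b1[2], b2[2])),
                       sep = ",", collapse = " "),
        fill = stroke)))
    }
  }
  out
}

group_transform <- function(tr) {
  deg <- tr$rotation * 180 / pi
  t <- sprintf("translate(%s %s)", fmt_num(tr$origin[1]), fmt_num(tr$origin[2]))
  if (abs(deg) > 1e-12) t <- paste0(t, sprintf(" rotate(%s)", fmt_num(deg)))
  if (abs((tr$scale %||% 1) - 1) > 1e-12)
    t <- paste0(t, sprintf(" scale(%s)", fmt_num(tr$scale)))
  t
}

# histogram bars / density polyline in axis-local coordinates:
# x 0..axis_length maps domain lo..hi, y 0 baseline, negative y up.
draw_distribution <- function(s, domain, settings, color) {
  L <- settings$axis_length
  H <- settings$glyph_height
  to_x <- function(v) (v - domain[1]) / diff(domain) * L
  if (s$geom == "hist") {
    g <- histogram(s$values, domain)
    hmax <- max(g$counts, 1)
    bars <- character(0)
    for (i in seq_along(g$counts)) {
      if (g$counts[i] == 0) next
      x0 <- to_x(g$bin_edges[i]); x1 <- to_x(g$bin_edges[i + 1])
      hh <- g$counts[i] / hmax * H
      bars <- c(bars, svg_el("rect", list(
        x = x0, y = -hh, width = x1 - x0, height = hh,
        fill = color, `fill-opacity` = 0.6, stroke = color,
        `stroke-width` = 0.5)))
    }
    bars
  } else {
    g <- tryCatch(kde(s$values, domain),
                  pg_degenerate_distribution = function(e) NULL)
    if (is.null(g)) {  # zero-variance fallback: histogram
      return(draw_distribution(utils::modifyList(s, list(geom = "hist")),
                               domain, settings, color))
    }
    keep <- g$grid >= domain[1] & g$grid <= domain[2]
    gx <- g$grid[keep]; gy <- g$density[keep]
    hmax <- max(gy, .Machine$double.eps)
    pts <- paste(fmt_num(to_x(gx)), fmt_num(-gy / hmax * H),
                 sep = ",", collapse = " ")
    svg_el("polyline", list(points = pts, fill = "none", stroke = color,
                            `stroke-width` = 1.5))
  }
}

draw_axis_line <- function(domain, settings) {
  L <- settings$axis_length
  fs <- settings$font_size * 0.7
  c(svg_el("line", list(x1 = 0, y1 = 0, x2 = L, y2 = 0,
                        stroke = "#333333", `stroke-width` = 1)),
    svg_el("text", list(x = 0, y = fs + 2, `font-size` = fs,
                        `text-anchor` = "middle", fill = "#333333"),
           text = format(signif(domain[1], 3))),
    svg_el("text", list(x = L, y = fs + 2, `font-size` = fs,
                        `text-anchor` = "middle", fill = "#333333"),
           text = format(signif(domain[2], 3))))
}

#' Render a map with its data overlay to SVG
#'
#' Draws, in z-order: canvas, reaction segments (cubic Beziers with
#' arrowheads on product ends), metabolite nodes, labels, box points,
#' distribution glyphs on their axis transforms, then the legend. Edge stroke
#' width/color and node radius/fill come from scales when the corresponding
#' layer is mapped, otherwise from defaults. When all conditions are
#' selected, distribution glyphs of every condition are drawn on the same
#' axis with per-condition colors and box points stack vertically, one square
#' per condition. Rendering is deterministic: element order follows sorted
#' reaction and node ids, so identical inputs give byte-identical SVG.
#'
#' @param map An `escher_map`.
#' @param spec A `dataspec`, or `NULL` to render the bare map.
#' @param settings A [render_settings()].
#' @param overlay Optional list of `axis_transform` (see [read_overlay()])
#'   overriding heuristic axis placement.
#' @return The SVG document as a character string.
#' @export
render_svg <- function(map, spec = NULL, settings = render_settings(),
                       overlay = NULL) {
  stopifnot(inherits(map, "escher_map"))
  cv <- map$body$canvas
  if (is.null(spec)) {
    spec <- structure(list(version = "pathglyph-1", conditions = character(0),
                           layers = list(), series = list()),
                      class = "dataspec")
  }
  selected <- if (length(spec$conditions)) selected_conditions_of(spec, settings)
              else character(0)

  report <- match_to_map(spec, map)
  if (length(report$unmatched_data)) {
    warning(sprintf("%d data identifiers not present in the map: %s",
                    length(report$unmatched_data),
                    paste(report$unmatched_data, collapse = ", ")),
            call. = FALSE)
  }
  matched <- report$matched

  # shared per-layer domains over matched ids and selected conditions
  layer_domains <- lapply(seq_along(spec$layers), function(li)
    layer_shared_limits(spec, li, matched, selected))

  # scales for point geoms, domain = the layer's shared limits
  point_scale <- function(li) {
    ly <- spec$layers[[li]]
    dom <- layer_domains[[li]]
    if (is.null(dom)) return(NULL)
    absf <- isTRUE(unname(settings$absolute[ly$geom]))
    if (absf) dom <- range(abs(dom), 0)
    if (ly$aesthetic == "size") {
      rng <- if (ly$geom == "arrow") c(1, 3 * settings$arrow_width)
             else c(0.5 * settings$node_radius, 1.8 * settings$node_radius)
      linear_scale(dom, rng, absolute = absf)
    } else {
      color_scale(dom, default_palette(ly$geom), absolute = absf)
    }
  }
  scales <- lapply(seq_along(spec$layers), point_scale)

  # display condition for single-valued aesthetics (edges/nodes show one
  # condition at a time; under "all" the first condition is shown)
  disp_cond <- if (length(selected)) selected[1] else NULL

  layer_of <- function(geom, aesthetic = NULL) {
    which(vapply(spec$layers, function(ly) ly$geom == geom &&
                   (is.null(aesthetic) || ly$aesthetic == aesthetic),
                 logical(1)))
  }
  lookup_point <- function(lis, id) {
    for (li in lis) {
      pv <- point_values(spec, li, id)
      if (!is.null(disp_cond) && disp_cond %in% names(pv)) {
        return(list(li = li, v = pv[[disp_cond]]))
      }
    }
    NULL
  }

  rxn_bigg <- map_reaction_bigg_ids(map)
  nodes <- map$body$nodes
  body_parts <- character(0)

  # canvas
  body_parts <- c(body_parts, svg_el("rect", list(
    class = "canvas", x = cv$x, y = cv$y, width = cv$width,
    height = cv$height, fill = settings$background)))

  # reactions
  rxn_parts <- character(0)
  arrow_color_layers <- layer_of("arrow", "color")
  arrow_size_layers <- layer_of("arrow", "size")
  for (rid in sort(names(map$body$reactions))) {
    rxn <- map$body$reactions[[rid]]
    bigg <- rxn_bigg[[rid]]
    stroke <- "#B0B0B0"
    width <- settings$arrow_width
    if (bigg %in% matched) {
      hit <- lookup_point(arrow_color_layers, bigg)
      if (!is.null(hit) && !is.null(scales[[hit$li]]))
        stroke <- map_color(scales[[hit$li]], hit$v)
      hit <- lookup_point(arrow_size_layers, bigg)
      if (!is.null(hit) && !is.null(scales[[hit$li]]))
        width <- map_size(scales[[hit$li]], hit$v)
    }
    segs <- vapply(sort(names(rxn$segments)), function(sid)
      draw_segment_path(map, rxn$segments[[sid]], stroke, width), character(1))
    heads <- draw_arrowheads(map, rxn, stroke, width)
    lbl <- if (!is.null(rxn$label_x)) {
      svg_el("text", list(class = "reaction-label", x = rxn$label_x,
                          y = rxn$label_y, `font-size` = settings$font_size,
                          fill = "#404040"),
             text = bigg)
    } else character(0)
    rxn_parts <- c(rxn_parts, svg_el("g", list(
      class = "reaction", `data-reaction` = bigg), c(segs, heads, lbl)))
  }
  body_parts <- c(body_parts, svg_el("g", list(class = "reactions"), rxn_parts))

  # metabolite nodes
  node_parts <- character(0)
  met_color_layers <- layer_of("metabolite", "color")
  met_size_layers <- layer_of("metabolite", "size")
  for (nid in sort(names(nodes))) {
    nd <- nodes[[nid]]
    if (!identical(nd$node_type, "metabolite")) next
    fill <- "#A8C4E0"
    radius <- settings$node_radius
    if (!is.null(nd$bigg_id) && nd$bigg_id %in% matched) {
      hit <- lookup_point(met_color_layers, nd$bigg_id)
      if (!is.null(hit) && !is.null(scales[[hit$li]]))
        fill <- map_color(scales[[hit$li]], hit$v)
      hit <- lookup_point(met_size_layers, nd$bigg_id)
      if (!is.null(hit) && !is.null(scales[[hit$li]]))
        radius <- map_size(scales[[hit$li]], hit$v)
    }
    node_parts <- c(node_parts, svg_el("circle", list(
      class = "metabolite", `data-node` = nid, `data-bigg` = nd$bigg_id,
      cx = nd$x, cy = nd$y, r = radius, fill = fill,
      stroke = "#606060", `stroke-width` = 1)))
    if (!is.null(nd$label_x)) {
      node_parts <- c(node_parts, svg_el("text", list(
        class = "metabolite-label", x = nd$label_x, y = nd$label_y,
        `font-size` = settings$font_size, fill = "#202020"),
        text = nd$bigg_id))
    }
  }
  body_parts <- c(body_parts, svg_el("g", list(class = "nodes"), node_parts))

  # geometry per reaction bigg id (first occurrence wins for duplicates)
  geom_cache <- list()
  rxn_geom <- function(bigg) {
    if (!is.null(geom_cache[[bigg]])) return(geom_cache[[bigg]])
    rid <- names(rxn_bigg)[rxn_bigg == bigg][1]
    ax <- reaction_axis(map, rid)
    d <- ax$polyline[-1, , drop = FALSE] -
      ax$polyline[-nrow(ax$polyline), , drop = FALSE]
    k <- which.max(sqrt(rowSums(d^2)))
    anchor <- (ax$polyline[k, ] + ax$polyline[k + 1, ]) / 2
    lbl <- map$body$reactions[[rid]]
    g <- list(axis = ax, anchor = anchor,
              label = c(lbl$label_x %||% anchor[1], lbl$label_y %||% anchor[2]))
    geom_cache[[bigg]] <<- g
    g
  }

  # box points: slot positions computed over the full condition list so that
  # narrowing the selection removes squares without moving the others
  box_parts <- character(0)
  for (li in layer_of("box")) {
    ly <- spec$layers[[li]]
    if (is.null(scales[[li]])) next
    ids <- sort(unique(vapply(Filter(function(s) s$layer == li, spec$series),
                              function(s) s$identifier, character(1))))
    for (id in ids[ids %in% matched]) {
      g <- rxn_geom(id)
      n_side <- left_normal(g$axis$direction)
      if (identical(ly$side, "right")) n_side <- -n_side
      stack_anchor <- if (identical(ly$side, "hover")) g$label
        else g$anchor + 1.25 * settings$box_size * n_side
      placements <- stack_box_points(
        id, ly$side, spec$conditions, point_values(spec, li, id),
        scales[[li]], settings$box_size, anchor = stack_anchor)
      for (p in placements) {
        if (!p$condition %in% selected) next
        box_parts <- c(box_parts, svg_el("rect", list(
          class = "boxpoint", `data-reaction` = id, `data-side` = p$side,
          `data-condition` = p$condition,
          x = p$center[1] - p$half_side, y = p$center[2] - p$half_side,
          width = 2 * p$half_side, height = 2 * p$half_side,
          fill = p$color, stroke = "#303030", `stroke-width` = 0.75)))
      }
    }
  }
  body_parts <- c(body_parts, svg_el("g", list(class = "boxpoints"), box_parts))

  # distribution glyphs
  dist_parts <- character(0)
  dist_layers <- sort(c(layer_of("hist"), layer_of("kde")))
  computed <- list()
  specs_by_axis <- list()
  for (li in dist_layers) {
    ly <- spec$layers[[li]]
    dom <- layer_domains[[li]]
    if (is.null(dom)) next
    ids <- sort(unique(vapply(Filter(function(s) s$layer == li, spec$series),
                              function(s) s$identifier, character(1))))
    for (id in ids[ids %in% matched]) {
      g <- rxn_geom(id)
      tr <- place_axis(g$axis$polyline, g$axis$direction, ly$side,
                       settings$axis_length,
                       glyph_height = settings$glyph_height,
                       clearance = settings$clearance,
                       label_pos = g$label, reaction_id = id)
      key <- paste(li, id, sep = "\r")
      computed[[key]] <- tr
      specs_by_axis[[key]] <- list(li = li, id = id, dom = dom, side = ly$side)
    }
  }
  if (!is.null(overlay) && length(computed)) {
    computed <- stats::setNames(
      apply_overlay(overlay, unname(computed)), names(computed))
  }
  for (key in names(computed)) {
    info <- specs_by_axis[[key]]
    ly <- spec$layers[[info$li]]
    tr <- computed[[key]]
    # center the axis on its origin
    tr$origin <- tr$origin - rot2(c(settings$axis_length / 2, 0), tr$rotation) *
      (tr$scale %||% 1)
    glyphs <- character(0)
    for (cd in spec$conditions[spec$conditions %in% selected]) {
      ser <- Filter(function(s) s$layer == info$li && s$identifier == info$id &&
                      s$condition == cd, spec$series)
      if (length(ser) == 0) next
      glyphs <- c(glyphs, svg_el("g", list(
        class = "glyph", `data-condition` = cd),
        draw_distribution(ser[[1]], info$dom, settings,
                          condition_color(settings, spec, cd))))
    }
    if (length(glyphs) == 0) next
    dist_parts <- c(dist_parts, svg_el("g", list(
      class = "glyph-axis", `data-reaction` = info$id,
      `data-geom` = ly$geom, `data-side` = info$side,
      `data-domain-lo` = fmt_num(info$dom[1]),
      `data-domain-hi` = fmt_num(info$dom[2]),
      transform = group_transform(tr)),
      c(glyphs, draw_axis_line(info$dom, settings))))
  }
  body_parts <- c(body_parts, svg_el("g", list(class = "distributions"),
                                     dist_parts))

  # legend
  legend <- build_legend(spec, settings, layer_domains, matched)
  leg_parts <- character(0)
  lx <- cv$x + 14; ly0 <- cv$y + 20; lh <- 20
  for (i in seq_along(legend$entries)) {
    e <- legend$entries[[i]]
    y <- ly0 + (i - 1) * lh
    label <- paste0(e$geom, " ", e$aesthetic,
                    if (!is.null(e$side)) paste0(" (", e$side, ")") else "",
                    " · ", e$condition,
                    if (nzchar(e$domain_text)) paste0(" · ", e$domain_text)
                    else "")
    leg_parts <- c(leg_parts,
      svg_el("rect", list(class = "legend-swatch",
                          `data-geom` = e$geom, `data-condition` = e$condition,
                          x = lx, y = y - 10, width = 12, height = 12,
                          fill = e$color, stroke = "#303030",
                          `stroke-width` = 0.5)),
      svg_el("text", list(class = "legend-text", x = lx + 18, y = y,
                          `font-size` = settings$font_size, fill = "#202020"),
             text = label))
  }
  body_parts <- c(body_parts, svg_el("g", list(class = "legend"), leg_parts))

  w <- settings$figure_width
  h <- w * cv$height / cv$width
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         svg_el("svg", list(
           xmlns = "http://www.w3.org/2000/svg", version = "1.1",
           width = fmt_num(w), height = fmt_num(h),
           viewBox = paste(fmt_num(c(cv$x, cv$y, cv$width, cv$height)),
                           collapse = " "),
           `font-family` = settings$font_family),
           body_parts),
         "\n")
}

# rotate a 2-vector by theta in y-down screen coordinates
rot2 <- function(p, theta) {
  c(cos(theta) * p[1] - sin(theta) * p[2],
    sin(theta) * p[1] + cos(theta) * p[2])
}
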