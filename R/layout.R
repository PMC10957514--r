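# Glyph placement along reaction edges: axis anchoring, box-point stacking,
# and saved-transform overlays.

# left normal of a unit direction in y-down screen coordinates:
# rotate by -90 degrees -> (y, -x). For a horizontal edge pointing +x this
# points up (smaller y), i.e. the "left" of a reader following the arrow.
left_normal <- function(direction) c(direction[2], -direction[1])

#' Place a glyph axis beside a reaction edge
#'
#' The axis anchor is the midpoint of the longest straight chord of the
#' reaction polyline (the stretch of edge with the most room). The axis is
#' rotated to the local edge tangent, flipped into `(-pi/2, pi/2]` so axis
#' text is never upside-down, and offset perpendicular to the edge by
#' `clearance * glyph_height` toward the requested side. `side = "hover"`
#' places a third, unrotated axis at the reaction label instead.
#'
#' @param polyline n x 2 matrix from [reaction_axis()].
#' @param direction Unit direction of the reaction (substrate to product).
#' @param side `"left"`, `"right"` or `"hover"`.
#' @param axis_length Axis length in map units (stored on the transform).
#' @param glyph_height Glyph height in map units used for the clearance.
#' @param clearance Perpendicular clearance in glyph heights (default 1.2).
#' @param label_pos Optional `c(x, y)` reaction label position for hover.
#' @param reaction_id Optional id recorded on the transform.
#' @return An `axis_transform`: `origin`, `rotation` (radians), `scale`,
#'   `side`, `reaction_id`, `axis_length`.
#' @export
place_axis <- function(polyline, direction, side, axis_length,
                       glyph_height = 30, clearance = 1.2,
                       label_pos = NULL, reaction_id = NULL) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 2)
  stopifnot(side %in% c("left", "right", "hover"))
  d <- polyline[-1, , drop = FALSE] - polyline[-nrow(polyline), , drop = FALSE]
  chord_len <- sqrt(rowSums(d^2))
  if (nrow(polyline) < 2 || max(chord_len) < 1e-12) {
    stop(pg_error("pg_degenerate_geometry", "degenerate polyline: no usable chord"))
  }
  k <- which.max(chord_len)
  anchor <- (polyline[k, ] + polyline[k + 1, ]) / 2
  tangent <- d[k, ] / chord_len[k]

  if (identical(side, "hover")) {
    origin <- if (!is.null(label_pos)) as.numeric(label_pos) else anchor
    return(structure(list(origin = origin, rotation = 0, scale = 1,
                          side = side, reaction_id = reaction_id,
                          axis_length = axis_length),
                     class = "axis_transform"))
  }

  rotation <- atan2(tangent[2], tangent[1])
  # flip into (-pi/2, pi/2] so text reads left to right
  if (rotation > pi / 2) rotation <- rotation - pi
  if (rotation <= -pi / 2) rotation <- rotation + pi

  n_left <- left_normal(direction)
  normal <- if (identical(side, "left")) n_left else -n_left
  origin <- anchor + clearance * glyph_height * normal
  structure(list(origin = origin, rotation = rotation, scale = 1,
                 side = side, reaction_id = reaction_id,
                 axis_length = axis_length),
            class = "axis_transform")
}

#' Stack box points for all conditions beside an edge
#'
#' One colored square per condition, stacked vertically in condition order
#' (first condition on top), centers separated by `1.25 * box_size` so boxes
#' never touch. The stack is centered on `anchor`; callers offset the anchor
#' toward the requested side of the edge (see [render_svg()]). A condition
#' with a missing value gets the scale's missing-value color and a warning.
#'
#' @param reaction_id Reaction the stack belongs to.
#' @param side `"left"` or `"right"`.
#' @param conditions Ordered character vector of condition names.
#' @param values Named numeric vector (names = conditions); one value per
#'   condition after aggregation.
#' @param color_scale A [color_scale()].
#' @param box_size Square side length in map units.
#' @param anchor `c(x, y)` stack center.
#' @return List of `box_placement`s: `reaction_id`, `side`, `condition`,
#'   `center`, `half_side`, `color`.
#' @export
stack_box_points <- function(reaction_id, side, conditions, values,
                             color_scale, box_size, anchor = c(0, 0)) {
  stopifnot(side %in% c("left", "right", "hover"))
  k <- length(conditions)
  stopifnot(k >= 1, box_size > 0)
  pitch <- 1.25 * box_size
  base <- anchor
  ys <- base[2] + (seq_len(k) - (k + 1) / 2) * pitch
  out <- vector("list", k)
  for (i in seq_len(k)) {
    cd <- conditions[i]
    v <- if (cd %in% names(values)) values[[cd]] else NA_real_
    if (!is.finite(v)) {
      warning(sprintf("box point %s/%s: no value for condition '%s'",
                      reaction_id, side, cd), call. = FALSE)
    }
    out[[i]] <- structure(list(
      reaction_id = reaction_id, side = side, condition = cd,
      center = c(base[1], ys[i]), half_side = box_size / 2,
      color = map_color(color_scale, v)),
      class = "box_placement")
  }
  out
}

#' Apply saved axis transforms over computed ones
#'
#' The overlay file is the static replacement for interactively moving,
#' rotating and scaling an axis and saving the result: any `(reaction_id,
#' side)` present in the overlay replaces the heuristic placement; all other
#' placements pass through unchanged. Overlay entries for reactions absent
#' from the computed set are ignored with a warning.
#'
#' @param transforms Overlay transforms (list of `axis_transform`).
#' @param computed Heuristic transforms (list of `axis_transform`).
#' @return List of `axis_transform`, same order/keys as `computed`.
#' @export
apply_overlay <- function(transforms, computed) {
  key <- function(t) paste(t$reaction_id, t$side, sep = "\r")
  comp_keys <- vapply(computed, key, character(1))
  for (ov in transforms) {
    hit <- which(comp_keys == key(ov))
    if (length(hit) == 0) {
      warning(sprintf("overlay transform for (%s, %s) matches no computed axis; ignored",
                      ov$reaction_id %||% "?", ov$side %||% "?"), call. = FALSE)
      next
    }
    for (h in hit) {
      keep_len <- computed[[h]]$axis_length
      computed[[h]]$origin <- as.numeric(ov$origin)
      computed[[h]]$rotation <- ov$rotation %||% computed[[h]]$rotation
      computed[[h]]$scale <- ov$scale %||% computed[[h]]$scale
      if (is.null(computed[[h]]$axis_length)) computed[[h]]$axis_length <- keep_len
    }
  }
  computed
}

#' Read an axis-transform overlay file
#'
#' A JSON list of `{reaction_id, side, origin: [x, y], rotation, scale}`.
#'
#' @param path Path to the overlay JSON.
#' @return List of `axis_transform`.
#' @export
read_overlay <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop(pg_error("pg_parse_error",
                    paste0("malformed overlay JSON: ", conditionMessage(e)))))
  lapply(doc, function(e) {
    structure(list(origin = as.numeric(unlist(e$origin)),
                   rotation = e$rotation %||% 0,
                   scale = e$scale %||% 1,
                   side = e$side, reaction_id = e$reaction_id),
              class = "axis_transform")
  })
}
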