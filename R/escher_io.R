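#' Parse an Escher-format metabolic map
#'
#' Reads the two-element JSON array used by Escher (schema 1-0-4): a metadata
#' header object followed by the map body holding `nodes`, `reactions`,
#' `text_labels` and `canvas`. All keys that pathglyph does not interpret are
#' preserved verbatim so that a written map stays usable in other Escher
#' consumers.
#'
#' @param text A length-one character string containing the JSON document, or
#'   a path to a file holding one.
#' @return An object of class `escher_map`: a list with elements `header`
#'   (named list), `body` (named list with at least `nodes`, `reactions`,
#'   `canvas`).
#' @details The map uses screen coordinates: y increases downward. Reaction
#'   segments are straight lines or cubic Beziers (`b1`/`b2` control points,
#'   both present or both absent).
#' @export
parse_escher_map <- function(text) {
  if (length(text) == 1 && !grepl("[\\[{]", substr(text, 1, 1)) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      stop(pg_error("pg_parse_error", paste0("malformed JSON: ", conditionMessage(e))))
    }
  )
  if (!is.list(doc) || length(doc) != 2 || !is.null(names(doc))) {
    stop(pg_error("pg_parse_error",
                  "Escher map must be a two-element JSON array [header, body]"))
  }
  m <- structure(list(header = doc[[1]], body = doc[[2]]), class = "escher_map")
  validate_escher_map(m)
  m
}

# Integrity checks shared by parse and write.
validate_escher_map <- function(m) {
  body <- m$body
  if (is.null(body$canvas)) {
    stop(pg_error("pg_integrity_error", "map body has no canvas"))
  }
  cv <- body$canvas
  if (!is.numeric(cv$width %||% NA) || !is.numeric(cv$height %||% NA) ||
      cv$width <= 0 || cv$height <= 0) {
    stop(pg_error("pg_integrity_error", "canvas width and height must be positive"))
  }
  node_ids <- names(body$nodes)
  if (anyDuplicated(node_ids)) {
    stop(pg_error("pg_integrity_error", "duplicate node ids"))
  }
  if (anyDuplicated(names(body$reactions))) {
    stop(pg_error("pg_integrity_error", "duplicate reaction ids"))
  }
  for (rid in names(body$reactions)) {
    rxn <- body$reactions[[rid]]
    if (length(rxn$segments) < 1) {
      stop(pg_error("pg_integrity_error",
                    sprintf("reaction '%s' has no segments", rid)))
    }
    for (sid in names(rxn$segments)) {
      seg <- rxn$segments[[sid]]
      for (endp in c(seg$from_node_id, seg$to_node_id)) {
        if (!endp %in% node_ids) {
          stop(pg_error("pg_integrity_error",
                        sprintf("segment '%s' of reaction '%s' references unknown node '%s'",
                                sid, rid, endp)))
        }
      }
      if (is.null(seg$b1) != is.null(seg$b2)) {
        stop(pg_error("pg_integrity_error",
                      sprintf("segment '%s' of reaction '%s' has only one Bezier control point",
                              sid, rid)))
      }
    }
    for (met in rxn$metabolites) {
      if (!is.null(met$coefficient) && met$coefficient == 0) {
        stop(pg_error("pg_integrity_error",
                      sprintf("reaction '%s' has a zero stoichiometric coefficient", rid)))
      }
    }
  }
  for (nid in node_ids) {
    nd <- body$nodes[[nid]]
    is_met <- identical(nd$node_type, "metabolite")
    if (is_met && is.null(nd$bigg_id)) {
      stop(pg_error("pg_integrity_error",
                    sprintf("metabolite node '%s' lacks a bigg_id", nid)))
    }
  }
  invisible(m)
}

#' Serialize an Escher map back to JSON
#'
#' Inverse of [parse_escher_map()]: header keys keep their original order, map
#' body keys are sorted, numbers use shortest full-precision form, unknown
#' keys survive verbatim. Serialization is deterministic, so writing the same
#' map twice yields byte-identical documents.
#'
#' @param map An `escher_map`.
#' @param path Optional file path; when given the JSON is also written there.
#' @return The JSON document as a character string (invisibly when `path` is
#'   given).
#' @export
write_escher_map <- function(map, path = NULL) {
  stopifnot(inherits(map, "escher_map"))
  validate_escher_map(map)
  body <- map$body
  body <- body[order(names(body))]
  json <- jsonlite::toJSON(list(map$header, body),
                           auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = FALSE)
  json <- as.character(json)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Reaction ids present in a map
#' @param map An `escher_map`.
#' @return Character vector of reaction ids (internal Escher ids).
#' @export
map_reaction_ids <- function(map) names(map$body$reactions)

#' Look up reactions / metabolite nodes by BiGG id
#'
#' @param map An `escher_map`.
#' @return `map_reaction_bigg_ids`: named character vector mapping internal
#'   reaction id to its `bigg_id`. `map_metabolite_bigg_ids`: named character
#'   vector mapping node id to metabolite `bigg_id` (metabolite nodes only;
#'   a bigg_id may occur at several node positions).
#' @export
map_reaction_bigg_ids <- function(map) {
  vapply(map$body$reactions, function(r) r$bigg_id %||% "", character(1))
}

#' @rdname map_reaction_bigg_ids
#' @export
map_metabolite_bigg_ids <- function(map) {
  nodes <- map$body$nodes
  keep <- vapply(nodes, function(n) identical(n$node_type, "metabolite"), logical(1))
  vapply(nodes[keep], function(n) n$bigg_id, character(1))
}

# Evaluate a cubic Bezier at parameter t (vectorized over t).
bezier_point <- function(p0, p1, p2, p3, t) {
  u <- 1 - t
  cbind(
    u^3 * p0[1] + 3 * u^2 * t * p1[1] + 3 * u * t^2 * p2[1] + t^3 * p3[1],
    u^3 * p0[2] + 3 * u^2 * t * p1[2] + 3 * u * t^2 * p2[2] + t^3 * p3[2]
  )
}

node_xy <- function(map, nid) {
  nd <- map$body$nodes[[nid]]
  c(nd$x, nd$y)
}

#' Ordered polyline and direction of a reaction's edge
#'
#' Walks the reaction's segments from the substrate side (metabolite nodes
#' with negative stoichiometric coefficient) to the product side and returns
#' the traversed polyline. Straight segments contribute their endpoints;
#' curved segments are sampled as a fixed 10-point polyline (endpoints plus 8
#' interior cubic-Bezier evaluations), which is deterministic and resolution
#' independent for placement purposes.
#'
#' @param map An `escher_map`.
#' @param reaction_id Internal reaction id (a name of `map$body$reactions`).
#' @return List with `polyline` (n x 2 matrix of map coordinates, y down) and
#'   `direction` (unit vector from first to last polyline point).
#' @export
reaction_axis <- function(map, reaction_id) {
  rxn <- map$body$reactions[[reaction_id]]
  if (is.null(rxn)) {
    stop(pg_error("pg_lookup_error",
                  sprintf("unknown reaction id '%s'", reaction_id)))
  }
  segs <- rxn$segments
  sids <- sort(names(segs))

  # adjacency over node ids
  ends <- lapply(segs[sids], function(s) c(s$from_node_id, s$to_node_id))
  all_nodes <- unique(unlist(ends))
  deg <- table(factor(unlist(ends), levels = all_nodes))
  endpoints <- names(deg)[deg == 1]
  if (length(endpoints) == 0) endpoints <- all_nodes  # cyclic fallback

  # prefer starting at a substrate metabolite node
  coefs <- stats::setNames(
    vapply(rxn$metabolites, function(m) as.numeric(m$coefficient), numeric(1)),
    vapply(rxn$metabolites, function(m) m$bigg_id, character(1))
  )
  node_bigg <- vapply(endpoints, function(nid) {
    map$body$nodes[[nid]]$bigg_id %||% ""
  }, character(1))
  is_sub <- !is.na(coefs[node_bigg]) & coefs[node_bigg] < 0
  is_sub[is.na(is_sub)] <- FALSE
  start <- if (any(is_sub)) endpoints[which(is_sub)[1]] else endpoints[1]

  # greedy walk over unvisited segments, deterministic by sorted segment id
  visited <- character(0)
  pts <- matrix(node_xy(map, start), ncol = 2)
  cur <- start
  repeat {
    nxt_sid <- NULL
    for (sid in sids) {
      if (sid %in% visited) next
      e <- ends[[sid]]
      if (cur %in% e) { nxt_sid <- sid; break }
    }
    if (is.null(nxt_sid)) break
    visited <- c(visited, nxt_sid)
    seg <- segs[[nxt_sid]]
    forward <- identical(seg$from_node_id, cur)
    from_id <- if (forward) seg$from_node_id else seg$to_node_id
    to_id <- if (forward) seg$to_node_id else seg$from_node_id
    p0 <- node_xy(map, from_id)
    p3 <- node_xy(map, to_id)
    if (!is.null(seg$b1)) {
      b1 <- c(seg$b1$x, seg$b1$y); b2 <- c(seg$b2$x, seg$b2$y)
      if (!forward) { tmp <- b1; b1 <- b2; b2 <- tmp }
      tt <- seq(0, 1, length.out = 10)[-1]
      pts <- rbind(pts, bezier_point(p0, b1, b2, p3, tt))
    } else {
      pts <- rbind(pts, p3)
    }
    cur <- to_id
  }

  span <- pts[nrow(pts), ] - pts[1, ]
  len <- sqrt(sum(span^2))
  if (len < 1e-12 || nrow(pts) < 2) {
    stop(pg_error("pg_degenerate_geometry",
                  sprintf("reaction '%s' has a degenerate (zero-length) polyline", reaction_id)))
  }
  list(polyline = unname(pts), direction = span / len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers can branch on error type
pg_error <- function(class, message) {
  structure(class = c(class, "pg_error", "error", "condition"),
            list(message = message, call = NULL))
}
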