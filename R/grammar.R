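#' Declare a visual layer
#'
#' A layer binds one column of a tidy measurement table to a geometric entity
#' family on the map (a geom) through a visual channel (an aesthetic).
#' Geoms: `arrow` (reaction edge), `metabolite` (node), `box` (stacked box
#' point), `hist` (histogram), `kde` (kernel density curve). Edge-anchored
#' distribution geoms and box points additionally carry a `side`: `left`,
#' `right` or `hover` (a third static axis at the reaction label).
#'
#' @param geom One of `"arrow"`, `"metabolite"`, `"box"`, `"hist"`, `"kde"`.
#' @param aesthetic One of `"color"`, `"size"`, `"y"`. `arrow`/`metabolite`
#'   accept color or size; `box` requires color; `hist`/`kde` require `y`.
#' @param side Required for box/hist/kde; forbidden otherwise.
#' @param column Name of the table column supplying the values.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(geom, aesthetic, side = NULL, column = "value") {
  geoms <- c("arrow", "metabolite", "box", "hist", "kde")
  if (!geom %in% geoms) {
    stop(pg_error("pg_schema_error",
                  sprintf("unknown geom '%s' (must be one of %s)", geom,
                          paste(geoms, collapse = ", "))))
  }
  ok <- switch(geom,
    arrow = ,
    metabolite = aesthetic %in% c("color", "size"),
    box = identical(aesthetic, "color"),
    hist = ,
    kde = identical(aesthetic, "y"))
  if (!ok) {
    stop(pg_error("pg_schema_error",
                  sprintf("aesthetic '%s' is not valid for geom '%s'", aesthetic, geom)))
  }
  needs_side <- geom %in% c("box", "hist", "kde")
  if (needs_side) {
    if (is.null(side) || !side %in% c("left", "right", "hover")) {
      stop(pg_error("pg_schema_error",
                    sprintf("geom '%s' requires side left, right or hover", geom)))
    }
  } else if (!is.null(side)) {
    stop(pg_error("pg_schema_error",
                  sprintf("geom '%s' does not take a side", geom)))
  }
  structure(list(geom = geom, aesthetic = aesthetic, side = side, column = column),
            class = "layer_spec")
}

point_geoms <- c("arrow", "metabolite", "box")

#' Build a data specification from a tidy table
#'
#' Groups the table by (layer, identifier, condition). Point-valued geoms
#' (arrow, metabolite, box) aggregate repeated measurements by arithmetic
#' mean; distribution geoms (hist, kde) keep every value. Rows with a missing
#' condition are assigned condition `"default"`. The condition order of the
#' result is the order of first appearance in the table, which is how stacked
#' box points are later ordered top to bottom.
#'
#' @param table A data.frame with columns `identifier`, optionally
#'   `condition`, and the value columns named by the layers.
#' @param layers A list of [layer_spec()] objects (a single spec is accepted).
#' @return A `dataspec` list with elements `version`, `conditions`, `layers`,
#'   `series`. Each series holds `layer` (1-based index), `geom`, `aesthetic`,
#'   `side`, `identifier`, `condition`, `values`.
#' @export
build_dataspec <- function(table, layers) {
  if (inherits(layers, "layer_spec")) layers <- list(layers)
  stopifnot(is.data.frame(table))
  if (!"identifier" %in% names(table)) {
    stop(pg_error("pg_schema_error", "table has no 'identifier' column"))
  }
  cond <- if ("condition" %in% names(table)) as.character(table$condition) else
    rep(NA_character_, nrow(table))
  cond[is.na(cond) | cond == ""] <- "default"
  conditions <- unique(cond)
  ident <- as.character(table$identifier)
  if (any(!nzchar(ident))) {
    stop(pg_error("pg_schema_error", "empty identifier in table"))
  }

  series <- list()
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (!ly$column %in% names(table)) {
      stop(pg_error("pg_schema_error",
                    sprintf("layer %d: column '%s' not found in table", li, ly$column)))
    }
    vals <- table[[ly$column]]
    if (!is.numeric(vals)) {
      stop(pg_error("pg_schema_error",
                    sprintf("layer %d: column '%s' is not numeric", li, ly$column)))
    }
    keep <- is.finite(vals)
    key_id <- ident[keep]; key_cond <- cond[keep]; v <- vals[keep]
    if (length(v) == 0) next
    # deterministic group order: identifier, then condition first-appearance
    for (id in unique(key_id)) {
      for (cd in conditions[conditions %in% key_cond[key_id == id]]) {
        vv <- v[key_id == id & key_cond == cd]
        if (ly$geom %in% point_geoms) {
          vv <- mean(vv)
        } else if (length(vv) < 2) {
          stop(pg_error("pg_insufficient_data",
                        sprintf("distribution series for '%s' (%s) has fewer than 2 values",
                                id, cd)))
        }
        series[[length(series) + 1]] <- list(
          layer = li, geom = ly$geom, aesthetic = ly$aesthetic,
          side = ly$side, identifier = id, condition = cd, values = vv)
      }
    }
  }
  structure(list(version = "pathglyph-1", conditions = conditions,
                 layers = layers, series = series),
            class = "dataspec")
}

#' Write a data specification to the interchange file
#'
#' The interchange file is the JSON that binds measurement values to map
#' identifiers, aesthetics, geoms, sides and conditions; its name must end in
#' `metabolism.json` so that downstream tools recognize it.
#'
#' @param spec A `dataspec`.
#' @param path Output path ending in `"metabolism.json"`.
#' @param force Allow a non-conforming file name.
#' @return `path`, invisibly.
#' @export
write_interchange <- function(spec, path, force = FALSE) {
  stopifnot(inherits(spec, "dataspec"))
  if (!force && !grepl("metabolism\\.json$", path)) {
    stop(pg_error("pg_naming_error",
                  sprintf("interchange path must end in 'metabolism.json' (got '%s'); use force = TRUE to override",
                          basename(path))))
  }
  payload <- list(
    version = jsonlite::unbox(spec$version),
    conditions = as.list(spec$conditions),
    layers = lapply(spec$layers, function(ly) {
      out <- list(geom = jsonlite::unbox(ly$geom),
                  aesthetic = jsonlite::unbox(ly$aesthetic),
                  column = jsonlite::unbox(ly$column))
      if (!is.null(ly$side)) out$side <- jsonlite::unbox(ly$side)
      out
    }),
    series = lapply(spec$series, function(s) {
      list(layer = jsonlite::unbox(s$layer),
           identifier = jsonlite::unbox(s$identifier),
           condition = jsonlite::unbox(s$condition),
           values = as.numeric(s$values))
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = FALSE, digits = NA)
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}

interchange_enums <- list(
  geom = c("arrow", "metabolite", "box", "hist", "kde"),
  aesthetic = c("color", "size", "y"),
  side = c("left", "right", "hover")
)

#' Read an interchange file back into a data specification
#'
#' Validates the document against the `pathglyph-1` interchange schema and
#' reports every violation with its JSON pointer path.
#'
#' @param path Path to a `*metabolism.json` file.
#' @return A `dataspec`.
#' @export
read_interchange <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop(pg_error("pg_parse_error",
                    paste0("malformed JSON: ", conditionMessage(e)))))
  errs <- character(0)
  bad <- function(ptr, msg) errs[[length(errs) + 1]] <<- sprintf("%s: %s", ptr, msg)

  if (!is.list(doc) || is.null(names(doc))) {
    stop(pg_error("pg_validation_error", "/: interchange document must be a JSON object"))
  }
  if (!identical(doc$version, "pathglyph-1")) bad("/version", "must be 'pathglyph-1'")
  conds <- vapply(doc$conditions %||% list(), as.character, character(1))
  layers <- list()
  for (i in seq_along(doc$layers %||% list())) {
    ly <- doc$layers[[i]]
    ptr <- sprintf("/layers/%d", i - 1)
    geom <- ly$geom %||% ""
    aest <- ly$aesthetic %||% ""
    side <- ly$side
    if (!geom %in% interchange_enums$geom) bad(paste0(ptr, "/geom"),
        sprintf("'%s' is not a known geom", geom))
    if (!aest %in% interchange_enums$aesthetic) bad(paste0(ptr, "/aesthetic"),
        sprintf("'%s' is not a known aesthetic", aest))
    if (!is.null(side) && !side %in% interchange_enums$side)
      bad(paste0(ptr, "/side"), sprintf("'%s' is not a known side", side))
    lyr <- tryCatch(layer_spec(geom, aest, side, ly$column %||% "value"),
                    pg_error = function(e) { bad(ptr, conditionMessage(e)); NULL })
    if (!is.null(lyr)) layers[[length(layers) + 1]] <- lyr else layers[length(layers) + 1] <- list(NULL)
  }
  series <- list()
  for (i in seq_along(doc$series %||% list())) {
    s <- doc$series[[i]]
    ptr <- sprintf("/series/%d", i - 1)
    li <- s$layer %||% NA
    if (!is.numeric(li) || is.na(li) || li < 1 || li > length(layers)) {
      bad(paste0(ptr, "/layer"), "must reference an existing layer (1-based)")
      next
    }
    ly <- layers[[li]]
    if (is.null(ly)) next
    vv <- as.numeric(unlist(s$values))
    if (!ly$geom %in% point_geoms && length(vv) < 2)
      bad(paste0(ptr, "/values"), "distribution series needs at least 2 values")
    if (ly$geom %in% point_geoms && length(vv) != 1)
      bad(paste0(ptr, "/values"), "point series must hold exactly one value")
    series[[length(series) + 1]] <- list(
      layer = as.integer(li), geom = ly$geom, aesthetic = ly$aesthetic,
      side = ly$side, identifier = as.character(s$identifier %||% ""),
      condition = as.character(s$condition %||% "default"), values = vv)
  }
  if (length(errs)) {
    stop(pg_error("pg_validation_error",
                  paste0("interchange schema violations:\n  ",
                         paste(errs, collapse = "\n  "))))
  }
  structure(list(version = "pathglyph-1", conditions = conds,
                 layers = layers, series = series),
            class = "dataspec")
}

#' Match data identifiers against map entities
#'
#' Matching is exact on reaction `bigg_id` for arrow/box/hist/kde series and
#' on metabolite node `bigg_id` for metabolite series. Unmatched data
#' identifiers are skipped at render time with a warning; map entities with
#' no data simply render with defaults.
#'
#' @param spec A `dataspec`.
#' @param map An `escher_map`.
#' @return A `match_report` list: `matched`, `unmatched_data`, `dataless_map`.
#' @export
match_to_map <- function(spec, map) {
  rxn_ids <- unique(unname(map_reaction_bigg_ids(map)))
  met_ids <- unique(unname(map_metabolite_bigg_ids(map)))
  data_rxn <- unique(vapply(
    Filter(function(s) s$geom != "metabolite", spec$series),
    function(s) s$identifier, character(1)))
  data_met <- unique(vapply(
    Filter(function(s) s$geom == "metabolite", spec$series),
    function(s) s$identifier, character(1)))
  matched <- c(intersect(data_rxn, rxn_ids), intersect(data_met, met_ids))
  unmatched <- c(setdiff(data_rxn, rxn_ids), setdiff(data_met, met_ids))
  dataless <- c(setdiff(rxn_ids, data_rxn), setdiff(met_ids, data_met))
  structure(list(matched = matched, unmatched_data = unmatched,
                 dataless_map = dataless),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("pathglyph match report: %d matched, %d unmatched data ids, %d data-less map entities\n",
              length(x$matched), length(x$unmatched_data), length(x$dataless_map)))
  if (length(x$unmatched_data))
    cat("  unmatched:", paste(x$unmatched_data, collapse = ", "), "\n")
  invisible(x)
}
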