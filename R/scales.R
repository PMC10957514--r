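#' Linear size scale
#'
#' Maps a continuous data value into a size range in map units. With
#' `absolute = TRUE` the magnitude of the value is used, so e.g. forward and
#' reverse fluxes of the same size render identically (flux as color and size
#' of edges in absolute scale).
#'
#' @param domain `c(lo, hi)` data domain; a degenerate domain is expanded by
#'   0.5 on each side.
#' @param range `c(r_lo, r_hi)` output sizes, `r_lo <= r_hi`.
#' @param absolute Use `|value|` before clamping.
#' @return A `linear_scale`.
#' @export
linear_scale <- function(domain, range, absolute = FALSE) {
  stopifnot(length(domain) == 2, length(range) == 2, range[1] <= range[2])
  if (domain[1] == domain[2]) domain <- domain + c(-0.5, 0.5)
  stopifnot(domain[1] < domain[2])
  structure(list(domain = domain, range = range, absolute = absolute),
            class = "linear_scale")
}

parse_hex <- function(col) {
  stopifnot(grepl("^#[0-9a-fA-F]{6}$", col))
  as.numeric(c(strtoi(substr(col, 2, 3), 16L),
               strtoi(substr(col, 4, 5), 16L),
               strtoi(substr(col, 6, 7), 16L)))
}

rgb_hex <- function(rgb) sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])

#' Continuous color scale
#'
#' Piecewise-linear interpolation between ordered color stops in sRGB,
#' componentwise. Stops are pairs of a position in \[0, 1\] (0 = domain low,
#' 1 = domain high; strictly increasing, first 0 and last 1) and a color.
#'
#' @param domain `c(lo, hi)` data domain; degenerate domains are expanded by
#'   0.5 on each side.
#' @param stops Character vector of hex colors `"#RRGGBB"` placed at equally
#'   spaced positions, or a list of `list(position, color)` pairs.
#' @param absolute Use `|value|` before clamping.
#' @param na_color Color for non-finite values (default mid-gray).
#' @return A `color_scale`.
#' @export
color_scale <- function(domain, stops = c("#2166AC", "#B2182B"),
                        absolute = FALSE, na_color = "#808080") {
  stopifnot(length(domain) == 2)
  if (domain[1] == domain[2]) domain <- domain + c(-0.5, 0.5)
  stopifnot(domain[1] < domain[2])
  if (is.character(stops)) {
    stopifnot(length(stops) >= 2)
    pos <- seq(0, 1, length.out = length(stops))
    stops <- Map(function(p, col) list(position = p, color = col), pos, stops)
  }
  pos <- vapply(stops, function(s) s$position, numeric(1))
  stopifnot(pos[1] == 0, pos[length(pos)] == 1, all(diff(pos) > 0))
  rgbm <- t(vapply(stops, function(s) parse_hex(s$color), numeric(3)))
  structure(list(domain = domain, positions = pos, rgb = rgbm,
                 absolute = absolute, na_color = na_color),
            class = "color_scale")
}

clamp_value <- function(value, domain, absolute) {
  v <- if (absolute) abs(value) else value
  min(max(v, domain[1]), domain[2])
}

#' Map a value to a color
#'
#' Clamps the (optionally absolute) value to the domain, finds the bracketing
#' stops and interpolates each sRGB channel linearly; channel values are
#' rounded half-up.
#'
#' @param scale A [color_scale()].
#' @param value A number; non-finite values return the scale's missing-value
#'   color.
#' @return Hex color string `"#RRGGBB"`.
#' @export
map_color <- function(scale, value) {
  stopifnot(inherits(scale, "color_scale"))
  if (!is.finite(value)) return(scale$na_color)
  v <- clamp_value(value, scale$domain, scale$absolute)
  t <- (v - scale$domain[1]) / diff(scale$domain)
  pos <- scale$positions
  i <- findInterval(t, pos, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(pos) - 1L)
  f <- (t - pos[i]) / (pos[i + 1] - pos[i])
  ch <- scale$rgb[i, ] + f * (scale$rgb[i + 1, ] - scale$rgb[i, ])
  rgb_hex(floor(ch + 0.5))  # round half up, per channel
}

#' Map a value to a size
#'
#' Same clamping and absolute-value semantics as [map_color()], followed by
#' linear interpolation into the size range.
#'
#' @param scale A [linear_scale()].
#' @param value A number; non-finite values return `default`.
#' @param default Size returned for non-finite values (midpoint of the range
#'   when `NULL`).
#' @return Size in map units.
#' @export
map_size <- function(scale, value, default = NULL) {
  stopifnot(inherits(scale, "linear_scale"))
  if (!is.finite(value)) {
    return(if (is.null(default)) mean(scale$range) else default)
  }
  v <- clamp_value(value, scale$domain, scale$absolute)
  t <- (v - scale$domain[1]) / diff(scale$domain)
  scale$range[1] + t * diff(scale$range)
}

# default palettes: sequential blue->red for signed data; white->green box
# points
default_palette <- function(geom) {
  if (identical(geom, "box")) c("#FFFFFF", "#1A9850") else c("#2166AC", "#B2182B")
}
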