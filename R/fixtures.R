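# Toy maps and synthetic multi-condition datasets: every module can be
# exercised without downloading published maps or model output.

#' Generate a toy Escher map
#'
#' A linear chain of reactions laid out on a grid: metabolite nodes every
#' 150 map units along x, two midmarkers between consecutive metabolites,
#' straight segments. Reactions are `R1..Rn`, metabolites `M1..M(n+1)`.
#' Options add a branch reaction, a curved (cubic Bezier) segment, or a
#' duplicated metabolite node (the same `bigg_id` at two positions), which
#' real Escher maps use for currency metabolites.
#'
#' @param n_linear_reactions Number of chain reactions (>= 1).
#' @param branch Add one branch reaction `RB1` from the middle metabolite
#'   down to `B1`.
#' @param seed Unused for layout (the map is fully deterministic) but kept so
#'   scenarios can thread one seed through fixture generation.
#' @param curved Make the middle segment of `R1` a cubic Bezier.
#' @param duplicate_met Add a second node carrying `M1`'s bigg_id.
#' @return An `escher_map`.
#' @export
toy_map <- function(n_linear_reactions, branch = FALSE, seed = 1,
                    curved = FALSE, duplicate_met = FALSE) {
  stopifnot(n_linear_reactions >= 1)
  n <- n_linear_reactions
  y0 <- 200
  nodes <- list()
  reactions <- list()
  next_id <- 1L
  new_id <- function() {
    id <- as.character(next_id)
    next_id <<- next_id + 1L
    id
  }

  met_ids <- character(n + 1)
  for (i in seq_len(n + 1)) {
    id <- new_id()
    met_ids[i] <- id
    x <- (i - 1) * 150
    nodes[[id]] <- list(node_type = "metabolite", x = x, y = y0,
                        bigg_id = paste0("M", i), name = paste0("Metabolite ", i),
                        label_x = x - 10, label_y = y0 - 20,
                        node_is_primary = TRUE)
  }

  make_reaction <- function(bigg, from_id, to_id, bezier = FALSE) {
    p0 <- c(nodes[[from_id]]$x, nodes[[from_id]]$y)
    p3 <- c(nodes[[to_id]]$x, nodes[[to_id]]$y)
    mm1 <- new_id(); mm2 <- new_id()
    q1 <- p0 + (p3 - p0) / 3
    q2 <- p0 + 2 * (p3 - p0) / 3
    nodes[[mm1]] <<- list(node_type = "midmarker", x = q1[1], y = q1[2])
    nodes[[mm2]] <<- list(node_type = "multimarker", x = q2[1], y = q2[2])
    segs <- list()
    segs[[new_id()]] <- list(from_node_id = from_id, to_node_id = mm1,
                             b1 = NULL, b2 = NULL)
    mid <- if (bezier) {
      perp <- left_normal((p3 - p0) / sqrt(sum((p3 - p0)^2)))
      list(from_node_id = mm1, to_node_id = mm2,
           b1 = list(x = q1[1] + 15 * perp[1], y = q1[2] + 40 * perp[2]),
           b2 = list(x = q2[1] - 15 * perp[1], y = q2[2] + 40 * perp[2]))
    } else {
      list(from_node_id = mm1, to_node_id = mm2, b1 = NULL, b2 = NULL)
    }
    segs[[new_id()]] <- mid
    segs[[new_id()]] <- list(from_node_id = mm2, to_node_id = to_id,
                             b1 = NULL, b2 = NULL)
    mid_xy <- (p0 + p3) / 2
    list(bigg_id = bigg, name = paste0("Reaction ", bigg),
         label_x = mid_xy[1] - 10, label_y = mid_xy[2] + 45,
         reversibility = FALSE,
         segments = segs,
         metabolites = list(
           list(bigg_id = nodes[[from_id]]$bigg_id, coefficient = -1),
           list(bigg_id = nodes[[to_id]]$bigg_id, coefficient = 1)))
  }

  for (i in seq_len(n)) {
    reactions[[paste0("r", i)]] <- make_reaction(
      paste0("R", i), met_ids[i], met_ids[i + 1],
      bezier = curved && i == 1)
  }

  if (branch) {
    mid_i <- max(2L, ceiling((n + 1) / 2))
    bid <- new_id()
    bx <- nodes[[met_ids[mid_i]]]$x
    nodes[[bid]] <- list(node_type = "metabolite", x = bx, y = y0 + 150,
                         bigg_id = "B1", name = "Branch metabolite 1",
                         label_x = bx + 15, label_y = y0 + 150,
                         node_is_primary = TRUE)
    reactions[["rb1"]] <- make_reaction("RB1", met_ids[mid_i], bid)
  }

  if (duplicate_met) {
    did <- new_id()
    nodes[[did]] <- list(node_type = "metabolite", x = 60, y = y0 - 120,
                         bigg_id = "M1", name = "Metabolite 1",
                         label_x = 60, label_y = y0 - 140,
                         node_is_primary = FALSE)
  }

  xs <- vapply(nodes, function(nd) nd$x, numeric(1))
  ys <- vapply(nodes, function(nd) nd$y, numeric(1))
  body <- list(
    canvas = list(x = min(xs) - 120, y = min(ys) - 140,
                  width = diff(range(xs)) + 240, height = diff(range(ys)) + 300),
    nodes = nodes,
    reactions = reactions,
    text_labels = structure(list(), names = character(0))
  )
  header <- list(map_name = sprintf("pathglyph toy map (%d reactions)", n),
                 map_id = sprintf("toy-%d-%d", n, seed),
                 map_description = "generated fixture",
                 homepage = "https://escher.github.io",
                 schema = "https://escher.github.io/escher/jsonschema/1-0-4#")
  m <- structure(list(header = header, body = body), class = "escher_map")
  validate_escher_map(m)
  m
}

#' Describe a synthetic multi-condition scenario
#'
#' Parameters of the synthetic dataset emulating a multi-omics case study:
#' per reaction and condition, a distribution of flux draws (normal, like
#' posterior or flux-sampling draws) and an enzyme-concentration point value
#' (lognormal, positive); per metabolite and condition, a concentration
#' point value (lognormal).
#'
#' @param n_conditions Number of conditions (3 gives the gas-mixture names
#'   `CO`, `H2-High CO`, `Syngas`; other counts are named `cond1..k`).
#' @param n_draws Draws per flux distribution.
#' @param seed Seed fixing every draw.
#' @param flux_mean,flux_sd Flux distribution location/spread (condition
#'   offsets are added to the mean).
#' @param enzyme_meanlog,enzyme_sdlog Lognormal enzyme parameters.
#' @param conc_meanlog,conc_sdlog Lognormal metabolite-concentration
#'   parameters.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_conditions = 3, n_draws = 200, seed = 42,
                               flux_mean = 2, flux_sd = 1,
                               enzyme_meanlog = 0, enzyme_sdlog = 0.5,
                               conc_meanlog = 0, conc_sdlog = 0.8) {
  stopifnot(n_conditions >= 1, n_draws >= 1)
  structure(list(n_conditions = n_conditions, n_draws = n_draws, seed = seed,
                 flux_mean = flux_mean, flux_sd = flux_sd,
                 enzyme_meanlog = enzyme_meanlog, enzyme_sdlog = enzyme_sdlog,
                 conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog),
            class = "synthetic_scenario")
}

scenario_conditions <- function(n) {
  if (n == 3) c("CO", "H2-High CO", "Syngas") else paste0("cond", seq_len(n))
}

#' Generate a synthetic multi-condition case study for a map
#'
#' Emulates a combined proteomics / metabolomics / flux-sampling study: per
#' reaction and condition, `n_draws` flux draws (mapped to kernel-density
#' curves on the left of the edge) and a lognormal enzyme level (mapped to
#' box-point color on the right); per metabolite and condition, a lognormal
#' concentration (mapped to node color and size).
#'
#' @param map An `escher_map` (ids are read from it).
#' @param scenario A [synthetic_scenario()].
#' @return List with `table` (tidy data.frame with columns `identifier`,
#'   `condition`, `flux`, `enzyme`, `concentration`) and `layers` (list of
#'   [layer_spec()] mirroring the case-study mapping).
#' @export
synthetic_case_study <- function(map, scenario = synthetic_scenario()) {
  stopifnot(inherits(map, "escher_map"), inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  conds <- scenario_conditions(scenario$n_conditions)
  rxns <- sort(unique(unname(map_reaction_bigg_ids(map))))
  mets <- sort(unique(unname(map_metabolite_bigg_ids(map))))

  rows <- list()
  add <- function(id, cond, flux = NA, enzyme = NA, conc = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      identifier = id, condition = cond, flux = flux, enzyme = enzyme,
      concentration = conc, stringsAsFactors = FALSE)
  }
  for (cj in seq_along(conds)) {
    offset <- 0.5 * (cj - 1)
    for (r in rxns) {
      draws <- stats::rnorm(scenario$n_draws,
                            mean = scenario$flux_mean + offset,
                            sd = scenario$flux_sd)
      add(r, conds[cj], flux = draws)
      add(r, conds[cj],
          enzyme = stats::rlnorm(1, scenario$enzyme_meanlog + 0.2 * (cj - 1),
                                 scenario$enzyme_sdlog))
    }
    for (m in mets) {
      add(m, conds[cj],
          conc = stats::rlnorm(1, scenario$conc_meanlog + 0.1 * (cj - 1),
                               scenario$conc_sdlog))
    }
  }
  table <- do.call(rbind, rows)
  layers <- list(
    layer_spec("metabolite", "color", column = "concentration"),
    layer_spec("metabolite", "size", column = "concentration"),
    layer_spec("box", "color", side = "right", column = "enzyme"),
    layer_spec("kde", "y", side = "left", column = "flux")
  )
  list(table = table, layers = layers)
}
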