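#' Hunting-pressure index for one plot
#'
#' Computes the settlement-based hunting-pressure (HP) proxy for a forest plot
#' as the sum of population-to-distance ratios over the nearest village and the
#' two regional towns (Carauari and Itamarati):
#' \deqn{HP = S_{vil}/d_{vil} + S_{car}/d_{car} + S_{ita}/d_{ita}}
#' where S is the human population of a settlement and d its distance (km)
#' from the plot centroid (Euclidean for villages, fluvial for towns; the
#' distinction is the data supplier's responsibility and is carried as
#' metadata). Units are persons/km. HP is strictly increasing in every
#' population and strictly decreasing in every distance.
#'
#' @param village,town_carauari,town_itamarati lists (or one-row data.frames)
#'   with elements `population` (persons, >= 1) and `distance_km` (> 0).
#' @return Numeric HP index (> 0).
#' @examples
#' hunting_pressure(list(population = 100, distance_km = 10),
#'                  list(population = 28076, distance_km = 100),
#'                  list(population = 7888, distance_km = 200))
#' @export
hunting_pressure <- function(village, town_carauari, town_itamarati) {
  term <- function(s, what) {
    s <- as.list(s)
    abort_if(is.null(s$population) || is.null(s$distance_km),
             sprintf("%s must carry population and distance_km", what))
    abort_if(s$population < 1, sprintf("%s population must be >= 1", what))
    abort_if(s$distance_km <= 0,
             sprintf("%s distance must be > 0 (plot coinciding with a settlement is out of model)",
                     what))
    s$population / s$distance_km
  }
  term(village, "village") + term(town_carauari, "town_carauari") +
    term(town_itamarati, "town_itamarati")
}

#' Nearest village to a plot
#'
#' Returns the village minimising distance to the plot centroid; ties are
#' broken by settlement name order.
#'
#' @param settlements data.frame with columns `name`, `kind`, `population`,
#'   `distance_km` (one plot's candidate settlements).
#' @return One-row data.frame for the nearest village.
#' @export
nearest_village <- function(settlements) {
  require_columns(settlements, c("name", "kind", "population", "distance_km"),
                  "settlement table")
  vil <- settlements[settlements$kind == "village", , drop = FALSE]
  abort_if(nrow(vil) == 0, "no village in settlement table")
  vil <- vil[order(vil$distance_km, vil$name), , drop = FALSE]
  vil[1, , drop = FALSE]
}

#' Plot-level HP from a settlement table
#'
#' For every plot in a long settlement table, picks the nearest village and the
#' towns (kind == "town", matched by name containing "carauari"/"itamarati",
#' case-insensitive) and evaluates the HP index.
#'
#' @param settlements data.frame with columns `plot_id`, `name`, `kind`,
#'   `population`, `distance_km`.
#' @return data.frame with `plot_id` and `hp`.
#' @export
plot_hp <- function(settlements) {
  require_columns(settlements,
                  c("plot_id", "name", "kind", "population", "distance_km"),
                  "settlement table")
  plots <- unique(settlements$plot_id)
  hp <- vapply(plots, function(p) {
    s <- settlements[settlements$plot_id == p, , drop = FALSE]
    towns <- s[s$kind == "town", , drop = FALSE]
    car <- towns[grepl("carauari", tolower(towns$name)), , drop = FALSE]
    ita <- towns[grepl("itamarati", tolower(towns$name)), , drop = FALSE]
    abort_if(nrow(car) != 1 || nrow(ita) != 1,
             sprintf("plot %s must list exactly one Carauari and one Itamarati town row", p))
    hunting_pressure(nearest_village(s), car, ita)
  }, numeric(1))
  data.frame(plot_id = plots, hp = hp, stringsAsFactors = FALSE)
}
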