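#' Generate a synthetic landscape of sites, plots and settlements
#'
#' Lays out `n_sites` forest sites of two plots each (0.25-ha tree plot with a
#' nested 0.05-ha sapling subplot) along a hunting-pressure gradient, together
#' with the settlement geometry that produces it and plot-level environmental
#' covariates.
#'
#' Site-level HP targets are log-spaced across `hp_range` (both plots of a
#' site share the site's hunting catchment and HP). Settlement populations are
#' drawn first and distances are then back-computed so that the HP index
#' evaluated on the settlement table reproduces the target exactly: the index,
#' not the map geometry, is what the analysis consumes. Each plot also gets a
#' decoy village farther away so nearest-village selection is exercised.
#'
#' Soil cation exchange capacity (CEC, cmol/kg) is drawn from a right-skewed
#' lognormal calibrated to a plot mean of ~0.8 cmol/kg; vertical distance to
#' nearest drainage (VDND, m) from a gamma with mean ~16.3 m.
#'
#' @param n_sites number of sites (>= 2); each contributes 2 plots.
#' @param hp_range length-2 numeric, min and max plot HP (persons/km). May be
#'   degenerate (equal endpoints).
#' @param village_pop_range integer range for village populations.
#' @param seed RNG seed or NULL.
#' @return List of class `hr_landscape` with elements `sites` (character),
#'   `plots` (data.frame: plot_id, site_id, hp, cec, vdnd, tree_area,
#'   sapling_area) and `settlements` (long data.frame usable by [plot_hp()]).
#' @export
generate_landscape <- function(n_sites = 15,
                               hp_range = c(2.4, 13.8),
                               village_pop_range = c(50, 400),
                               seed = NULL) {
  abort_if(n_sites < 2, "n_sites must be >= 2")
  abort_if(length(hp_range) != 2 || any(hp_range <= 0) ||
             hp_range[2] < hp_range[1],
           "hp_range must be a positive, non-decreasing interval")
  if (!is.null(seed)) set.seed(seed)

  towns <- data.frame(name = c("Carauari", "Itamarati"),
                      population = c(28076L, 7888L))

  site_hp <- if (hp_range[1] == hp_range[2]) {
    rep(hp_range[1], n_sites)
  } else {
    exp(seq(log(hp_range[1]), log(hp_range[2]), length.out = n_sites))
  }

  sites <- sprintf("S%02d", seq_len(n_sites))
  plots <- data.frame(
    plot_id = sprintf("%sP%d", rep(sites, each = 2), rep(1:2, n_sites)),
    site_id = rep(sites, each = 2),
    hp_target = rep(site_hp, each = 2),
    stringsAsFactors = FALSE
  )
  n_plots <- nrow(plots)

  settlements <- do.call(rbind, lapply(seq_len(n_plots), function(i) {
    hp <- plots$hp_target[i]
    # Split the index across the three terms, village-dominated.
    f_vil <- stats::runif(1, 0.45, 0.65)
    f_car <- (1 - f_vil) * stats::runif(1, 0.6, 0.8)
    f_ita <- 1 - f_vil - f_car
    pop_vil <- sample(seq(village_pop_range[1], village_pop_range[2]), 1)
    d_vil <- pop_vil / (f_vil * hp)
    d_car <- towns$population[1] / (f_car * hp)
    d_ita <- towns$population[2] / (f_ita * hp)
    decoy_pop <- sample(seq(village_pop_range[1], village_pop_range[2]), 1)
    decoy_d <- d_vil * stats::runif(1, 1.5, 4)
    data.frame(
      plot_id = plots$plot_id[i],
      name = c(sprintf("village_%s", plots$plot_id[i]), "Carauari", "Itamarati",
               sprintf("village_far_%s", plots$plot_id[i])),
      kind = c("village", "town", "town", "village"),
      population = c(pop_vil, towns$population, decoy_pop),
      distance_km = c(d_vil, d_car, d_ita, decoy_d),
      stringsAsFactors = FALSE
    )
  }))

  hp_realised <- plot_hp(settlements)
  plots$hp <- hp_realised$hp[match(plots$plot_id, hp_realised$plot_id)]
  plots$hp_target <- NULL
  plots$cec <- stats::rlnorm(n_plots, log(0.55), 0.9)
  plots$vdnd <- stats::rgamma(n_plots, shape = 1.5, scale = 16.3 / 1.5)
  plots$tree_area <- 0.25
  plots$sapling_area <- 0.05

  structure(list(sites = sites, plots = plots, settlements = settlements),
            class = "hr_landscape")
}
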