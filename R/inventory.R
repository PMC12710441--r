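#' Ground-truth parameter set for the synthetic inventory
#'
#' Encodes the effect structure that the model suite is meant to recover:
#' guild-specific hunting-pressure slopes on the log sapling density, an
#' HP-by-seed-length interaction restricted to endozoochorous species,
#' additive covariate effects, and species/family random-intercept SDs. All
#' slopes act on standardised (z-scored) predictors, with seed length
#' standardised within the endozoochorous guild.
#'
#' Defaults encode the study's qualitative findings: recruitment of
#' endozoochorous species declines with HP while abiotic and scatter-hoarded
#' species gain, and larger-seeded endozoochorous species are hit harder.
#'
#' @param beta_hp_by_mode named numeric length 3: HP slope per dispersal mode
#'   (log sapling-density scale, per SD of HP).
#' @param beta_hp_x_sl HP x standardised-SL interaction, endozoochorous only.
#' @param beta_cec,beta_vdnd additive covariate slopes.
#' @param sigma_species,sigma_family random-intercept SDs (>= 0).
#' @param seed integer seed stored with the truth and used by
#'   [generate_inventory()].
#' @return List of class `hr_ground_truth`.
#' @export
ground_truth <- function(beta_hp_by_mode = c(abiotic = 0.15,
                                             scatter_hoarded = 0.15,
                                             endozoochory = -0.3),
                         beta_hp_x_sl = -0.15,
                         beta_cec = 0.05,
                         beta_vdnd = 0.10,
                         sigma_species = 0.5,
                         sigma_family = 0.2,
                         seed = 1L) {
  abort_if(!setequal(names(beta_hp_by_mode), dispersal_modes()),
           "beta_hp_by_mode must be named with the three dispersal modes")
  vals <- c(beta_hp_by_mode, beta_hp_x_sl, beta_cec, beta_vdnd,
            sigma_species, sigma_family)
  abort_if(any(!is.finite(vals)), "all ground-truth parameters must be finite")
  abort_if(sigma_species < 0 || sigma_family < 0, "sigma_* must be >= 0")
  structure(list(beta_hp_by_mode = beta_hp_by_mode[dispersal_modes()],
                 beta_hp_x_sl = beta_hp_x_sl,
                 beta_cec = beta_cec, beta_vdnd = beta_vdnd,
                 sigma_species = sigma_species, sigma_family = sigma_family,
                 seed = as.integer(seed)),
            class = "hr_ground_truth")
}

#' Generate a synthetic stem inventory
#'
#' Simulates adult and sapling stems for every plot of a landscape from a
#' species pool and a ground-truth parameter set.
#'
#' Adult abundance is independent of hunting pressure: species get lognormal
#' relative abundances (a species-abundance distribution), scaled to an
#' expected `mean_trees_per_plot` stems per 0.25-ha plot, and per-plot counts
#' are negative binomial (size = 1), which reproduces realistic rarity.
#' Sapling counts in the nested 0.05-ha subplot are Poisson with log-mean
#' \deqn{\log(\mu_{adult} \cdot A_{sap}/A_{tree} \cdot c_0) +
#'   \beta_{mode} z_{HP} + 1[endo]\,\beta_{HP \times SL} z_{HP} z_{SL} +
#'   \beta_{CEC} z_{CEC} + \beta_{VDND} z_{VDND} + u_{species} + u_{family}}
#' so that at null effects the expected per-hectare sapling density tracks the
#' adult density up to the constant \eqn{c_0} (set by `mean_saplings_per_plot`),
#' giving the sapling-to-tree ratio a meaningful null. Adult DBH is >= 10 cm
#' (shifted exponential); sapling diameters are uniform on 1-5 cm.
#'
#' @param pool `hr_species_pool`.
#' @param landscape `hr_landscape`.
#' @param truth `hr_ground_truth`; its `seed` drives all randomness here.
#' @param mean_trees_per_plot expected adult stems per tree plot.
#' @param mean_saplings_per_plot expected saplings per sapling subplot.
#' @param sad_sdlog lognormal SD of the species-abundance distribution.
#' @return data.frame of class `hr_stem_table` (stem_id, plot_id, site_id,
#'   life_stage, species_id, genus, family, dbh_cm), with the ground truth in
#'   `attr(, "ground_truth")`.
#' @export
generate_inventory <- function(pool, landscape, truth,
                               mean_trees_per_plot = 160,
                               mean_saplings_per_plot = 200,
                               sad_sdlog = 1.5) {
  abort_if(!inherits(pool, "hr_species_pool"), "pool must be a hr_species_pool")
  abort_if(!inherits(landscape, "hr_landscape"),
           "landscape must be a hr_landscape")
  abort_if(!inherits(truth, "hr_ground_truth"),
           "truth must be a hr_ground_truth")
  set.seed(derive_seed(truth$seed, 7L))

  plots <- landscape$plots
  n_sp <- nrow(pool)
  n_pl <- nrow(plots)
  area_ratio <- plots$sapling_area[1] / plots$tree_area[1]

  rel <- stats::rlnorm(n_sp, 0, sad_sdlog)
  rel <- rel / sum(rel)
  mu_adult <- rel * mean_trees_per_plot # per 0.25-ha plot

  z_hp <- zstd(plots$hp)
  z_cec <- zstd(plots$cec)
  z_vdnd <- zstd(plots$vdnd)

  is_endo <- pool$dispersal_mode == "endozoochory"
  z_sl_endo <- rep(0, n_sp)
  if (any(is_endo)) z_sl_endo[is_endo] <- zstd(pool$SL[is_endo])

  u_sp <- stats::rnorm(n_sp, 0, truth$sigma_species)
  fams <- unique(pool$family)
  u_fam <- stats::rnorm(length(fams), 0, truth$sigma_family)[match(pool$family, fams)]

  c0 <- mean_saplings_per_plot / (mean_trees_per_plot * area_ratio)
  beta_mode <- truth$beta_hp_by_mode[as.character(pool$dispersal_mode)]

  # species x plot matrices
  adult_counts <- matrix(stats::rnbinom(n_sp * n_pl, size = 1,
                                        mu = rep(mu_adult, n_pl)),
                         nrow = n_sp)
  eta <- log(mu_adult * area_ratio * c0) + u_sp + u_fam +
    outer(beta_mode, z_hp) +
    outer(ifelse(is_endo, truth$beta_hp_x_sl * z_sl_endo, 0), z_hp) +
    matrix(rep(truth$beta_cec * z_cec + truth$beta_vdnd * z_vdnd,
               each = n_sp), nrow = n_sp)
  sap_counts <- matrix(stats::rpois(n_sp * n_pl, lambda = exp(eta)),
                       nrow = n_sp)

  expand_stage <- function(counts, stage) {
    idx <- which(counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    n <- counts[idx]
    sp <- rep(idx[, 1], n)
    pl <- rep(idx[, 2], n)
    dbh <- if (stage == "adult") {
      10 + stats::rexp(length(sp), rate = 1 / 12)
    } else {
      stats::runif(length(sp), 1, 5)
    }
    data.frame(plot_id = plots$plot_id[pl], site_id = plots$site_id[pl],
               life_stage = stage, species_id = pool$species_id[sp],
               genus = pool$genus[sp], family = pool$family[sp],
               dbh_cm = dbh, stringsAsFactors = FALSE)
  }

  stems <- rbind(expand_stage(adult_counts, "adult"),
                 expand_stage(sap_counts, "sapling"))
  stems <- stems[order(stems$plot_id, stems$life_stage, stems$species_id), ]
  stems$stem_id <- sprintf("stem%06d", seq_len(nrow(stems)))
  rownames(stems) <- NULL
  stems <- stems[, c("stem_id", "plot_id", "site_id", "life_stage",
                     "species_id", "genus", "family", "dbh_cm")]
  attr(stems, "ground_truth") <- truth
  class(stems) <- c("hr_stem_table", "data.frame")
  stems
}

#' Write/read ground truth as a key-value text file
#'
#' @param truth a `hr_ground_truth`.
#' @param path file path.
#' @return `read_ground_truth` returns a `hr_ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  kv <- c(
    sprintf("beta_hp_%s = %.10g", names(truth$beta_hp_by_mode),
            truth$beta_hp_by_mode),
    sprintf("beta_hp_x_sl = %.10g", truth$beta_hp_x_sl),
    sprintf("beta_cec = %.10g", truth$beta_cec),
    sprintf("beta_vdnd = %.10g", truth$beta_vdnd),
    sprintf("sigma_species = %.10g", truth$sigma_species),
    sprintf("sigma_family = %.10g", truth$sigma_family),
    sprintf("seed = %d", truth$seed)
  )
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          col.names = c("key", "value"),
                          stringsAsFactors = FALSE)
  g <- function(k) as.numeric(kv$value[kv$key == k])
  ground_truth(
    beta_hp_by_mode = c(abiotic = g("beta_hp_abiotic"),
                        scatter_hoarded = g("beta_hp_scatter_hoarded"),
                        endozoochory = g("beta_hp_endozoochory")),
    beta_hp_x_sl = g("beta_hp_x_sl"), beta_cec = g("beta_cec"),
    beta_vdnd = g("beta_vdnd"), sigma_species = g("sigma_species"),
    sigma_family = g("sigma_family"), seed = as.integer(g("seed"))
  )
}
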