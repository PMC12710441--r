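#' Generate a synthetic species pool with guild-structured traits
#'
#' Draws a pool of tree species with dispersal modes, a genus/family taxonomy,
#' and correlated functional traits whose per-guild distributions reproduce the
#' qualitative structure observed in western Amazonian inventories:
#' scatter-hoarded species are the densest-wooded and have the highest leaf
#' mass per area; endozoochorous species have the smallest seeds; wood density,
#' seed length and LMA are positively inter-correlated within the
#' endozoochorous guild, while wood density and seed length are negatively
#' correlated among abiotically dispersed species.
#'
#' Traits are drawn through per-guild Gaussian copulas (correlation set by
#' `endo_rho` for the endozoochorous guild and `abiotic_rho_wd_sl` for the
#' abiotic WD-SL pair) with lognormal marginals for SL and LMA and a truncated
#' normal marginal for WD on (0.1, 1.2) g/cm3. Seed width and seed dry mass
#' are generated allometrically from seed length. A fraction of species per
#' trait (controlled by `obs_prob`) lacks a species-level measurement, so that
#' genus- and family-level imputation paths are exercised downstream.
#'
#' @param n_species number of species (>= 3).
#' @param mode_props named numeric of length 3 giving guild proportions for
#'   abiotic, scatter_hoarded and endozoochory; must be non-negative and sum
#'   to 1. Defaults are the species shares reported for the study flora
#'   (12.1/8.8/79.1 percent).
#' @param endo_rho pairwise copula correlation among SL, WD and LMA within the
#'   endozoochorous guild.
#' @param abiotic_rho_wd_sl copula correlation between WD and SL within the
#'   abiotic guild (negative by default).
#' @param obs_prob named numeric: probability that a species carries a
#'   species-level measurement for each trait.
#' @param species_per_genus,genera_per_family mean taxonomy granularity.
#' @param seed integer RNG seed or NULL.
#'
#' @return A data.frame of class `hr_species_pool` with columns `species_id`,
#'   `genus`, `family`, `dispersal_mode`, the five traits (true values, always
#'   present), and logical `has_<trait>` flags marking species-level
#'   observation. Generation parameters are stored in `attr(, "params")`.
#' @export
generate_species_pool <- function(n_species = 300,
                                  mode_props = c(abiotic = 0.121,
                                                 scatter_hoarded = 0.088,
                                                 endozoochory = 0.791),
                                  endo_rho = 0.3,
                                  abiotic_rho_wd_sl = -0.45,
                                  obs_prob = c(WD = 0.60, LMA = 0.75, SL = 0.80,
                                               SW = 0.55, SM = 0.55),
                                  species_per_genus = 3.2,
                                  genera_per_family = 4,
                                  seed = NULL) {
  abort_if(n_species < 3, "n_species must be >= 3")
  abort_if(length(mode_props) != 3 || is.null(names(mode_props)) ||
             !setequal(names(mode_props),
                       c("abiotic", "scatter_hoarded", "endozoochory")),
           "mode_props must be named with abiotic, scatter_hoarded, endozoochory")
  abort_if(any(mode_props < 0) || abs(sum(mode_props) - 1) > 1e-8,
           "mode_props must be non-negative and sum to 1")
  abort_if(abs(endo_rho) >= 1 || abs(abiotic_rho_wd_sl) >= 1,
           "copula correlations must lie in (-1, 1)")
  if (!is.null(seed)) set.seed(seed)

  mode_props <- mode_props[c("abiotic", "scatter_hoarded", "endozoochory")]
  mode <- sample(names(mode_props), n_species, replace = TRUE,
                 prob = mode_props)

  # Taxonomy: genera nested within families.
  n_gen <- max(1L, round(n_species / species_per_genus))
  n_fam <- max(1L, round(n_gen / genera_per_family))
  fam_of_gen <- sample.int(n_fam, n_gen, replace = TRUE)
  gen_idx <- sample.int(n_gen, n_species, replace = TRUE)
  genus <- sprintf("G%03d", gen_idx)
  family <- sprintf("F%02d", fam_of_gen[gen_idx])

  # Per-guild marginal parameters (WD truncated-normal mean/sd; LMA and SL
  # lognormal meanlog/sdlog). Orderings: WD scatter > endo ~ abiotic;
  # LMA scatter > endo > abiotic; SL scatter ~ abiotic > endo.
  wd_mu <- c(abiotic = 0.58, scatter_hoarded = 0.72, endozoochory = 0.60)
  wd_sd <- 0.12
  lma_mu <- log(c(abiotic = 0.0070, scatter_hoarded = 0.0115,
                  endozoochory = 0.0090))
  lma_sd <- 0.30
  sl_mu <- log(c(abiotic = 22, scatter_hoarded = 24, endozoochory = 12))
  sl_sd <- c(abiotic = 0.60, scatter_hoarded = 0.60, endozoochory = 0.80)

  qtrunc_norm <- function(p, mean, sd, lo = 0.1, hi = 1.2) {
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(plo + p * (phi - plo), mean, sd)
  }

  SL <- WD <- LMA <- numeric(n_species)
  for (m in names(mode_props)) {
    idx <- which(mode == m)
    if (length(idx) == 0) next
    R <- diag(3) # order: SL, WD, LMA
    if (m == "endozoochory") {
      R[upper.tri(R)] <- endo_rho
      R[lower.tri(R)] <- endo_rho
    } else if (m == "abiotic") {
      R[1, 2] <- R[2, 1] <- abiotic_rho_wd_sl
    }
    z <- MASS::mvrnorm(length(idx), mu = rep(0, 3), Sigma = R)
    z <- matrix(z, ncol = 3)
    u <- stats::pnorm(z)
    SL[idx] <- stats::qlnorm(u[, 1], sl_mu[m], sl_sd[m])
    WD[idx] <- qtrunc_norm(u[, 2], wd_mu[m], wd_sd)
    LMA[idx] <- stats::qlnorm(u[, 3], lma_mu[m], lma_sd)
  }

  # Allometric companions of seed length.
  SW <- 0.65 * SL * exp(stats::rnorm(n_species, 0, 0.25))
  SM <- 5e-4 * SL^2.8 * exp(stats::rnorm(n_species, 0, 0.5))

  has <- sapply(trait_names(), function(tr) {
    stats::runif(n_species) < obs_prob[[tr]]
  })

  pool <- data.frame(
    species_id = sprintf("sp%04d", seq_len(n_species)),
    genus = genus,
    family = family,
    dispersal_mode = factor(mode, levels = dispersal_modes()),
    SL = SL, SW = SW, SM = SM, WD = WD, LMA = LMA,
    stringsAsFactors = FALSE
  )
  for (tr in trait_names()) pool[[paste0("has_", tolower(tr))]] <- has[, tr]

  attr(pool, "params") <- list(mode_props = mode_props, endo_rho = endo_rho,
                               abiotic_rho_wd_sl = abiotic_rho_wd_sl,
                               obs_prob = obs_prob, seed = seed)
  class(pool) <- c("hr_species_pool", "data.frame")
  pool
}

#' Species-level trait table as observed (with missingness)
#'
#' Masks trait values for species lacking a species-level measurement, giving
#' the table that the imputation step consumes. True values remain in the pool.
#'
#' @param pool a `hr_species_pool`.
#' @return data.frame with species_id, genus, family, dispersal_mode and the
#'   five traits, NA where no species-level observation exists.
#' @export
observed_traits <- function(pool) {
  require_columns(pool, c("species_id", "genus", "family", "dispersal_mode"),
                  "species pool")
  out <- pool[, c("species_id", "genus", "family", "dispersal_mode")]
  for (tr in trait_names()) {
    v <- pool[[tr]]
    flag <- pool[[paste0("has_", tolower(tr))]]
    if (!is.null(flag)) v[!flag] <- NA_real_
    out[[tr]] <- v
  }
  out
}
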