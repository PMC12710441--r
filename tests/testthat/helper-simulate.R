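# Shared fixtures, built in code.

null_truth <- function(seed = 1L, sigma_species = 0.5, sigma_family = 0.2) {
  ground_truth(beta_hp_by_mode = c(abiotic = 0, scatter_hoarded = 0,
                                   endozoochory = 0),
               beta_hp_x_sl = 0, beta_cec = 0, beta_vdnd = 0,
               sigma_species = sigma_species, sigma_family = sigma_family,
               seed = seed)
}

# Reduced-scale study used by the simulation-calibration checks: 15 sites
# (30 plots) as in the field design, 100 species to keep a replicate ~1 s.
calib_study <- function(seed, truth) {
  simulate_study(n_sites = 15, n_species = 100, truth = truth, seed = seed)
}

# Default-scale study memoised across test files.
.default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(seed = 42)
    cache
  }
})

# Hand-built miniature stem table: counts[species, plot, stage] spelled out.
tiny_stems <- function(df) {
  rows <- df[rep(seq_len(nrow(df)), df$n), , drop = FALSE]
  rows$n <- NULL
  rows$stem_id <- sprintf("t%04d", seq_len(nrow(rows)))
  if (is.null(rows$genus)) rows$genus <- "G1"
  if (is.null(rows$family)) rows$family <- "F1"
  if (is.null(rows$site_id)) rows$site_id <- "S01"
  if (is.null(rows$dbh_cm)) {
    rows$dbh_cm <- ifelse(rows$life_stage == "adult", 20, 3)
  }
  rows
}

tiny_plots <- function(plot_ids = "P1", hp = 5, cec = 1, vdnd = 10) {
  data.frame(plot_id = plot_ids, site_id = plot_ids, hp = hp, cec = cec,
             vdnd = vdnd, tree_area = 0.25, sapling_area = 0.05,
             stringsAsFactors = FALSE)
}

# Simulate presence/absence data directly from the binomial GLMM the package
# fits (truth injected on the logit scale), for CI-coverage checks.
simulate_glmm_dataset <- function(seed, beta, sigma_species = 0.5,
                                  n_species = 100, n_sites = 15) {
  set.seed(seed)
  land <- generate_landscape(n_sites, seed = seed)
  plots <- land$plots
  species <- sprintf("sp%03d", seq_len(n_species))
  # order follows dispersal_modes(): abiotic, endozoochory, scatter_hoarded
  mode <- factor(sample(dispersal_modes(), n_species, replace = TRUE,
                        prob = c(0.121, 0.791, 0.088)),
                 levels = dispersal_modes())
  d <- expand.grid(species_id = species, plot_id = plots$plot_id,
                   stringsAsFactors = FALSE)
  d$dispersal_mode <- mode[match(d$species_id, species)]
  d$hp <- plots$hp[match(d$plot_id, plots$plot_id)]
  d$cec <- plots$cec[match(d$plot_id, plots$plot_id)]
  d$vdnd <- plots$vdnd[match(d$plot_id, plots$plot_id)]
  d$n_adults <- stats::rpois(nrow(d), 2) + 1L
  for (v in c("hp", "cec", "vdnd", "n_adults")) {
    d[[paste0("z_", v)]] <- as.vector(scale(d[[v]]))
  }
  X <- stats::model.matrix(~ z_hp * dispersal_mode + z_cec + z_vdnd +
                             z_n_adults, d)
  stopifnot(setequal(colnames(X), names(beta)))
  beta <- beta[colnames(X)]
  u <- stats::rnorm(n_species, 0, sigma_species)
  eta <- as.vector(X %*% beta) + u[match(d$species_id, species)]
  d$sapling_present <- stats::rbinom(nrow(d), 1, stats::plogis(eta))
  d$n_saplings <- d$sapling_present
  d$st_ratio <- NA_real_
  modes_tab <- data.frame(species_id = species, dispersal_mode = mode,
                          stringsAsFactors = FALSE)
  list(records = d[, c("species_id", "plot_id", "n_adults", "n_saplings",
                       "sapling_present", "st_ratio")],
       plots = plots, modes = modes_tab, beta = beta)
}

# Direct simulation of S:T-like records from the Gaussian LMM the package
# fits, with truth injected on the model's own scale.
simulate_endo_dataset <- function(seed, b_hp = 0, b_sl = 0, b_int = 0,
                                  sigma_species = 0.2, sigma_family = 0.1,
                                  sigma_resid = 0.3, n_species = 60,
                                  n_sites = 15) {
  set.seed(seed)
  land <- generate_landscape(n_sites, seed = seed)
  plots <- land$plots
  species <- sprintf("e%03d", seq_len(n_species))
  fam <- sprintf("F%02d", sample.int(max(2, n_species %/% 5), n_species,
                                     replace = TRUE))
  SL <- stats::rlnorm(n_species, log(12), 0.8)
  traits <- data.frame(species_id = species, family = fam,
                       dispersal_mode = "endozoochory", SL = SL,
                       stringsAsFactors = FALSE)
  d <- expand.grid(species_id = species, plot_id = plots$plot_id,
                   stringsAsFactors = FALSE)
  d <- d[sample.int(nrow(d), round(0.6 * nrow(d))), ] # unbalanced like real data
  z_hp <- as.vector(scale(plots$hp))[match(d$plot_id, plots$plot_id)]
  z_sl <- as.vector(scale(SL))[match(d$species_id, species)]
  u_s <- stats::rnorm(n_species, 0, sigma_species)
  u_f <- stats::rnorm(length(unique(fam)), 0, sigma_family)
  eta <- 0.5 + b_hp * z_hp + b_sl * z_sl + b_int * z_hp * z_sl +
    u_s[match(d$species_id, species)] +
    u_f[match(fam[match(d$species_id, species)], unique(fam))]
  d$st_ratio <- eta + stats::rnorm(nrow(d), 0, sigma_resid)
  d$n_adults <- stats::rpois(nrow(d), 2) + 1L
  d$n_saplings <- 1L
  d$sapling_present <- 1L
  list(records = d, plots = plots, traits = traits)
}
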