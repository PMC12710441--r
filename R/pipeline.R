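#' Simulate a complete synthetic study
#'
#' Bundles the three generators: a species pool, a landscape along the
#' hunting-pressure gradient, a stem inventory carrying the ground-truth
#' effect structure, and a pure-birth phylogeny over the pool. One master seed
#' drives everything; stage-level seeds are derived by fixed offsets so each
#' stage is independently reproducible.
#'
#' @param n_sites sites (2 plots each).
#' @param n_species species-pool size.
#' @param truth `hr_ground_truth`; its seed is overridden by `seed`.
#' @param hp_range plot-level HP range (persons/km).
#' @param mode_props guild proportions for the pool.
#' @param seed master seed.
#' @param ... further arguments to [generate_inventory()].
#' @return List of class `hr_study`: pool, landscape, stems, traits (observed
#'   species-level table), tree, truth.
#' @export
simulate_study <- function(n_sites = 15, n_species = 300,
                           truth = ground_truth(),
                           hp_range = c(2.4, 13.8),
                           mode_props = c(abiotic = 0.121,
                                          scatter_hoarded = 0.088,
                                          endozoochory = 0.791),
                           seed = 1L, ...) {
  truth$seed <- derive_seed(seed, 3L)
  pool <- generate_species_pool(n_species, mode_props = mode_props,
                                seed = derive_seed(seed, 1L))
  landscape <- generate_landscape(n_sites, hp_range = hp_range,
                                  seed = derive_seed(seed, 2L))
  stems <- generate_inventory(pool, landscape, truth, ...)
  tree <- pool_phylogeny(pool, seed = derive_seed(seed, 4L))
  structure(list(pool = pool, landscape = landscape, stems = stems,
                 traits = observed_traits(pool), tree = tree, truth = truth,
                 seed = seed),
            class = "hr_study")
}

#' Inventory summary
#'
#' Counts of stems by life stage, distinct species/genera/families, stem and
#' species shares by dispersal mode, and the per-trait provenance coverage
#' ledger.
#'
#' @param stems stem table.
#' @param traits species-level trait table with `dispersal_mode`.
#' @return List: `counts` (stage counts and taxon totals), `mode_shares`
#'   (per-mode stem shares by stage and species shares), `coverage` (per-trait
#'   stem fractions at each provenance level).
#' @export
summarize_inventory <- function(stems, traits) {
  if (nrow(stems) == 0) {
    return(list(counts = data.frame(n_trees = 0L, n_saplings = 0L,
                                    n_species = 0L, n_genera = 0L,
                                    n_families = 0L),
                mode_shares = NULL, coverage = NULL))
  }
  require_columns(stems, c("life_stage", "species_id", "genus", "family"),
                  "stem table")
  counts <- data.frame(
    n_trees = sum(stems$life_stage == "adult"),
    n_saplings = sum(stems$life_stage == "sapling"),
    n_species = length(unique(stems$species_id)),
    n_genera = length(unique(stems$genus)),
    n_families = length(unique(stems$family[!is.na(stems$family)]))
  )
  mode_of <- traits$dispersal_mode[match(stems$species_id, traits$species_id)]
  sp_mode <- traits$dispersal_mode[match(unique(stems$species_id),
                                         traits$species_id)]
  share <- function(modes) {
    tab <- table(factor(as.character(modes), levels = dispersal_modes()))
    as.numeric(tab) / max(1, sum(tab))
  }
  mode_shares <- data.frame(
    dispersal_mode = dispersal_modes(),
    tree_share = share(mode_of[stems$life_stage == "adult"]),
    sapling_share = share(mode_of[stems$life_stage == "sapling"]),
    species_share = share(sp_mode),
    stringsAsFactors = FALSE
  )
  cov <- lapply(trait_names(), function(tr) {
    impute_trait(stems, traits, tr)$coverage
  })
  names(cov) <- trait_names()
  list(counts = counts, mode_shares = mode_shares, coverage = cov)
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis on a simulated (or assembled) study: inventory
#' summary, recruitment table, trait imputation, the three mixed models with
#' Nakagawa R2 and marginal effects, CWM tables and linear models, trait
#' correlations and pairwise guild tests, and Pagel's lambda diagnostics on
#' the mixed-model residuals. All tables are written as CSV under `out_dir`
#' together with a run log recording the seed, a config hash, the package
#' version and row counts in and out of every filter. Partial outputs are
#' removed on error.
#'
#' If the study has no saplings at all, the presence/absence universe is still
#' built but the S:T and sapling-CWM stages are skipped with explicit log
#' lines.
#'
#' @param study `hr_study` from [simulate_study()], or a list with elements
#'   `stems`, `traits`, `landscape` (and optionally `tree`).
#' @param out_dir output directory (created; must not exist or be empty).
#' @param write_tables write CSV outputs (default TRUE); the function also
#'   returns everything invisibly.
#' @return (invisibly) list with all computed objects: summary, collinearity,
#'   recruitment, fits (glmm, st_lmm, endo_lmm, cwm per trait), cwm table,
#'   correlations, pairwise tests, seed-limitation count, lambda diagnostics,
#'   log lines.
#' @export
run_pipeline <- function(study, out_dir = NULL, write_tables = !is.null(out_dir)) {
  stems <- study$stems
  traits <- study$traits
  plots <- study$landscape$plots
  require_columns(plots, c("plot_id", "hp", "cec", "vdnd", "tree_area",
                           "sapling_area"), "plot table")
  require_columns(stems, c("stem_id", "plot_id", "life_stage", "species_id",
                           "genus", "family", "dbh_cm"), "stem table")
  require_columns(traits, c("species_id", "dispersal_mode"), "trait table")

  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  cfg <- list(seed = study$seed, n_plots = nrow(plots),
              n_species_pool = nrow(traits))
  cfg_file <- tempfile()
  dput(cfg, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  say("run: seed=%s config_hash=%s package=huntRecruit %s",
      deparse(study$seed), cfg_hash,
      as.character(utils::packageVersion("huntRecruit")))

  res <- list(log = NULL)
  say("inventory: %d stems across %d plots", nrow(stems), nrow(plots))
  res$summary <- summarize_inventory(stems, traits)
  res$collinearity <- collinearity_screen(plots[, c("hp", "cec", "vdnd")])
  say("collinearity screen: %d pair(s) with |r| > 0.7",
      nrow(res$collinearity$flags))

  res$recruitment <- build_recruitment_table(stems, plots)
  say("recruitment table: %d species x plot records (>=1 conspecific adult) from %d adult stems",
      nrow(res$recruitment), sum(stems$life_stage == "adult"))

  stems_tr <- attach_traits(stems, traits)
  res$coverage <- attr(stems_tr, "coverage")
  res$limited <- count_limited_species(traits)
  say("seed-size limitation: %d of %d classifiable endozoochorous species flagged",
      res$limited$n_limited, res$limited$n_endozoochorous)

  res$fits <- list()
  if (length(unique(res$recruitment$sapling_present)) > 1) {
    res$fits$glmm <- fit_recruitment_glmm(res$recruitment, plots, traits)
    say("recruitment GLMM: %d obs, converged=%s, R2m=%.3f R2c=%.3f",
        nrow(res$fits$glmm$data), res$fits$glmm$converged,
        res$fits$glmm$r2_marginal, res$fits$glmm$r2_conditional)
  } else {
    say("recruitment GLMM skipped: sapling presence is constant across the universe")
  }

  have_saplings <- any(stems$life_stage == "sapling")
  n_st <- sum(!is.na(res$recruitment$st_ratio))
  if (have_saplings && n_st >= 10) {
    res$fits$st_lmm <- fit_st_lmm(res$recruitment, plots, traits)
    say("S:T LMM: %d records with defined ratio", n_st)
    res$fits$endo_lmm <- fit_endozoochory_lmm(res$recruitment, plots, traits)
    say("endozoochory seed-size LMM: %d records",
        nrow(res$fits$endo_lmm$data))
  } else {
    say("S:T stage skipped: no saplings recorded (or < 10 defined ratios)")
  }

  res$cwm <- suppressWarnings(cwm_table(stems_tr))
  stages <- unique(res$cwm$life_stage)
  if (length(stages) == 2) {
    for (tr in c("WD", "LMA", "SL")) {
      res$fits[[paste0("cwm_", tolower(tr))]] <-
        fit_cwm_lm(res$cwm, tr, plots)
    }
    say("CWM linear models fitted for WD, LMA, SL")
  } else {
    say("CWM models skipped: only stage(s) %s present",
        paste(stages, collapse = ", "))
  }

  res$correlations_all <- trait_correlations(traits, grouping = "all")
  res$correlations_mode <- trait_correlations(traits, grouping = "mode")
  res$pairwise <- do.call(rbind, lapply(c("WD", "LMA", "SL"), function(tr) {
    cbind(trait = tr, pairwise_mode_tests(traits, tr))
  }))

  if (!is.null(study$tree)) {
    res$lambda <- lapply(res$fits[intersect(names(res$fits),
                                            c("glmm", "st_lmm", "endo_lmm"))],
                         function(f) {
                           estimate_lambda(species_residuals(f), study$tree)
                         })
    for (nm in names(res$lambda)) {
      say("Pagel's lambda (%s residuals): %.4f, p = %.4g", nm,
          res$lambda[[nm]]$lambda, res$lambda[[nm]]$p)
    }
  } else {
    say("phylogenetic-signal diagnostics skipped: no tree supplied")
  }

  res$marginal_effects <- if (!is.null(res$fits$glmm) &&
                                res$fits$glmm$converged) {
    marginal_effects(res$fits$glmm,
                     hp = seq(min(plots$hp), max(plots$hp), length.out = 25))
  }
  res$log <- log_lines

  if (write_tables) {
    abort_if(is.null(out_dir), "out_dir required when write_tables = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    on_fail <- function(e) {
      unlink(written)
      stop(e)
    }
    tryCatch({
      wr <- function(obj, name) {
        path <- file.path(out_dir, paste0(name, ".csv"))
        utils::write.csv(obj, path, row.names = FALSE)
        written <<- c(written, path)
      }
      wr(res$summary$counts, "inventory_counts")
      wr(res$summary$mode_shares, "mode_shares")
      cov_tab <- do.call(rbind, lapply(names(res$coverage), function(tr) {
        data.frame(trait = tr, provenance = names(res$coverage[[tr]]),
                   fraction = as.numeric(res$coverage[[tr]]))
      }))
      wr(cov_tab, "trait_coverage")
      wr(as.data.frame(res$recruitment), "recruitment_table")
      wr(res$cwm, "cwm_table")
      for (nm in names(res$fits)) {
        wr(cbind(model = nm, res$fits[[nm]]$coefficients),
           paste0("coefficients_", nm))
      }
      wr(res$correlations_all, "trait_correlations_all")
      wr(res$correlations_mode, "trait_correlations_by_mode")
      wr(res$pairwise, "pairwise_mode_tests")
      if (!is.null(res$marginal_effects)) {
        wr(res$marginal_effects, "marginal_effects_glmm")
      }
      if (!is.null(res$lambda)) {
        lam <- do.call(rbind, lapply(names(res$lambda), function(nm) {
          l <- res$lambda[[nm]]
          data.frame(model = nm, lambda = l$lambda, loglik = l$loglik_at_hat,
                     loglik0 = l$loglik_at_zero, p = l$p, n = l$n)
        }))
        wr(lam, "lambda_diagnostics")
      }
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    }, error = on_fail)
  }
  invisible(res)
}
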