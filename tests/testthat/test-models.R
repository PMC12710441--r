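test_that("collinearity screen flags |r| > 0.7 and handles degenerate columns", {
  set.seed(1)
  x <- rnorm(50)
  covs <- data.frame(a = x, b = x, c = -x, d = rnorm(50), e = rep(1, 50))
  out <- collinearity_screen(covs)
  expect_equal(out$r["a", "b"], 1)
  expect_equal(out$r["a", "c"], -1)
  expect_true(any(out$flags$var1 == "a" & out$flags$var2 == "b"))
  expect_true(all(is.na(out$r["e", ])))
  expect_false("e" %in% c(out$flags$var1, out$flags$var2))
  # independent covariates at large n stay unflagged
  big <- as.data.frame(matrix(rnorm(3 * 1e4), ncol = 3))
  out2 <- collinearity_screen(big)
  expect_equal(nrow(out2$flags), 0)
  expect_lt(max(abs(out2$r[upper.tri(out2$r)])), 0.05)
})

test_that("GLMM collapses to the GLM when the random variance vanishes", {
  beta <- c("(Intercept)" = 0.3, "z_hp" = 0.2,
            "dispersal_modeendozoochory" = -0.2,
            "dispersal_modescatter_hoarded" = 0.1,
            "z_cec" = 0, "z_vdnd" = 0.2, "z_n_adults" = 0.3,
            "z_hp:dispersal_modeendozoochory" = -0.3,
            "z_hp:dispersal_modescatter_hoarded" = 0)
  sim <- simulate_glmm_dataset(56, beta, sigma_species = 0)
  fit <- suppressWarnings(fit_recruitment_glmm(sim$records, sim$plots,
                                               sim$modes))
  expect_true(fit$converged)
  expect_lt(fit$varcomps[["species_id"]], 1e-3)
  glm_fit <- glm(sapling_present ~ z_hp * dispersal_mode + z_cec + z_vdnd +
                   z_n_adults, data = fit$data, family = binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(glm_fit)),
               tolerance = 1e-4)
})

test_that("a single species yields the boundary fit with zero random variance", {
  set.seed(41)
  rec <- data.frame(species_id = "s1",
                    plot_id = tiny_plots(sprintf("P%02d", 1:20),
                                         hp = seq(2, 14, length.out = 20),
                                         cec = runif(20), vdnd = runif(20, 0, 30))$plot_id,
                    n_adults = rpois(20, 3) + 1L,
                    n_saplings = rbinom(20, 1, 0.5), stringsAsFactors = FALSE)
  rec$sapling_present <- as.integer(rec$n_saplings >= 1)
  rec$st_ratio <- NA_real_
  plots <- tiny_plots(sprintf("P%02d", 1:20), hp = seq(2, 14, length.out = 20),
                      cec = runif(20), vdnd = runif(20, 0, 30))
  modes <- data.frame(species_id = "s1", dispersal_mode = "endozoochory")
  expect_warning(
    expect_warning(fit <- fit_recruitment_glmm(rec, plots, modes),
                   "single dispersal mode"),
    "single species")
  expect_true(fit$converged)
  expect_equal(fit$varcomps[["species_id"]], 0)
  expect_null(fit$interaction_test)
})

test_that("REML variance components match closed-form balanced one-way ANOVA", {
  set.seed(31)
  k <- 12; m <- 8 # groups x replicates
  g <- factor(rep(seq_len(k), each = m))
  sig_a <- 0.7; sig_e <- 0.4
  y <- rep(rnorm(k, 0, sig_a), each = m) + rnorm(k * m, 0, sig_e)
  fit <- lmerTest::lmer(y ~ 1 + (1 | g), REML = TRUE)
  msa <- anova(lm(y ~ g))["g", "Mean Sq"]
  mse <- anova(lm(y ~ g))["Residuals", "Mean Sq"]
  expect_equal(unname(huntRecruit:::varcomp_table(fit)), (msa - mse) / m,
               tolerance = 1e-6)
  expect_equal(sigma(fit)^2, mse, tolerance = 1e-6)
})

test_that("shifting the S:T response by a constant moves only the intercept", {
  study <- .default_study()
  rec <- build_recruitment_table(study$stems, study$landscape$plots)
  f1 <- suppressWarnings(fit_st_lmm(rec, study$landscape$plots, study$traits))
  rec2 <- rec
  rec2$st_ratio <- rec2$st_ratio + 0.8
  f2 <- suppressWarnings(fit_st_lmm(rec2, study$landscape$plots, study$traits))
  b1 <- f1$coefficients$estimate
  b2 <- f2$coefficients$estimate
  expect_equal(b2[1] - b1[1], 0.8, tolerance = 1e-6)
  expect_equal(b2[-1], b1[-1], tolerance = 1e-6)
})

test_that("interaction p-values are approximately uniform under the null", {
  p <- vapply(1:200, function(s) {
    sim <- simulate_endo_dataset(s)
    modes <- data.frame(species_id = sim$traits$species_id,
                        dispersal_mode = sample(dispersal_modes(),
                                                nrow(sim$traits),
                                                replace = TRUE),
                        stringsAsFactors = FALSE)
    fit <- suppressWarnings(fit_st_lmm(sim$records, sim$plots, modes))
    fit$interaction_test$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("seed-size model recovers the sign flip across seed-length classes", {
  sim <- simulate_endo_dataset(5, b_hp = 0.1, b_int = -0.3)
  fit <- fit_endozoochory_lmm(sim$records, sim$plots, sim$traits)
  expect_true(fit$converged)
  sl <- hp_slope_at_sl(fit, c(1, 18, 50))
  expect_gt(sl$slope[sl$sl_mm == 1], 0)
  expect_lt(sl$slope[sl$sl_mm == 50], 0)
})

test_that("without interaction the HP slope is seed-length invariant", {
  sim <- simulate_endo_dataset(6, b_hp = -0.2, b_int = 0)
  fit <- fit_endozoochory_lmm(sim$records, sim$plots, sim$traits)
  sl <- hp_slope_at_sl(fit, c(1, 50))
  b_int <- fit$coefficients[fit$coefficients$term == "z_hp:z_sl", ]
  # slope difference is b_int * dz; consistent with zero interaction
  expect_lt(abs(sl$slope[1] - sl$slope[2]),
            3 * b_int$se * abs(diff((c(1, 50) - fit$scaling$sl["mean"]) /
                                      fit$scaling$sl["sd"])))
})

test_that("a single plant family degrades the nesting with a warning", {
  sim <- simulate_endo_dataset(7)
  sim$traits$family <- "F01"
  expect_warning(fit <- fit_endozoochory_lmm(sim$records, sim$plots,
                                             sim$traits),
                 "single family")
  expect_true("species_id" %in% names(fit$varcomps))
  expect_false("family" %in% names(fit$varcomps))
})

test_that("Nakagawa R2 closed forms and ordering invariants hold", {
  expect_error(nakagawa_r2(0, 0, 0), "positive")
  r2 <- nakagawa_r2(2, 0, 1) # no random variance: marginal = conditional
  expect_equal(unname(r2["r2_marginal"]), unname(r2["r2_conditional"]))
  expect_equal(unname(nakagawa_r2(0, 1, pi^2 / 3)["r2_marginal"]), 0)
  study <- .default_study()
  rec <- build_recruitment_table(study$stems, study$landscape$plots)
  fit <- suppressWarnings(fit_recruitment_glmm(rec, study$landscape$plots,
                                               study$traits))
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_lte(fit$r2_conditional, 1)
  expect_gte(fit$r2_marginal, 0)
})

test_that("marginal effects respect link, bounds and extrapolation flags", {
  study <- .default_study()
  rec <- build_recruitment_table(study$stems, study$landscape$plots)
  fit <- suppressWarnings(fit_recruitment_glmm(rec, study$landscape$plots,
                                               study$traits))
  hp <- range(study$landscape$plots$hp)
  me <- marginal_effects(fit, hp = c(hp[1], mean(hp), hp[2] + 5))
  expect_true(all(me$predicted >= 0 & me$predicted <= 1))
  expect_true(all(me$lwr <= me$predicted & me$predicted <= me$upr))
  expect_equal(unique(me$extrapolated[me$hp == hp[2] + 5]), TRUE)
  expect_equal(unique(me$extrapolated[me$hp == hp[1]]), FALSE)
})

test_that("linear-model marginal effects reproduce the coefficients", {
  study <- .default_study()
  stems_tr <- attach_traits(study$stems, study$traits)
  tab <- suppressWarnings(cwm_table(stems_tr))
  fit <- fit_cwm_lm(tab, "WD", study$landscape$plots)
  sc <- fit$scaling$hp
  me <- marginal_effects(fit, hp = sc["mean"] + sc["sd"] * c(0, 1))
  b <- coef(fit$model)
  ad <- me[me$life_stage == "adult", ]
  expect_equal(ad$predicted[2] - ad$predicted[1], unname(b["z_hp"]),
               tolerance = 1e-10)
  sa <- me[me$life_stage == "sapling", ]
  expect_equal(sa$predicted[2] - sa$predicted[1],
               unname(b["z_hp"] + b["z_hp:life_stagesapling"]),
               tolerance = 1e-10)
})

test_that("identical adult and sapling CWM tables zero the stage effect", {
  study <- .default_study()
  plots <- study$landscape$plots
  tab <- data.frame(plot_id = rep(plots$plot_id, 2),
                    life_stage = rep(c("adult", "sapling"),
                                     each = nrow(plots)),
                    trait = "WD",
                    cwm = rep(0.5 + 0.01 * seq_len(nrow(plots)), 2),
                    total_ba = 1, n_stems_used = 10,
                    stringsAsFactors = FALSE)
  fit <- fit_cwm_lm(tab, "WD", plots)
  b <- fit$coefficients
  expect_equal(b$estimate[b$term == "life_stagesapling"], 0,
               tolerance = 1e-12)
  expect_equal(b$estimate[b$term == "z_hp:life_stagesapling"], 0,
               tolerance = 1e-12)
})

test_that("an injected stage offset is recovered by the CWM model", {
  set.seed(9)
  plots <- generate_landscape(15, seed = 9)$plots
  delta <- 0.07
  base <- 0.55 + 0.02 * rnorm(nrow(plots))
  tab <- data.frame(plot_id = rep(plots$plot_id, 2),
                    life_stage = rep(c("adult", "sapling"),
                                     each = nrow(plots)),
                    trait = "WD",
                    cwm = c(base, base - delta + rnorm(nrow(plots), 0, 0.005)),
                    total_ba = 1, n_stems_used = 10,
                    stringsAsFactors = FALSE)
  fit <- fit_cwm_lm(tab, "WD", plots)
  b <- fit$coefficients
  expect_equal(b$estimate[b$term == "life_stagesapling"], -delta,
               tolerance = 0.01)
})

test_that("trait correlations: exact, null and degenerate cases", {
  d <- data.frame(WD = 1:10, LMA = 2 * (1:10) + 3, SL = rnorm(10))
  out <- trait_correlations(d, which = c("WD", "LMA"))
  expect_equal(out$r, 1)
  set.seed(10)
  big <- data.frame(WD = rnorm(1e4), LMA = rnorm(1e4), SL = rnorm(1e4))
  out2 <- trait_correlations(big)
  expect_lt(max(abs(out2$r)), 0.05)
  small <- data.frame(WD = c(1, 2, NA), LMA = c(NA, 1, 2), SL = 1:3)
  expect_warning(out3 <- trait_correlations(small, which = c("WD", "LMA")),
                 "fewer than 3")
  expect_true(is.na(out3$r))
})

test_that("significance stars are a pure function of p with exact boundaries", {
  expect_equal(p_stars(c(0.03, 5e-4, 0.2, 0.05, 1e-4, 1e-5, NA)),
               c("*", "***", "n.s.", "*", "****", "****", "n.s."))
})

test_that("pairwise Welch tests detect separation and handle identical groups", {
  set.seed(12)
  d <- data.frame(
    dispersal_mode = rep(c("abiotic", "endozoochory", "scatter_hoarded"),
                         each = 200),
    WD = c(rnorm(200, 0.5, 0.1), rnorm(200, 0.5, 0.1), rnorm(200, 0.8, 0.1)))
  out <- pairwise_mode_tests(d, "WD")
  expect_equal(nrow(out), 3)
  sc <- out$mode1 == "abiotic" & out$mode2 == "scatter_hoarded"
  expect_equal(out$stars[sc], "****") # 3-SD gap at n = 200
  ident <- data.frame(dispersal_mode = rep(c("abiotic", "endozoochory"), 3),
                      WD = rep(0.6, 6))
  out2 <- pairwise_mode_tests(ident, "WD")
  expect_equal(out2$stars, "n.s.")
})
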