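#' Collinearity screen on plot-level covariates
#'
#' Pairwise Pearson correlations among plot covariates; any |r| > 0.7 is
#' flagged as high multicollinearity. Constant covariates have undefined
#' correlations, reported as NA and never flagged.
#'
#' @param covariates data.frame of numeric plot-level covariates (>= 2
#'   columns, >= 3 rows).
#' @return List with `r` (correlation matrix) and `flags` (data.frame of
#'   flagged pairs: var1, var2, r).
#' @export
collinearity_screen <- function(covariates) {
  covariates <- as.data.frame(covariates)
  num <- vapply(covariates, is.numeric, logical(1))
  covariates <- covariates[, num, drop = FALSE]
  abort_if(ncol(covariates) < 2, "need at least 2 numeric covariates")
  abort_if(nrow(covariates) < 3, "need at least 3 plots")
  constant <- vapply(covariates, function(x) stats::sd(x, na.rm = TRUE) == 0,
                     logical(1))
  r <- suppressWarnings(stats::cor(covariates, use = "pairwise.complete.obs"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  diag(r)[constant] <- NA_real_
  pairs <- which(upper.tri(r) & !is.na(r) & abs(r) > 0.7, arr.ind = TRUE)
  flags <- data.frame(var1 = rownames(r)[pairs[, 1]],
                      var2 = colnames(r)[pairs[, 2]],
                      r = r[pairs], stringsAsFactors = FALSE)
  list(r = r, flags = flags)
}

# ---- internal fit plumbing ---------------------------------------------------

# Merge recruitment records with plot covariates and species dispersal modes,
# and add standardised predictor columns. Scaling constants are returned so
# that marginal-effect grids can be expressed on the raw scale.
prepare_recruitment_data <- function(records, plots, species_modes,
                                     standardize = TRUE) {
  require_columns(records, c("species_id", "plot_id", "n_adults",
                             "sapling_present"), "recruitment table")
  require_columns(plots, c("plot_id", "hp", "cec", "vdnd"), "plot table")
  require_columns(species_modes, c("species_id", "dispersal_mode"),
                  "species mode table")
  d <- merge(records, plots[, c("plot_id", "hp", "cec", "vdnd")],
             by = "plot_id")
  d <- merge(d, species_modes[!duplicated(species_modes$species_id),
                              c("species_id", "dispersal_mode",
                                intersect("SL", names(species_modes)))],
             by = "species_id")
  d$dispersal_mode <- factor(as.character(d$dispersal_mode),
                             levels = dispersal_modes())
  d$dispersal_mode <- droplevels(d$dispersal_mode)
  scaling <- list()
  for (v in c("hp", "cec", "vdnd", "n_adults")) {
    if (standardize) {
      scaling[[v]] <- c(mean = mean(d[[v]]), sd = stats::sd(d[[v]]))
      d[[paste0("z_", v)]] <- zstd(d[[v]])
    } else {
      scaling[[v]] <- c(mean = 0, sd = 1)
      d[[paste0("z_", v)]] <- d[[v]]
    }
  }
  attr(d, "scaling") <- scaling
  d
}

# Unified coefficient table from a merMod / lmerModLmerTest / lm fit.
coef_table <- function(model) {
  sm <- stats::coef(summary(model))
  out <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"], stringsAsFactors = FALSE)
  statcol <- intersect(c("z value", "t value"), colnames(sm))[1]
  pcol <- intersect(c("Pr(>|z|)", "Pr(>|t|)"), colnames(sm))
  out$statistic <- sm[, statcol]
  out$df <- if ("df" %in% colnames(sm)) sm[, "df"] else NA_real_
  out$p <- if (length(pcol)) sm[, pcol[1]] else NA_real_
  rownames(out) <- NULL
  out
}

# Random-effect variance components (intercepts) of a merMod, named by group.
varcomp_table <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  vc <- vc[is.na(vc$var2) & vc$grp != "Residual", , drop = FALSE]
  stats::setNames(vc$vcov, vc$grp)
}

merMod_converged <- function(model) {
  msgs <- model@optinfo$conv$lme4$messages
  # A singular (boundary) fit is a converged fit with a variance at 0.
  msgs <- msgs[!grepl("boundary|singular", msgs, ignore.case = TRUE)]
  code <- model@optinfo$conv$opt
  length(msgs) == 0 && (is.null(code) || code == 0)
}

# Joint Wald chi-square test of the fixed-effect terms whose names match all
# supplied patterns (used for the HP x mode interaction).
wald_joint_test <- function(model, patterns = c("z_hp", ":")) {
  b <- if (inherits(model, "merMod")) lme4::fixef(model) else stats::coef(model)
  keep <- Reduce(`&`, lapply(patterns, function(p) grepl(p, names(b), fixed = TRUE)))
  abort_if(!any(keep), "no fixed-effect terms match the interaction pattern")
  V <- as.matrix(stats::vcov(model))[keep, keep, drop = FALSE]
  bb <- b[keep]
  stat <- as.numeric(t(bb) %*% solve(V, bb))
  df <- sum(keep)
  list(chisq = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE),
       terms = names(b)[keep])
}

# Assemble the shared FitResult structure.
make_fit <- function(model, family, data, scaling, converged,
                     extra = list()) {
  is_mer <- inherits(model, "merMod")
  vc <- if (is_mer) varcomp_table(model) else numeric(0)
  sigma_resid <- if (family == "gaussian") stats::sigma(model)^2 else NA_real_
  # Marginal (fixed-effects-only) residuals on the response scale.
  X <- if (is_mer) lme4::getME(model, "X") else stats::model.matrix(model)
  b <- if (is_mer) lme4::fixef(model) else stats::coef(model)
  eta_fixed <- as.vector(X %*% b)
  y <- if (is_mer) lme4::getME(model, "y") else stats::model.response(stats::model.frame(model))
  mu <- if (family == "binomial") stats::plogis(eta_fixed) else eta_fixed
  fit <- structure(c(list(
    model = model, family = family,
    engine = class(model)[1],
    coefficients = coef_table(model),
    varcomps = vc, sigma_resid = sigma_resid,
    loglik = as.numeric(stats::logLik(model)),
    residuals_marginal = y - mu,
    eta_fixed = eta_fixed,
    species_id = if ("species_id" %in% names(data)) data$species_id else NULL,
    data = data, scaling = scaling, converged = converged
  ), extra), class = "hr_fit")
  r2 <- try(nakagawa_r2(fit), silent = TRUE)
  if (!inherits(r2, "try-error")) {
    fit$r2_marginal <- r2[["r2_marginal"]]
    fit$r2_conditional <- r2[["r2_conditional"]]
  }
  fit
}

#' @export
print.hr_fit <- function(x, ...) {
  cat(sprintf("<hr_fit> %s (%s), converged: %s\n", x$engine, x$family,
              x$converged))
  print(x$coefficients, digits = 3)
  if (length(x$varcomps)) {
    cat("Random-effect variances:\n")
    print(x$varcomps, digits = 3)
  }
  if (!is.null(x$r2_marginal)) {
    cat(sprintf("R2 marginal = %.3f, conditional = %.3f\n",
                x$r2_marginal, x$r2_conditional))
  }
  invisible(x)
}

# ---- model suite -------------------------------------------------------------

#' Binomial GLMM for sapling recruitment probability
#'
#' Fits, by maximum likelihood with the Laplace approximation, the
#' presence/absence model: logit P(at least one conspecific sapling | >= 1
#' conspecific adult) ~ HP x dispersal mode + CEC + VDND + number of
#' conspecific adults, with a species random intercept. Continuous predictors
#' are standardised by default. The first fit uses the bobyqa optimizer; on
#' non-convergence it is refit once with lme4's default optimizer and more
#' iterations, and persistent failure is surfaced through
#' `converged = FALSE`, never silently.
#'
#' @param records recruitment table from [build_recruitment_table()].
#' @param plots plot table with `plot_id`, `hp`, `cec`, `vdnd`.
#' @param species_modes table with `species_id`, `dispersal_mode`.
#' @param standardize centre/scale continuous predictors (default TRUE).
#' @return `hr_fit` with coefficient table, species random-intercept variance,
#'   Nakagawa R2, derived mode-specific HP slopes ([mode_hp_slopes()]) and the
#'   joint Wald test of the HP x mode interaction in `$interaction_test`.
#' @export
fit_recruitment_glmm <- function(records, plots, species_modes,
                                 standardize = TRUE) {
  d <- prepare_recruitment_data(records, plots, species_modes, standardize)
  one_mode <- nlevels(d$dispersal_mode) < 2
  one_species <- length(unique(d$species_id)) < 2
  if (one_mode) {
    warning("single dispersal mode present; HP x mode interaction dropped")
  }
  rhs <- if (one_mode) "z_hp" else "z_hp * dispersal_mode"
  fixed <- sprintf("sapling_present ~ %s + z_cec + z_vdnd + z_n_adults", rhs)
  if (one_species) {
    # A single grouping level carries no information on the random variance;
    # the boundary fit (variance 0) is the fixed-effects GLM.
    warning("single species present; random variance fixed at the 0 boundary (GLM fit)")
    model <- stats::glm(stats::as.formula(fixed), data = d,
                        family = stats::binomial())
    fit <- make_fit(model, "binomial", d, attr(d, "scaling"), TRUE)
    fit$varcomps <- c(species_id = 0)
  } else {
    form <- stats::as.formula(paste(fixed, "+ (1 | species_id)"))
    model <- suppressMessages(lme4::glmer(
      form, data = d, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa")))
    converged <- merMod_converged(model)
    if (!converged) {
      model2 <- suppressMessages(lme4::glmer(
        form, data = d, family = stats::binomial(),
        control = lme4::glmerControl(optCtrl = list(maxfun = 1e5))))
      if (merMod_converged(model2)) {
        model <- model2
        converged <- TRUE
      }
    }
    fit <- make_fit(model, "binomial", d, attr(d, "scaling"), converged)
  }
  fit$interaction_test <- if (!one_mode) wald_joint_test(fit$model) else NULL
  fit$mode_slopes <- mode_hp_slopes(fit)
  fit
}

#' Gaussian LMM for sapling-to-tree abundance ratios
#'
#' Same fixed and random structure as the recruitment GLMM, with the S:T
#' log-ratio as response, restricted to records where it is defined. Fit by
#' REML; p-values use Satterthwaite degrees of freedom.
#'
#' @inheritParams fit_recruitment_glmm
#' @return `hr_fit` (see [fit_recruitment_glmm()]).
#' @export
fit_st_lmm <- function(records, plots, species_modes, standardize = TRUE) {
  records <- records[!is.na(records$st_ratio), , drop = FALSE]
  abort_if(nrow(records) < 10, "too few records with a defined S:T ratio")
  d <- prepare_recruitment_data(records, plots, species_modes, standardize)
  one_mode <- nlevels(d$dispersal_mode) < 2
  if (one_mode) {
    warning("single dispersal mode present; HP x mode interaction dropped")
  }
  rhs <- if (one_mode) "z_hp" else "z_hp * dispersal_mode"
  form <- stats::as.formula(sprintf(
    "st_ratio ~ %s + z_cec + z_vdnd + z_n_adults + (1 | species_id)", rhs))
  model <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  converged <- merMod_converged(model)
  fit <- make_fit(model, "gaussian", d, attr(d, "scaling"), converged)
  fit$interaction_test <- if (!one_mode) wald_joint_test(model) else NULL
  fit$mode_slopes <- mode_hp_slopes(fit)
  fit
}

#' Seed-size LMM for endozoochorous species
#'
#' Gaussian LMM of the S:T ratio for endozoochorous species only, with fixed
#' effects HP x seed length (SL standardised over the distinct endozoochorous
#' species entering the model) plus additive CEC and VDND, and nested random
#' intercepts of species within family. With a single family the nesting
#' degenerates to a species-only intercept, with a warning.
#'
#' @param records recruitment table.
#' @param plots plot table.
#' @param traits species table with `species_id`, `family`, `dispersal_mode`,
#'   `SL` (mm); endozoochorous species lacking a seed length are excluded.
#' @param standardize centre/scale continuous predictors.
#' @return `hr_fit`; marginal HP slopes at given seed lengths via
#'   [hp_slope_at_sl()].
#' @export
fit_endozoochory_lmm <- function(records, plots, traits, standardize = TRUE) {
  require_columns(traits, c("species_id", "family", "dispersal_mode", "SL"),
                  "trait table")
  endo <- traits[traits$dispersal_mode == "endozoochory" &
                   !is.na(traits$SL), , drop = FALSE]
  records <- records[records$species_id %in% endo$species_id &
                       !is.na(records$st_ratio), , drop = FALSE]
  abort_if(nrow(records) < 10,
           "too few endozoochorous records with S:T and seed length")
  d <- prepare_recruitment_data(records, plots, endo, standardize)
  d$family <- endo$family[match(d$species_id, endo$species_id)]
  d$SL <- endo$SL[match(d$species_id, endo$species_id)]
  abort_if(any(is.na(d$SL)), "SL must be present for all included species")
  sp <- d[!duplicated(d$species_id), c("species_id", "SL")]
  sl_scale <- c(mean = mean(sp$SL), sd = stats::sd(sp$SL))
  d$z_sl <- (d$SL - sl_scale["mean"]) / sl_scale["sd"]
  scaling <- attr(d, "scaling")
  scaling$sl <- sl_scale

  single_family <- length(unique(d$family)) < 2
  form <- if (single_family) {
    warning("single family present; nested random effect degenerates to species only")
    st_ratio ~ z_hp * z_sl + z_cec + z_vdnd + (1 | species_id)
  } else {
    st_ratio ~ z_hp * z_sl + z_cec + z_vdnd + (1 | family / species_id)
  }
  model <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  fit <- make_fit(model, "gaussian", d, scaling, merMod_converged(model))
  fit$interaction_test <- wald_joint_test(model, c("z_hp", ":"))
  fit
}

#' Marginal HP slope at a given seed length
#'
#' For the endozoochory seed-size model: the slope of the response in
#' standardised-HP units evaluated at seed length `sl_mm`,
#' i.e. beta_zhp + beta_interaction * z(SL), with a delta-method SE.
#'
#' @param fit `hr_fit` from [fit_endozoochory_lmm()].
#' @param sl_mm seed lengths (mm) at which to evaluate.
#' @return data.frame: sl_mm, slope, se.
#' @export
hp_slope_at_sl <- function(fit, sl_mm = c(1, 18, 50)) {
  z <- (sl_mm - fit$scaling$sl["mean"]) / fit$scaling$sl["sd"]
  b <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  i1 <- which(names(b) == "z_hp")
  i2 <- grep("z_hp:z_sl|z_sl:z_hp", names(b))
  abort_if(length(i1) != 1 || length(i2) != 1, "fit lacks z_hp and interaction terms")
  slope <- b[i1] + b[i2] * z
  se <- sqrt(V[i1, i1] + z^2 * V[i2, i2] + 2 * z * V[i1, i2])
  data.frame(sl_mm = sl_mm, slope = as.numeric(slope), se = as.numeric(se))
}

#' Derived mode-specific HP slopes
#'
#' Reconstructs the HP slope (standardised scale) for each dispersal mode from
#' the treatment-coded interaction fit, with delta-method SEs, so the choice of
#' reference level is immaterial.
#'
#' @param fit `hr_fit` from [fit_recruitment_glmm()] or [fit_st_lmm()].
#' @return data.frame: dispersal_mode, slope, se.
#' @export
mode_hp_slopes <- function(fit) {
  b <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model) else
    stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  modes <- levels(fit$data$dispersal_mode)
  out <- lapply(modes, function(m) {
    L <- stats::setNames(rep(0, length(b)), names(b))
    L["z_hp"] <- 1
    inter <- paste0("z_hp:dispersal_mode", m)
    if (inter %in% names(b)) L[inter] <- 1
    data.frame(dispersal_mode = m, slope = sum(L * b),
               se = sqrt(as.numeric(t(L) %*% V %*% L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Linear model for community-weighted mean traits
#'
#' Ordinary least squares of the CWM of one trait on the HP x life stage
#' interaction plus additive VDND and CEC (one model per trait).
#'
#' @param cwm_tab output of [cwm_table()] (both life stages present).
#' @param trait which trait's CWMs to model.
#' @param plots plot table with `hp`, `cec`, `vdnd`.
#' @param standardize centre/scale continuous predictors.
#' @return `hr_fit` (engine lm; `r2_marginal` is the OLS R2).
#' @export
fit_cwm_lm <- function(cwm_tab, trait, plots, standardize = TRUE) {
  d <- cwm_tab[cwm_tab$trait == trait, , drop = FALSE]
  abort_if(length(unique(d$life_stage)) < 2,
           "both life stages must be present")
  d <- merge(d, plots[, c("plot_id", "hp", "cec", "vdnd")], by = "plot_id")
  d$life_stage <- factor(d$life_stage, levels = c("adult", "sapling"))
  scaling <- list()
  for (v in c("hp", "cec", "vdnd")) {
    if (standardize) {
      scaling[[v]] <- c(mean = mean(d[[v]]), sd = stats::sd(d[[v]]))
      d[[paste0("z_", v)]] <- zstd(d[[v]])
    } else {
      scaling[[v]] <- c(mean = 0, sd = 1)
      d[[paste0("z_", v)]] <- d[[v]]
    }
  }
  model <- stats::lm(cwm ~ z_hp * life_stage + z_vdnd + z_cec, data = d)
  fit <- make_fit(model, "gaussian", d, scaling, TRUE)
  fit$r2_marginal <- summary(model)$r.squared
  fit$r2_conditional <- fit$r2_marginal
  fit
}

#' Nakagawa marginal and conditional R-squared
#'
#' For mixed models: \eqn{R^2_m = \sigma^2_f / (\sigma^2_f + \Sigma\sigma^2_r
#' + \sigma^2_e)} and \eqn{R^2_c = (\sigma^2_f + \Sigma\sigma^2_r) /
#' (\sigma^2_f + \Sigma\sigma^2_r + \sigma^2_e)}, where \eqn{\sigma^2_f} is
#' the variance of the fixed-effect linear predictor, \eqn{\sigma^2_r} the
#' random-intercept variances, and \eqn{\sigma^2_e} the residual variance --
#' the logit-link distribution-specific variance \eqn{\pi^2/3} for binomial
#' models.
#'
#' @param x a `hr_fit`, or (default method) the fixed-effect variance.
#' @param ... passed on.
#' @return Named numeric: r2_marginal, r2_conditional.
#' @export
nakagawa_r2 <- function(x, ...) UseMethod("nakagawa_r2")

#' @rdname nakagawa_r2
#' @param sigma2_random sum (or vector) of random-effect variances.
#' @param sigma2_resid residual (or distribution-specific) variance.
#' @export
nakagawa_r2.default <- function(x, sigma2_random, sigma2_resid, ...) {
  sigma2_fixed <- x
  tot <- sigma2_fixed + sum(sigma2_random) + sigma2_resid
  abort_if(!is.finite(tot) || tot <= 0, "total variance must be positive")
  c(r2_marginal = sigma2_fixed / tot,
    r2_conditional = (sigma2_fixed + sum(sigma2_random)) / tot)
}

#' @rdname nakagawa_r2
#' @export
nakagawa_r2.hr_fit <- function(x, ...) {
  sigma2_fixed <- stats::var(x$eta_fixed)
  sigma2_resid <- if (x$family == "binomial") pi^2 / 3 else x$sigma_resid
  if (x$engine == "lm") sigma2_resid <- stats::sigma(x$model)^2
  nakagawa_r2.default(sigma2_fixed, x$varcomps, sigma2_resid)
}

#' Marginal-effect predictions over an HP grid
#'
#' Predicted response (with delta-method confidence band) along a grid of raw
#' HP values, holding other continuous covariates at their sample means and
#' random effects at zero; the inverse link is applied for binomial fits. HP
#' values outside the fitted range are flagged as extrapolation, not refused.
#'
#' @param fit `hr_fit` from one of the model fitters.
#' @param hp numeric grid of raw HP values.
#' @param dispersal_mode mode(s) to predict for (interaction fits); default all
#'   modes in the data.
#' @param sl_mm seed length(s), mm, for the endozoochory seed-size fit.
#' @param level confidence level.
#' @return data.frame: hp, grouping columns, predicted, lwr, upr, eta (link
#'   scale), extrapolated.
#' @export
marginal_effects <- function(fit, hp, dispersal_mode = NULL, sl_mm = NULL,
                             level = 0.95) {
  abort_if(!isTRUE(fit$converged), "fit did not converge")
  sc <- fit$scaling
  has_mode <- "dispersal_mode" %in% names(fit$data)
  has_sl <- "z_sl" %in% names(fit$data)
  has_stage <- "life_stage" %in% names(fit$data)

  grid <- expand.grid(
    hp = hp,
    dispersal_mode = if (has_mode) {
      if (is.null(dispersal_mode)) levels(fit$data$dispersal_mode) else dispersal_mode
    } else NA,
    sl_mm = if (has_sl) { if (is.null(sl_mm)) c(1, 18, 50) else sl_mm } else NA,
    life_stage = if (has_stage) levels(fit$data$life_stage) else NA,
    stringsAsFactors = FALSE
  )
  nd <- data.frame(z_hp = (grid$hp - sc$hp["mean"]) / sc$hp["sd"])
  for (v in c("cec", "vdnd", "n_adults")) {
    col <- paste0("z_", v)
    if (col %in% names(fit$data)) nd[[col]] <- 0
  }
  if (has_mode) {
    nd$dispersal_mode <- factor(grid$dispersal_mode,
                                levels = levels(fit$data$dispersal_mode))
  }
  if (has_sl) nd$z_sl <- (grid$sl_mm - sc$sl["mean"]) / sc$sl["sd"]
  if (has_stage) {
    nd$life_stage <- factor(grid$life_stage,
                            levels = levels(fit$data$life_stage))
  }

  form <- if (inherits(fit$model, "merMod")) {
    lme4::nobars(stats::formula(fit$model))
  } else stats::formula(fit$model)
  X <- stats::model.matrix(stats::delete.response(stats::terms(form)), nd)
  b <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model) else stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  eta <- as.vector(X %*% b)
  se <- sqrt(rowSums((X %*% V) * X))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  link_inv <- if (fit$family == "binomial") stats::plogis else identity
  out <- data.frame(hp = grid$hp)
  if (has_mode) out$dispersal_mode <- grid$dispersal_mode
  if (has_sl) out$sl_mm <- grid$sl_mm
  if (has_stage) out$life_stage <- grid$life_stage
  out$eta <- eta
  out$predicted <- link_inv(eta)
  out$lwr <- link_inv(eta - zq * se)
  out$upr <- link_inv(eta + zq * se)
  out$extrapolated <- grid$hp < min(fit$data$hp) | grid$hp > max(fit$data$hp)
  out
}

#' Pairwise Pearson trait correlations
#'
#' Pearson r with two-sided t-test p-values for every trait pair, using
#' complete pairs per pair, for all species together and (optionally) within
#' each dispersal mode. Pairs with fewer than 3 complete observations are
#' reported as NA with a warning.
#'
#' @param traits species-level table with the trait columns (and
#'   `dispersal_mode` if `grouping = "mode"`).
#' @param which trait columns to correlate.
#' @param grouping "all" or "mode".
#' @return data.frame: group, trait1, trait2, r, p, n.
#' @export
trait_correlations <- function(traits, which = c("WD", "LMA", "SL"),
                               grouping = c("all", "mode")) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "all") list(all = traits) else
    split(traits, traits$dispersal_mode)
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    cmb <- utils::combn(which, 2)
    for (k in seq_len(ncol(cmb))) {
      x <- d[[cmb[1, k]]]; y <- d[[cmb[2, k]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) {
        warning(sprintf("fewer than 3 complete pairs for %s-%s in group %s",
                        cmb[1, k], cmb[2, k], g))
        res <- list(estimate = NA_real_, p.value = NA_real_)
      } else {
        res <- stats::cor.test(x[ok], y[ok], method = "pearson")
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, trait1 = cmb[1, k], trait2 = cmb[2, k],
        r = as.numeric(res$estimate), p = res$p.value, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Significance star codes
#'
#' `****` for p <= 0.0001, `***` for p <= 0.001, `**` for p <= 0.01, `*` for
#' p <= 0.05, and `n.s.` otherwise (undefined p is reported n.s.).
#'
#' @param p p-values.
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  out <- rep("n.s.", length(p))
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out[!is.na(p) & p <= 0.0001] <- "****"
  out
}

#' Pairwise Welch t-tests of a trait across dispersal modes
#'
#' Welch two-sample t-tests for each pair of dispersal modes, with star codes
#' per [p_stars()]. Modes with fewer than 2 values are skipped. Raw p-values
#' are reported by default; Holm correction is available behind a flag.
#'
#' @param traits species table with `dispersal_mode` and the trait column.
#' @param trait trait name.
#' @param adjust "none" (default) or "holm".
#' @return data.frame: mode1, mode2, diff (mean1 - mean2), t, df, p, stars.
#' @export
pairwise_mode_tests <- function(traits, trait, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  vals <- split(traits[[trait]], as.character(traits$dispersal_mode))
  vals <- lapply(vals, function(v) v[!is.na(v)])
  vals <- vals[vapply(vals, length, 0L) >= 2]
  modes <- sort(names(vals))
  abort_if(length(modes) < 2, "need at least two modes with >= 2 values")
  cmb <- utils::combn(modes, 2)
  out <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- vals[[cmb[1, k]]]; b <- vals[[cmb[2, k]]]
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    data.frame(mode1 = cmb[1, k], mode2 = cmb[2, k],
               diff = mean(a) - mean(b),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out$stars <- p_stars(out$p)
  out
}
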