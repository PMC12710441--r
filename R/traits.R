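#' Hierarchical trait imputation with a provenance ledger
#'
#' Attaches a trait value to every stem using a species -> genus -> family
#' fallback: the species-level value if present, otherwise the unweighted mean
#' of species-level values within the stem's genus, otherwise within its
#' family, otherwise missing. Genus and family means average over species (not
#' stems), so abundant species do not leak extra weight into the imputation.
#' Stems lacking a family label can reach at most genus-level provenance.
#'
#' @param stems data.frame with `stem_id`, `species_id`, `genus`, `family`.
#' @param traits species-level trait table (one row per species) with
#'   `species_id`, `genus`, `family` and the trait column; NA where no
#'   species-level value exists.
#' @param trait trait column name (one of [trait_names()]).
#' @return List with `assignments` (stem_id, species_id, trait, value,
#'   provenance in species/genus/family/missing) and `coverage` (named
#'   fractions of stems at each provenance level, summing to 1).
#' @export
impute_trait <- function(stems, traits, trait) {
  require_columns(stems, c("stem_id", "species_id", "genus"), "stem table")
  require_columns(traits, c("species_id", trait), "trait table")
  sp_val <- traits[[trait]][match(stems$species_id, traits$species_id)]

  # Means over species carrying a species-level value.
  has <- !is.na(traits[[trait]])
  gen_mean <- tapply(traits[[trait]][has], traits$genus[has], mean)
  fam_mean <- if ("family" %in% names(traits)) {
    tapply(traits[[trait]][has], traits$family[has], mean)
  } else NULL

  value <- sp_val
  provenance <- ifelse(is.na(value), NA_character_, "species")

  need <- is.na(value)
  if (any(need)) {
    gv <- gen_mean[stems$genus[need]]
    fill <- !is.na(gv)
    value[need][fill] <- gv[fill]
    provenance[need][fill] <- "genus"
  }
  need <- is.na(value)
  if (any(need) && !is.null(fam_mean) && "family" %in% names(stems)) {
    fam <- stems$family[need]
    fv <- rep(NA_real_, length(fam))
    ok <- !is.na(fam)
    fv[ok] <- fam_mean[fam[ok]]
    fill <- !is.na(fv)
    value[need][fill] <- fv[fill]
    provenance[need][fill] <- "family"
  }
  provenance[is.na(provenance)] <- "missing"

  assignments <- data.frame(stem_id = stems$stem_id,
                            species_id = stems$species_id,
                            trait = trait, value = value,
                            provenance = factor(provenance,
                                                levels = c("species", "genus",
                                                           "family", "missing")),
                            stringsAsFactors = FALSE)
  coverage <- table(assignments$provenance) / nrow(assignments)
  list(assignments = assignments,
       coverage = stats::setNames(as.numeric(coverage), names(coverage)))
}

#' Attach imputed traits (and provenances) to a stem table
#'
#' Convenience wrapper over [impute_trait()] for several traits at once; adds
#' `<trait>` and `<trait>_provenance` columns to the stem table.
#'
#' @inheritParams impute_trait
#' @param which traits to attach (default all five).
#' @return The stem table with added columns; per-trait coverage ledgers in
#'   `attr(, "coverage")`.
#' @export
attach_traits <- function(stems, traits, which = trait_names()) {
  cov <- list()
  for (tr in which) {
    imp <- impute_trait(stems, traits, tr)
    stems[[tr]] <- imp$assignments$value
    stems[[paste0(tr, "_provenance")]] <- as.character(imp$assignments$provenance)
    cov[[tr]] <- imp$coverage
  }
  attr(stems, "coverage") <- cov
  stems
}

#' Classify seed-size dispersal limitation
#'
#' A species is flagged as potentially dispersal-limited when its seed length
#' exceeds 18 mm; where seed length is unavailable, a seed width above 12 mm
#' is used instead. Boundary values are not limited (strict inequality).
#'
#' @param SL seed length, mm (may be NA).
#' @param SW seed width, mm (may be NA).
#' @return data.frame with `limited` (logical) and `rule_used`
#'   ("SL>18mm" or "SW>12mm"). Errors if both measurements are absent for any
#'   element.
#' @export
classify_seed_limitation <- function(SL, SW = NA_real_) {
  n <- max(length(SL), length(SW))
  SL <- rep_len(SL, n); SW <- rep_len(SW, n)
  abort_if(any(is.na(SL) & is.na(SW)),
           "at least one of SL, SW must be present for every species")
  use_sl <- !is.na(SL)
  data.frame(limited = ifelse(use_sl, SL > 18, SW > 12),
             rule_used = ifelse(use_sl, "SL>18mm", "SW>12mm"),
             stringsAsFactors = FALSE)
}

#' Count endozoochorous species flagged as dispersal-limited
#'
#' Counts distinct species (not stems). Species missing both seed length and
#' width cannot be classified and are excluded from both numerator and
#' denominator; if no endozoochorous species can be classified the fraction is
#' reported as NA.
#'
#' @param traits species-level table with `species_id`, `dispersal_mode`,
#'   `SL`, `SW`.
#' @return List: `n_limited`, `n_endozoochorous` (classifiable), `fraction`.
#' @export
count_limited_species <- function(traits) {
  require_columns(traits, c("species_id", "dispersal_mode", "SL"),
                  "trait table")
  endo <- traits[!duplicated(traits$species_id) &
                   traits$dispersal_mode == "endozoochory", , drop = FALSE]
  sw <- if ("SW" %in% names(endo)) endo$SW else rep(NA_real_, nrow(endo))
  classifiable <- !(is.na(endo$SL) & is.na(sw))
  endo <- endo[classifiable, , drop = FALSE]
  if (nrow(endo) == 0) {
    return(list(n_limited = 0L, n_endozoochorous = 0L, fraction = NA_real_))
  }
  cls <- classify_seed_limitation(endo$SL,
                                  if ("SW" %in% names(endo)) endo$SW else NA_real_)
  list(n_limited = sum(cls$limited),
       n_endozoochorous = nrow(endo),
       fraction = mean(cls$limited))
}
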