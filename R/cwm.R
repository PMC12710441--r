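#' Stem basal area
#'
#' \deqn{BA = \pi (DBH/2)^2} in cm2. For saplings the diameter at the point of
#' measurement plays the role of DBH; the formula is applied identically to
#' both stages.
#'
#' @param dbh_cm stem diameter, cm (> 0; vectorised).
#' @return basal area, cm2.
#' @export
basal_area <- function(dbh_cm) {
  abort_if(any(!is.finite(dbh_cm)) || any(dbh_cm <= 0), "dbh must be > 0")
  pi * (dbh_cm / 2)^2
}

#' Basal-area-weighted community mean of a trait
#'
#' \deqn{CWM = \sum_i BA_i T_i / \sum_i BA_i} over the included stems.
#'
#' @param ba basal areas (> 0).
#' @param value trait values, same length.
#' @return weighted mean.
#' @export
cwm <- function(ba, value) {
  abort_if(length(ba) != length(value), "ba and value lengths differ")
  abort_if(length(ba) == 0, "no stems supplied")
  abort_if(any(ba <= 0), "basal areas must be > 0")
  sum(ba * value) / sum(ba)
}

#' Community-weighted mean trait table per plot and life stage
#'
#' Computes BA-weighted CWMs for each plot x life stage x trait. Only stems
#' whose trait provenance is species- or genus-level enter the weighted mean
#' (family-level imputations and missing values are excluded, though they
#' remain in the coverage ledger); stems of species lacking a given trait are
#' excluded from that trait's CWM only. Combinations with no eligible stems
#' are dropped with a warning.
#'
#' @param stems stem table with `plot_id`, `life_stage`, `dbh_cm` and, per
#'   trait, `<trait>` and `<trait>_provenance` columns (see
#'   [attach_traits()]).
#' @param traits trait names to summarise (default WD, LMA, SL).
#' @param include_provenance provenance levels eligible for the CWM.
#' @return data.frame: plot_id, life_stage, trait, cwm, total_ba (cm2),
#'   n_stems_used.
#' @export
cwm_table <- function(stems, traits = c("WD", "LMA", "SL"),
                      include_provenance = c("species", "genus")) {
  require_columns(stems, c("plot_id", "life_stage", "dbh_cm"), "stem table")
  ba <- basal_area(stems$dbh_cm)
  out <- list()
  dropped <- 0L
  for (tr in traits) {
    require_columns(stems, tr, "stem table")
    prov_col <- paste0(tr, "_provenance")
    eligible <- !is.na(stems[[tr]])
    if (prov_col %in% names(stems)) {
      eligible <- eligible & stems[[prov_col]] %in% include_provenance
    }
    for (pl in unique(stems$plot_id)) {
      for (st in unique(stems$life_stage)) {
        sel <- eligible & stems$plot_id == pl & stems$life_stage == st
        if (!any(sel)) { dropped <- dropped + 1L; next }
        out[[length(out) + 1L]] <- data.frame(
          plot_id = pl, life_stage = st, trait = tr,
          cwm = cwm(ba[sel], stems[[tr]][sel]),
          total_ba = sum(ba[sel]), n_stems_used = sum(sel),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped > 0) {
    warning(sprintf("%d plot x stage x trait combination(s) had no eligible stems and were dropped",
                    dropped))
  }
  do.call(rbind, out)
}
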