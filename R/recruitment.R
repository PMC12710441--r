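#' Stem density per hectare
#'
#' @param count stem count (>= 0).
#' @param area_ha sampled area in hectares (> 0).
#' @return stems per hectare.
#' @export
stem_density <- function(count, area_ha) {
  abort_if(any(area_ha <= 0), "area must be > 0")
  abort_if(any(count < 0), "count must be >= 0")
  count / area_ha
}

#' Sapling-to-tree abundance log-ratio
#'
#' \deqn{S{:}T = \log_{10}(D_{sapling} / D_{tree})} on per-hectare densities.
#' Positive values indicate a greater conspecific sapling than adult density;
#' the ratio is only defined for species recorded at least once in both
#' stages, so zero densities yield NA (the record is excluded from S:T
#' models).
#'
#' @param d_sapling,d_tree per-hectare densities (vectorised).
#' @return log10 ratio, NA where either density is zero.
#' @export
st_ratio <- function(d_sapling, d_tree) {
  abort_if(any(d_sapling < 0) || any(d_tree < 0), "densities must be >= 0")
  out <- rep(NA_real_, length(d_sapling))
  ok <- d_sapling > 0 & d_tree > 0
  out[ok] <- log10(d_sapling[ok] / d_tree[ok])
  out
}

#' Build the species-by-plot recruitment table
#'
#' One record per species x plot combination with at least one conspecific
#' adult in the 0.25-ha tree plot (the presence/absence analysis universe
#' conditions on adult presence). Sapling counts come from the nested 0.05-ha
#' subplot. Densities are per-hectare; `sapling_present` is 1 iff at least one
#' sapling was recorded; `st_ratio` is present only where both stages were
#' recorded.
#'
#' @param stems stem table with `plot_id`, `life_stage` (adult/sapling),
#'   `species_id`.
#' @param plots plot table with `plot_id`, `tree_area`, `sapling_area` (ha).
#' @return data.frame of class `hr_recruitment`: species_id, plot_id,
#'   n_adults, n_saplings, d_tree, d_sapling, sapling_present, st_ratio.
#' @export
build_recruitment_table <- function(stems, plots) {
  require_columns(stems, c("plot_id", "life_stage", "species_id"), "stem table")
  require_columns(plots, c("plot_id", "tree_area", "sapling_area"),
                  "plot table")
  ad <- stems[stems$life_stage == "adult", , drop = FALSE]
  sa <- stems[stems$life_stage == "sapling", , drop = FALSE]

  key <- function(d) paste(d$species_id, d$plot_id, sep = "\r")
  ad_tab <- table(key(ad))
  sa_tab <- table(key(sa))

  ks <- names(ad_tab) # universe: >= 1 conspecific adult
  parts <- strsplit(ks, "\r", fixed = TRUE)
  rec <- data.frame(
    species_id = vapply(parts, `[`, "", 1),
    plot_id = vapply(parts, `[`, "", 2),
    n_adults = as.integer(ad_tab),
    n_saplings = as.integer(ifelse(is.na(sa_tab[ks]), 0L, sa_tab[ks])),
    stringsAsFactors = FALSE
  )
  m <- match(rec$plot_id, plots$plot_id)
  abort_if(any(is.na(m)), "stem table references plots absent from plot table")
  rec$d_tree <- stem_density(rec$n_adults, plots$tree_area[m])
  rec$d_sapling <- stem_density(rec$n_saplings, plots$sapling_area[m])
  rec$sapling_present <- as.integer(rec$n_saplings >= 1)
  rec$st_ratio <- st_ratio(rec$d_sapling, rec$d_tree)
  rec <- rec[order(rec$plot_id, rec$species_id), ]
  rownames(rec) <- NULL
  class(rec) <- c("hr_recruitment", "data.frame")
  rec
}
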