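# Internal helpers shared across modules.

# Stop with a message naming the offending argument.
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

# Require columns in a data frame, failing fast with the missing names.
require_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  abort_if(length(missing) > 0,
           sprintf("%s is missing required column(s): %s",
                   what, paste(missing, collapse = ", ")))
  invisible(df)
}

# Centre and scale to unit SD; constant vectors map to 0 (their information
# content for a regression is nil, and dropping them is the caller's call).
zstd <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - m) / s
}

# Derive a child RNG seed from a master seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1009 * offset) %% (.Machine$integer.max - 1L)) + 1L
}

#' Canonical dispersal-mode levels
#'
#' The three seed-dispersal guilds used throughout the analysis, in the fixed
#' factor order (alphabetical, so treatment contrasts use "abiotic" as the
#' reference level): abiotic (wind, water, ballistic), endozoochory (gut
#' passage by frugivores), and scatter-hoarding by large rodents.
#'
#' @return Character vector of the three mode levels.
#' @export
dispersal_modes <- function() c("abiotic", "endozoochory", "scatter_hoarded")

#' Continuous functional traits handled by the pipeline
#'
#' @return Character vector of trait names: wood density WD (g/cm3), leaf mass
#'   per area LMA (g/cm2), seed length SL (mm), seed width SW (mm), seed dry
#'   mass SM (g).
#' @export
trait_names <- function() c("WD", "LMA", "SL", "SW", "SM")
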