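#' Phylogenetic variance-covariance matrix
#'
#' Brownian-motion covariance of a tree: entry (i, j) is the shared
#' root-to-MRCA branch length of tips i and j; the diagonal holds root-to-tip
#' distances.
#'
#' @param tree an `ape::phylo` with branch lengths and unique tip labels.
#' @return symmetric positive semi-definite matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  abort_if(!inherits(tree, "phylo"), "tree must be an ape phylo object")
  abort_if(anyDuplicated(tree$tip.label) > 0, "duplicate tip labels")
  abort_if(is.null(tree$edge.length), "tree must have branch lengths")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal covariances by lambda, leaving the diagonal
#' unchanged. Lambda is restricted to [0, 1] (no extension above 1, keeping the
#' matrix positive semi-definite on arbitrary trees).
#'
#' @param vcv covariance matrix from [phylo_vcv()].
#' @param lambda scalar in [0, 1].
#' @return transformed covariance matrix.
#' @export
lambda_transform <- function(vcv, lambda) {
  abort_if(!is.numeric(lambda) || length(lambda) != 1 ||
             lambda < 0 || lambda > 1, "lambda must be a scalar in [0, 1]")
  W <- lambda * vcv
  diag(W) <- diag(vcv)
  W
}

# Profiled log-likelihood of lambda: mean and scale are maximised analytically
# (GLS mean; ML variance), so the profile depends on lambda alone.
lambda_loglik <- function(lambda, y, V) {
  W <- lambda_transform(V, lambda)
  n <- length(y)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  abort_if(is.null(ch),
           sprintf("singular transformed covariance at lambda = %.4f (reciprocal condition number %.3g)",
                   lambda, rcond(W)))
  logdet <- 2 * sum(log(diag(ch)))
  Winv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Winv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Winv_y) / sum(Winv_1)
  r <- y - mu
  q <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
  sigma2 <- q / n
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Estimate Pagel's lambda for species-level residuals
#'
#' Maximum-likelihood estimate of the phylogenetic-signal parameter lambda in
#' [0, 1] for a set of species-level values (typically per-species means of a
#' model's marginal residuals) on a phylogeny. The multivariate-normal
#' likelihood is profiled analytically over mean and scale at each lambda and
#' maximised by bounded scalar optimisation (tolerance 1e-6 in lambda),
#' with both endpoints checked. The test of lambda = 0 is a likelihood-ratio
#' test against the boundary-corrected half-chi-square(1) mixture.
#'
#' Tips absent from the residual set are pruned; at least 4 shared species are
#' required.
#'
#' @param residuals named numeric vector (names = species ids), or a
#'   data.frame with columns `species_id` and `residual`.
#' @param tree an `ape::phylo`.
#' @return List of class `hr_phylosig`: `lambda` (the ML estimate),
#'   `loglik_at_hat`, `loglik_at_zero`, `lrt_stat`, `p`, `n`.
#' @export
estimate_lambda <- function(residuals, tree) {
  if (is.data.frame(residuals)) {
    require_columns(residuals, c("species_id", "residual"), "residual table")
    residuals <- stats::setNames(residuals$residual, residuals$species_id)
  }
  abort_if(is.null(names(residuals)), "residuals must be named by species id")
  common <- intersect(names(residuals), tree$tip.label)
  abort_if(length(common) < 4,
           "need >= 4 species shared between residuals and tree")
  tree <- ape::keep.tip(tree, common)
  y <- residuals[tree$tip.label]
  V <- phylo_vcv(tree)

  f <- function(l) lambda_loglik(l, y, V)
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, f(0)), c(1, f(1)))
  best <- cand[which.max(cand[, 2]), ]
  ll0 <- cand[2, 2]
  stat <- max(0, 2 * (best[2] - ll0))
  p <- if (stat <= sqrt(.Machine$double.eps)) 1 else
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(lambda = unname(best[1]), loglik_at_hat = unname(best[2]),
                 loglik_at_zero = unname(ll0), lrt_stat = unname(stat),
                 p = p, n = length(y)),
            class = "hr_phylosig")
}

#' @export
print.hr_phylosig <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (logLik %.3f vs %.3f at lambda = 0), LRT p = %.4g, n = %d\n",
              x$lambda, x$loglik_at_hat, x$loglik_at_zero, x$p, x$n))
  invisible(x)
}

#' Species-level residuals of a fitted model
#'
#' Per-species means of the marginal (fixed-effects-only, response-scale)
#' residuals of a `hr_fit`, suitable as input to [estimate_lambda()].
#'
#' @param fit `hr_fit` with per-observation residuals and species ids.
#' @return named numeric vector of per-species mean residuals.
#' @export
species_residuals <- function(fit) {
  abort_if(is.null(fit$species_id), "fit carries no species identifiers")
  tapply(fit$residuals_marginal, fit$species_id, mean)
}

#' Pure-birth phylogeny over a species pool
#'
#' A Yule (pure-birth) tree with tips relabelled to the pool's species ids,
#' used for phylogenetic-signal diagnostics on synthetic runs. The topology is
#' random and does not mirror the pool's genus/family taxonomy.
#'
#' @param pool `hr_species_pool` (or any table with `species_id`).
#' @param seed RNG seed or NULL.
#' @return an `ape::phylo` with `nrow(pool)` tips.
#' @export
pool_phylogeny <- function(pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(nrow(pool), birth = 1, death = 0)
  tree$tip.label <- sample(pool$species_id)
  tree
}
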