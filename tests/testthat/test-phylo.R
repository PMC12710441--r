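test_that("phylogenetic covariance matches shared branch lengths", {
  star <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_vcv(star)), diag(2))
  cherry <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- phylo_vcv(cherry)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  dup <- star; dup$tip.label <- c("A", "A")
  expect_error(phylo_vcv(dup), "duplicate")
})

test_that("covariance equals brute-force MRCA-depth computation", {
  set.seed(14)
  tree <- ape::rtree(10)
  V <- phylo_vcv(tree)
  n <- length(tree$tip.label)
  # oracle: distance from root to the most recent common ancestor
  depths <- ape::node.depth.edgelength(tree)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      anc <- if (i == j) i else ape::getMRCA(tree, c(i, j))
      expect_equal(V[tree$tip.label[i], tree$tip.label[j]], depths[anc],
                   tolerance = 1e-12)
    }
  }
})

test_that("lambda transform scales only the off-diagonal", {
  V <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(V, 0.5), matrix(c(2, 0.5, 0.5, 2), 2))
  expect_error(lambda_transform(V, 1.2), "lambda")
  expect_error(lambda_transform(V, -0.1), "lambda")
})

test_that("lambda estimates are invariant to affine transforms and pruning", {
  set.seed(15)
  tree <- ape::rphylo(60, 1, 0)
  y <- as.vector(MASS::mvrnorm(1, rep(0, 60),
                               lambda_transform(phylo_vcv(tree), 0.5)))
  names(y) <- tree$tip.label
  est <- estimate_lambda(y, tree)
  expect_gte(est$lambda, 0); expect_lte(est$lambda, 1)
  expect_gte(est$loglik_at_hat, est$loglik_at_zero)
  est2 <- estimate_lambda(3.7 * y + 11, tree)
  expect_equal(est2$lambda, est$lambda, tolerance = 1e-4)
  # pruning tips absent from the residual set changes nothing
  sub <- y[1:40]
  expect_equal(estimate_lambda(sub, tree)$lambda,
               estimate_lambda(sub, ape::keep.tip(tree, names(sub)))$lambda,
               tolerance = 1e-8)
})

test_that("permuted residuals show no phylogenetic signal", {
  set.seed(16)
  tree <- ape::rphylo(100, 1, 0)
  V <- phylo_vcv(tree)
  lam <- vapply(1:50, function(i) {
    y <- as.vector(MASS::mvrnorm(1, rep(0, 100), V))
    names(y) <- sample(tree$tip.label) # permutation destroys the signal
    estimate_lambda(y, tree)$lambda
  }, numeric(1))
  expect_lte(median(lam), 0.1)
})

test_that("lambda agrees with an independent phylogenetics implementation", {
  set.seed(18)
  tree <- ape::rphylo(80, 1, 0)
  y <- as.vector(MASS::mvrnorm(1, rep(0, 80),
                               lambda_transform(phylo_vcv(tree), 0.6)))
  names(y) <- tree$tip.label
  ours <- estimate_lambda(y, tree)
  ref <- phytools::phylosig(tree, y, method = "lambda", test = TRUE)
  expect_equal(ours$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(ours$loglik_at_hat, ref$logL, tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  tree <- ape::rphylo(10, 1, 0)
  y <- setNames(rnorm(3), tree$tip.label[1:3])
  expect_error(estimate_lambda(y, tree), ">= 4 species")
  expect_error(estimate_lambda(rnorm(10), tree), "named")
})

test_that("species residuals average per species", {
  study <- .default_study()
  rec <- build_recruitment_table(study$stems, study$landscape$plots)
  fit <- suppressWarnings(fit_recruitment_glmm(rec, study$landscape$plots,
                                               study$traits))
  r <- species_residuals(fit)
  one <- names(r)[1]
  expect_equal(unname(r[one]),
               mean(fit$residuals_marginal[fit$species_id == one]))
})

test_that("pool phylogeny covers all species and is reproducible", {
  pool <- generate_species_pool(50, seed = 20)
  t1 <- pool_phylogeny(pool, seed = 21)
  t2 <- pool_phylogeny(pool, seed = 21)
  expect_setequal(t1$tip.label, pool$species_id)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})
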