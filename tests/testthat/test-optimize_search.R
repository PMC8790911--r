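test_that("branch-length optimization hits bounds and recovers distances", {
  m <- build_gt16_rate_matrix()
  # identical error-free cells: optimal length at the lower bound
  gm <- matrix(rep(c("A", "C", "M", "T", "K"), 2), 2, 5, byrow = TRUE,
               dimnames = list(c("x", "y"), NULL))
  d <- genotype_data(genotypes = gm)
  tips <- build_tip_clvs(d, error_params(), FALSE)
  tr <- ape::read.tree(text = "(x:0.3,y:0.3);")
  res <- optimize_branch_lengths(tr, tips, m)
  expect_lt(sum(res$tree$edge.length), 1e-6)
  # two-cell simulated distance recovered within 20%
  set.seed(21)
  p <- transition_probabilities(m, 0.05)
  x <- sample.int(16, 10000, replace = TRUE, prob = m$pi)
  y <- vapply(x, function(s) sample.int(16, 1, prob = p[s, ]), 0L)
  u2p <- scphylo:::phased_to_unphased()
  gm <- rbind(x = u2p[x], y = u2p[y])
  d2 <- genotype_data(genotypes = gm)
  comp <- compress_patterns(d2)
  tips2 <- build_tip_clvs(comp$data, error_params(), FALSE)
  tr2 <- ape::read.tree(text = "(x:0.3,y:0.3);")
  res2 <- optimize_branch_lengths(tr2, tips2, m, weights = comp$weights,
                                  epsilon = 1e-4)
  expect_lt(abs(sum(res2$tree$edge.length) - 0.05) / 0.05, 0.2)
  # re-running from perturbed lengths converges to the same score
  tr3 <- res2$tree
  tr3$edge.length <- tr3$edge.length * 3 + 0.01
  res3 <- optimize_branch_lengths(tr3, tips2, m, weights = comp$weights,
                                  epsilon = 1e-4)
  expect_lt(abs(res3$loglik - res2$loglik), 0.01)
})

test_that("substitution parameter optimization recovers equal exchangeabilities", {
  set.seed(31)
  sim <- simulate_dataset(sim_config(n_cells = 10, n_snvs = 2000, seed = 17))
  comp <- compress_patterns(sim$truth$data)
  tips <- build_tip_clvs(comp$data, error_params(), FALSE)
  params <- substitution_params(
    exchangeabilities = c(3, 0.3, 2, 0.5, 2),  # deliberately wrong start
    frequencies = scphylo:::empirical_frequencies(comp$data, 16))
  bo <- optimize_branch_lengths(sim$tree, tips,
                                build_model(params, 16), weights = comp$weights)
  res <- optimize_substitution_params(bo$tree, tips, params,
                                      weights = comp$weights,
                                      maxit = 40, optimize_freqs = FALSE)
  ex <- res$params$exchangeabilities
  expect_lt(max(ex) / min(ex), 4)   # all estimates within a factor ~2 of each other
  expect_gte(res$loglik, bo$loglik)
  # optimizing twice changes the score by < epsilon
  res2 <- optimize_substitution_params(bo$tree, tips, res$params,
                                       weights = comp$weights,
                                       maxit = 40, optimize_freqs = FALSE)
  expect_lt(abs(res2$loglik - res$loglik), 0.5)
})

test_that("degenerate single-site data warns and keeps the incumbent", {
  gm <- matrix(c("A", "C"), 2, 1, dimnames = list(c("x", "y"), NULL))
  d <- genotype_data(genotypes = gm)
  tips <- build_tip_clvs(d, error_params(), FALSE)
  tr <- ape::read.tree(text = "(x:0.1,y:0.1);")
  expect_warning(
    res <- optimize_substitution_params(tr, tips, substitution_params()),
    "too few")
  expect_equal(res$params$exchangeabilities, rep(1, 5))
})

test_that("error rates are estimated near zero on clean data and are order-invariant", {
  # clean data generated under the substitution model itself (skewed,
  # hom-ref-heavy frequencies, as in real SNV matrices), so the estimator
  # is tested without simulator/model mismatch; profile-likelihood mode
  # is needed because error rates and pendant branch lengths are weakly
  # confounded near zero error
  set.seed(41)
  f <- c(0.35, rep(0.02, 4), 0.25, rep(0.02, 4), 0.15, rep(0.02, 4), 0.05)
  m <- build_gt16_rate_matrix(substitution_params(frequencies = f / sum(f)))
  tr <- starting_tree_random(paste0("c", 1:16), seed = 2)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.15)
  gm16 <- simulate_gt16_matrix(tr, m, 4000)
  gm <- matrix(scphylo:::phased_to_unphased()[gm16], nrow(gm16), ncol(gm16),
               dimnames = dimnames(gm16))
  d <- genotype_data(genotypes = gm)
  comp <- compress_patterns(d)
  tips <- build_tip_clvs(comp$data, error_params(0.05, 0.05), TRUE)
  bo <- optimize_branch_lengths(tr, tips, m, weights = comp$weights)
  res <- optimize_error_params(bo$tree, comp$data, m, error_params(0.05, 0.05),
                               weights = comp$weights, epsilon = 0.001,
                               profile = TRUE)
  # point estimates land at (or within the estimator's sampling
  # variability of) zero ...
  expect_lt(res$error$delta, 0.02)
  expect_lt(res$error$epsilon, 0.02)
  # ... and the zero-error model is statistically indistinguishable from
  # the fitted optimum (95% likelihood-ratio tolerance, 2 df)
  tips0 <- build_tip_clvs(comp$data, error_params(0, 0), TRUE)
  ll0 <- optimize_branch_lengths(bo$tree, tips0, m, weights = comp$weights,
                                 epsilon = 1e-4)$loglik
  expect_gt(ll0, res$loglik - stats::qchisq(0.95, df = 2) / 2)
  # site permutation leaves the estimates unchanged (conditional mode on a
  # slice of the data, permuted vs not)
  ds <- genotype_data(genotypes = d$genotypes[, 1:800])
  perm <- sample(800)
  dp <- genotype_data(genotypes = ds$genotypes[, perm])
  resA <- optimize_error_params(bo$tree, ds, m, error_params(0.05, 0.05))
  resB <- optimize_error_params(bo$tree, dp, m, error_params(0.05, 0.05))
  expect_equal(resB$error$delta, resA$error$delta, tolerance = 1e-8)
  expect_equal(resB$error$epsilon, resA$error$epsilon, tolerance = 1e-8)
  # GL input has no error parameters to estimate
  gl <- array(0, dim = c(2, 3, 10))
  dgl <- genotype_data(gl = gl)
  expect_error(optimize_error_params(bo$tree, dgl, m), "genotype input")
})

test_that("random starting trees are uniform, reproducible, and validated", {
  expect_error(starting_tree_random(c("a", "a", "b")), "duplicate")
  expect_error(starting_tree_random(c("a", "b")), "at least 3")
  t3 <- starting_tree_random(c("a", "b", "c"), seed = 1)
  expect_equal(ape::Ntip(t3), 3)
  expect_equal(t3$Nnode, 1)
  a <- starting_tree_random(letters[1:8], seed = 99)
  b <- starting_tree_random(letters[1:8], seed = 99)
  expect_equal(topology_key(a), topology_key(b))
  # all 15 topologies on 5 labels appear at uniform frequency (3 sigma)
  set.seed(7)
  n_draw <- 6000
  keys <- replicate(n_draw, topology_key(starting_tree_random(letters[1:5])))
  tab <- table(keys)
  expect_length(tab, 15)
  expected <- n_draw / 15
  band <- 3 * sqrt(n_draw * (1 / 15) * (14 / 15))
  expect_true(all(abs(tab - expected) <= band))
})

test_that("parsimony starting trees use the data and are reproducible", {
  # two perfectly compatible binary characters pick the compatible topology
  gm <- matrix(c("A", "A",
                 "A", "A",
                 "C", "C",
                 "C", "C"), 4, 2, byrow = TRUE,
               dimnames = list(c("p", "q", "r", "s"), NULL))
  gm <- cbind(gm, c("G", "G", "T", "T"))
  d <- genotype_data(genotypes = gm)
  tr <- starting_tree_parsimony(d, seed = 3)
  expect_equal(topology_key(tr),
               topology_key(ape::read.tree(text = "((p,q),(r,s));")))
  expect_equal(topology_key(starting_tree_parsimony(d, seed = 12)),
               topology_key(starting_tree_parsimony(d, seed = 12)))
  # parsimony start never scores worse than a random topology (paired)
  set.seed(8)
  sim <- simulate_dataset(sim_config(n_cells = 8, n_snvs = 100,
                                     delta = 0.2, genotype_error = 0.1, seed = 31))
  wins <- 0L
  for (i in 1:20) {
    ps <- parsimony_score(starting_tree_parsimony(sim$observed, seed = 100 + i),
                          sim$observed)
    rs <- parsimony_score(starting_tree_random(sim$observed$cells, seed = 200 + i),
                          sim$observed)
    if (ps <= rs) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
  # an all-missing cell is placed with a warning
  gm2 <- gm
  gm2[2, ] <- "?"
  expect_warning(starting_tree_parsimony(genotype_data(genotypes = gm2), seed = 1),
                 "no observed genotypes")
})

test_that("SPR search improves the score, is deterministic, and never harms a good start", {
  set.seed(9)
  sim <- simulate_dataset(sim_config(n_cells = 12, n_snvs = 400, seed = 71))
  d <- sim$truth$data
  cfg <- search_config(seed = 5, spr_radius = 5, max_outer = 3)
  model_cfg <- parse_model_string("GT16+FC")
  # start from the true tree on error-free data: no harm
  start_ll <- tree_loglikelihood(
    sim$tree, build_tip_clvs(d, error_params(), FALSE),
    build_gt16_rate_matrix(
      substitution_params(frequencies = scphylo:::empirical_frequencies(d, 16),
                          frequency_mode = "empirical")))$loglik
  res <- spr_search(sim$tree, d, model_cfg, cfg)
  expect_gte(res$loglik, start_ll)
  expect_lte(nrf_distance(res$tree, sim$tree), 0)
  # determinism: same seed, same everything
  res2 <- spr_search(sim$tree, d, model_cfg, cfg)
  expect_equal(res2$loglik, res$loglik)
  expect_equal(topology_key(res2$tree), topology_key(res$tree))
})

test_that("tree specifier strings are parsed like the command line", {
  expect_equal(scphylo:::parse_tree_spec("pars{2}", NULL)$pars, 2L)
  expect_equal(scphylo:::parse_tree_spec("pars{1},rand{3}", NULL)$rand, 3L)
  expect_error(scphylo:::parse_tree_spec("foo{1}", NULL), "specifier")
})
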