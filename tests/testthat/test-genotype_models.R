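test_that("genotype alphabet has the expected structure", {
  ab <- genotype_alphabet()
  expect_length(ab$phased_states, 16)
  expect_length(ab$unphased_states, 10)
  u2p <- scphylo:::unphased_to_phased()
  hets <- lengths(u2p)
  expect_equal(sort(hets), c(rep(1, 4), rep(2, 6)))
  # char_codes is an invertible map, missing is not a code
  expect_equal(length(unique(ab$char_codes)), 10)
  expect_false(ab$missing_code %in% names(ab$char_codes))
  idx <- decode_genotypes(c("A", "M", "k", "?", "n"))
  expect_equal(encode_genotypes(idx), c("A", "M", "K", "?", "?"))
  expect_error(decode_genotypes("X"), "illegal")
})

test_that("GT16 rate matrix follows the single-allele-change construction", {
  m <- build_gt16_rate_matrix(substitution_params())
  expect_lt(max(abs(rowSums(m$Q))), 1e-10)
  # with equal inputs, every admissible off-diagonal entry is equal and
  # there are 48 symmetric nonzero pairs
  off <- m$Q[row(m$Q) != col(m$Q)]
  nz <- off[off > 0]
  expect_length(nz, 96)
  expect_equal(max(nz), min(nz))
  # a double-allele change is impossible in an instant
  expect_equal(m$Q["A|A", "C|G"], 0)
  expect_equal(m$Q["A|C", "C|A"], 0)
  # exchangeability ratio propagates: alpha doubled
  m2 <- build_gt16_rate_matrix(substitution_params(exchangeabilities = c(2, 1, 1, 1, 1)))
  expect_equal(m2$Q["A|A", "A|C"] / m2$Q["A|A", "A|G"], 2)
  # detailed balance and stationarity
  flux <- diag(m$pi) %*% m$Q
  expect_lt(max(abs(flux - t(flux))), 1e-10)
  expect_lt(max(abs(m$pi %*% m$Q)), 1e-10)
  # unit expected rate at stationarity
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  expect_error(substitution_params(exchangeabilities = c(-1, 1, 1, 1, 1)))
  expect_error(substitution_params(frequencies = rep(0.1, 16)))
})

test_that("GT10 rate matrix is a valid reversible 10-state model", {
  m <- build_gt10_rate_matrix(substitution_params(frequencies = rep(1 / 10, 10)))
  expect_equal(nrow(m$Q), 10)
  expect_lt(max(abs(rowSums(m$Q))), 1e-10)
  flux <- diag(m$pi) %*% m$Q
  expect_lt(max(abs(flux - t(flux))), 1e-10)
})

test_that("GT10 and GT16 give close log-likelihoods on error-free unphased data", {
  set.seed(42)
  sim <- simulate_dataset(sim_config(n_cells = 8, n_snvs = 150, seed = 8))
  tips <- build_tip_clvs(sim$truth$data, error_params(), FALSE)
  tr <- starting_tree_random(sim$truth$data$cells, seed = 1)
  l16 <- tree_loglikelihood(tr, tips, build_gt16_rate_matrix())$loglik
  l10 <- tree_loglikelihood(tr, tips,
                            build_gt10_rate_matrix(substitution_params(frequencies = rep(0.1, 10))))$loglik
  expect_lt(abs(l16 - l10) / abs(l16), 0.1)
})

test_that("transition probabilities are stochastic and correct", {
  m <- build_gt16_rate_matrix(substitution_params(exchangeabilities = c(2, 1.5, 0.8, 1.2, 3)))
  expect_equal(transition_probabilities(m, 0), diag(16), ignore_attr = TRUE)
  p <- transition_probabilities(m, 0.1)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
  expect_true(all(p >= 0))
  # independent scaling-and-squaring Taylor oracle
  expect_lt(max(abs(p - taylor_expm(m$Q, 0.1))), 1e-8)
  # stationarity limit
  pinf <- transition_probabilities(m, 1e4)
  expect_lt(max(abs(sweep(pinf, 2, m$pi))), 1e-6)
  # Chapman-Kolmogorov on a grid
  for (ts in list(c(0.05, 0.3), c(1, 2), c(0.001, 0.1))) {
    expect_lt(max(abs(transition_probabilities(m, sum(ts)) -
                        transition_probabilities(m, ts[1]) %*%
                        transition_probabilities(m, ts[2]))), 1e-8)
  }
  # time reversibility of P(t)
  f <- diag(m$pi) %*% p
  expect_lt(max(abs(f - t(f))), 1e-12)
  expect_error(transition_probabilities(m, -0.1), "must be")
})

test_that("GTnR matrix is built as specified", {
  q <- build_gtnr_matrix(gtnr_signature1_rates())
  expect_equal(q$Q["G", "A"] * q$scaling, 6.68)
  expect_equal(q$Q["C", "T"] * q$scaling, 0.68)
  expect_lt(max(abs(rowSums(q$Q))), 1e-10)
  expect_error(build_gtnr_matrix(rep(-1, 12)))
  # equal rates reduce to Jukes-Cantor: closed form
  jc <- build_gtnr_matrix(rep(1, 12))
  expect_equal(jc$pi, rep(0.25, 4), tolerance = 1e-12, ignore_attr = TRUE)
  for (t in c(0.05, 0.5, 5)) {
    p <- transition_probabilities(jc, t)
    expect_equal(p[1, 1], 0.25 + 0.75 * exp(-4 / 3 * t), tolerance = 1e-8)
    expect_equal(p[1, 2], 0.25 - 0.25 * exp(-4 / 3 * t), tolerance = 1e-8)
  }
  expect_lt(max(abs(transition_probabilities(jc, 100) - 0.25)), 1e-9)
})

test_that("model strings parse like the command-line flags", {
  expect_equal(parse_model_string("GT16+FO"),
               list(n_states = 16L, frequency_mode = "optimized", error_model = FALSE))
  expect_true(parse_model_string("GT16+FO+E")$error_model)
  expect_equal(parse_model_string("GT10+FO+E")$n_states, 10L)
  expect_equal(parse_model_string("GT16+FE")$frequency_mode, "equal")
  expect_error(parse_model_string("GTR+FO"), "unknown model")
  expect_error(parse_model_string("GT16+XX"), "flag")
})
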