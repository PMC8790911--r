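test_that("bootstrap replicates resample sites jointly with the right statistics", {
  set.seed(14)
  sim <- simulate_dataset(sim_config(n_cells = 6, n_snvs = 30, seed = 44))
  d <- sim$truth$data
  reps <- bootstrap_replicates(d, 10, seed = 3)
  expect_length(reps, 10)
  for (r in reps) expect_equal(dim(r$genotypes), dim(d$genotypes))
  expect_identical(bootstrap_replicates(d, 3, seed = 9)[[2]]$genotypes,
                   bootstrap_replicates(d, 3, seed = 9)[[2]]$genotypes)
  # expected multiplicity of each original column is 1 (3 sigma over 1000)
  n <- 1000
  counts <- matrix(0, n, 30)
  reps <- bootstrap_replicates(d, n, seed = 5)
  for (i in seq_len(n)) {
    counts[i, ] <- tabulate(attr(reps[[i]], "indices"), nbins = 30)
  }
  mean_mult <- colMeans(counts)
  se <- sqrt((29 / 30) / n)              # per-column Binomial(30, 1/30) mean
  expect_true(all(abs(mean_mult - 1) <= 3.5 * se))
  gl <- array(rnorm(6 * 30 * 10), dim = c(6, 30, 10))
  dgl <- genotype_data(gl = gl)
  r <- bootstrap_replicates(dgl, 1, seed = 1)[[1]]
  expect_equal(r$gl[, 1, ], gl[, attr(r, "indices")[1], ])
  expect_error(bootstrap_replicates(d, 0), "n >= 1")
})

test_that("standard bootstrap support counts exact bipartition matches", {
  ml <- ape::read.tree(text = "((a,b),(c,d),e);")
  same <- list(ml, ml, ml)
  fs <- felsenstein_support(ml, same)
  expect_equal(fs$support$support, rep(100, nrow(fs$support)))
  other <- ape::read.tree(text = "((a,c),(b,d),e);")
  fs0 <- felsenstein_support(ml, list(other, other))
  expect_equal(fs0$support$support, rep(0, nrow(fs0$support)))
  # hand-checkable 5-taxon case vs exhaustive counting
  bs <- list(ape::read.tree(text = "((a,b),(c,d),e);"),
             ape::read.tree(text = "((a,b),(c,e),d);"),
             ape::read.tree(text = "((a,c),(b,d),e);"))
  fs <- felsenstein_support(ml, bs)
  # branch {a,b}: present in replicates 1 and 2 -> 66.7; branch {c,d}: only 1
  ab <- fs$support$support[fs$support$bipartition == bipartition_key_for(ml, c("a", "b"))]
  expect_equal(ab, 200 / 3)
  cd <- fs$support$support[fs$support$bipartition == bipartition_key_for(ml, c("c", "d"))]
  expect_equal(cd, 100 / 3)
  expect_error(felsenstein_support(ml, list(ape::rtree(4))), "do not match")
})

test_that("transfer support bounds, equalities and hand examples hold", {
  ml <- ape::read.tree(text = "((a,b),(c,d),e);")
  ts <- transfer_support(ml, list(ml, ml))
  expect_equal(ts$support$support, rep(100, nrow(ts$support)))
  # transfer >= standard on random trees, both in [0, 100]
  set.seed(6)
  for (i in 1:8) {
    ml6 <- starting_tree_random(letters[1:6], seed = 50 + i)
    bs6 <- lapply(1:5, function(j) starting_tree_random(letters[1:6], seed = 60 + 10 * i + j))
    f <- felsenstein_support(ml6, bs6)$support
    t <- transfer_support(ml6, bs6)$support
    m <- merge(f, t, by = "bipartition")
    expect_true(all(m$support.y >= m$support.x - 1e-9))
    expect_true(all(t$support >= 0 & t$support <= 100))
  }
  # p = 5 branch with a single-taxon transfer in every replicate: 1 - 1/4
  ml10 <- ape::read.tree(text = "(((((a,b),c),d),e),(f,(g,(h,(i,j)))));")
  bs10 <- ape::read.tree(text = "(((((a,b),c),d),f),(e,(g,(h,(i,j)))));")
  tt <- transfer_support(ape::unroot(ml10), list(ape::unroot(bs10)))
  key5 <- bipartition_key_for(ml10, c("a", "b", "c", "d", "e"))
  expect_equal(tt$support$support[tt$support$bipartition == key5], 75)
  # a cherry (p = 2) absent from the replicate scores 0 under both measures
  mlc <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  bsc <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  tc <- transfer_support(mlc, list(bsc))
  keyab <- bipartition_key_for(mlc, c("a", "b"))
  expect_equal(tc$support$support[tc$support$bipartition == keyab], 0)
})

test_that("nRF distance matches hand counts and an independent implementation", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_equal(nrf_distance(t1, t1), 0)
  expect_equal(nrf_distance(t1, t2), 1)   # RF = 4, denominator = 4
  # symmetric
  expect_equal(nrf_distance(t2, t1), nrf_distance(t1, t2))
  # 5-taxon trees sharing no bipartition
  t3 <- ape::read.tree(text = "((a,d),(b,e),c);")
  expect_equal(nrf_distance(t1, t3), 1)
  expect_error(nrf_distance(t1, ape::read.tree(text = "((a,b),(c,x),e);")),
               "different taxon sets")
  expect_error(nrf_distance(ape::read.tree(text = "(a,b,c);"),
                            ape::read.tree(text = "(a,b,c);")), "at least 4")
  # agreement with phangorn on random binary pairs: absolute RF equals
  # nrf * (2 * (n - 3)) for binary trees
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    a <- starting_tree_random(paste0("t", 1:n), seed = 70 + i)
    b <- starting_tree_random(paste0("t", 1:n), seed = 90 + i)
    rf_ph <- phangorn::RF.dist(a, b)
    expect_equal(nrf_distance(a, b) * 2 * (n - 3), rf_ph)
  }
  # multifurcations reduce the denominator
  m1 <- ape::read.tree(text = "((a,b),c,d,e);")      # one internal branch
  m2 <- ape::read.tree(text = "((a,c),(b,d),e);")    # two internal branches
  expect_equal(nrf_distance(m1, m2), 1)               # 3 unshared / 3 total
  expect_equal(nrf_distance(m1, ape::read.tree(text = "((a,b),(c,d),e);")),
               1 / 3)                                 # shares {a,b}: (0+1)/3
})
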