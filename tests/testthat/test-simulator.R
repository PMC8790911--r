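test_that("coalescent genealogy has the designed structure", {
  set.seed(2)
  cfg <- sim_config(n_cells = 10, seed = 7)
  gen <- simulate_genealogy(cfg)
  expect_equal(sort(gen$tree$tip.label),
               sort(c(paste0("cell", 1:10), "healthy")))
  # outgroup branch length zero: healthy sits at the MRCA
  og_edge <- gen$tree$edge.length[gen$tree$edge[, 2] ==
                                    which(gen$tree$tip.label == "healthy")]
  expect_equal(og_edge, 0)
  # degenerate Gamma (shape -> Inf) keeps the ingroup ultrametric
  cfg2 <- sim_config(n_cells = 8, branch_rate_gamma_shape = Inf, seed = 9)
  gen2 <- simulate_genealogy(cfg2)
  ing <- ape::drop.tip(gen2$tree, "healthy")
  depths <- ape::node.depth.edgelength(ing)[1:ape::Ntip(ing)]
  expect_lt(max(depths) - min(depths), 1e-9)
  # n = 2, no growth: mean pairwise coalescent time matches the
  # constant-size expectation of 1 (units of 2N generations)
  cfg3 <- sim_config(n_cells = 2, growth_rate = 0, root_branch = 0,
                     branch_rate_gamma_shape = Inf, seed = 1)
  set.seed(33)
  times <- replicate(4000, simulate_genealogy(cfg3)$mrca_height)
  expect_lt(abs(mean(times) - 1), 3 / sqrt(4000))  # sd of Exp(1) is 1
})

test_that("infinite-site mutations land once per site, proportionally to length", {
  set.seed(5)
  cfg <- sim_config(n_cells = 10, n_snvs = 250, seed = 13)
  sim <- simulate_dataset(cfg)
  d <- sim$truth$data
  gm <- d$genotypes
  al10 <- gt10_alleles()
  is_het <- matrix(al10[gm, 1] != al10[gm, 2], nrow(gm), ncol(gm))
  # exactly the requested number of variant sites, each polymorphic or
  # shared-heterozygous (stem)
  expect_equal(ncol(gm), 250)
  expect_true(all(colSums(is_het) > 0))
  # stem mutations are heterozygous in every cell (healthy included)
  stem_sites <- sim$truth$truth$branch == "stem"
  if (any(stem_sites)) {
    expect_true(all(is_het[, stem_sites]))
  }
  # outgroup genotypes match the MRCA state: heterozygous only at stem sites
  healthy <- which(rownames(gm) == "healthy")
  expect_equal(unname(is_het[healthy, ]), unname(stem_sites))
  # refusing more SNVs than genome sites
  gen <- simulate_genealogy(cfg)
  expect_error(simulate_mutations_ism(gen, 100, n_genome_sites = 50), "only 50")
  # branch assignment frequencies proportional to branch lengths
  set.seed(6)
  gen2 <- simulate_genealogy(sim_config(n_cells = 6, seed = 21))
  mu <- simulate_mutations_ism(gen2, 8000)
  phy <- ape::reorder.phylo(gen2$tree, "postorder")
  lens <- c(phy$edge.length, gen2$stem_length)
  labs <- c(vapply(seq_len(nrow(phy$edge)), function(k) {
    ch <- phy$edge[k, 2]
    if (ch <= ape::Ntip(phy)) phy$tip.label[ch] else paste0("node", ch - ape::Ntip(phy))
  }, ""), "stem")
  obs <- table(factor(mu$truth$branch, levels = labs))
  keep <- lens > 0
  p <- lens[keep] / sum(lens[keep])
  pv <- suppressWarnings(stats::chisq.test(obs[keep], p = p)$p.value)
  expect_gt(pv, 0.001)
})

test_that("finite-site simulation respects the mutation process", {
  set.seed(3)
  gen <- simulate_genealogy(sim_config(n_cells = 8, mutation_model = "gtnr", seed = 41))
  # mu = 0: everyone identical to the root
  gen0 <- gen
  gen0$tree$edge.length <- gen0$tree$edge.length * 0
  gen0$stem_length <- 0
  mu0 <- simulate_mutations_finite(gen0, n_sites = 300)
  expect_equal(mu0$n_true_snvs, 0)
  # substitution spectrum of the simulator's jump-chain sampler matches the
  # matrix-exponential route exactly: counts of (root base -> tip base)
  # changes follow pi_i * P_ij(t), with G->A dominant under signature-1 rates
  q <- build_gtnr_matrix(gtnr_signature1_rates())
  nuc <- c("A", "C", "G", "T")
  t <- 0.05
  gen1 <- list(tree = ape::read.tree(text = sprintf(
    "(cell1:%g,cell2:%g,healthy:0);", t, t)), stem_length = 0)
  set.seed(8)
  mu <- simulate_mutations_finite(gen1, dna_model = q, n_sites = 120000,
                                  site_rate_gamma_shape = Inf)
  ref <- match(mu$ref, nuc)
  tip1 <- mu$haplotypes[1, , 1]          # one haplotype of cell1
  chg <- ref != tip1
  types <- paste(nuc[ref[chg]], nuc[tip1[chg]], sep = ">")
  tab <- sort(table(types), decreasing = TRUE)
  expect_equal(names(tab)[1], "G>A")
  p <- transition_probabilities(q, t)
  expectm <- q$pi * p                    # joint (start, end) probabilities
  diag(expectm) <- 0
  lab <- as.vector(t(outer(nuc, nuc, paste, sep = ">")))
  expectp <- as.vector(t(expectm))
  keep <- expectp > 0
  obs <- as.vector(table(factor(types, levels = lab[keep])))
  pv <- suppressWarnings(
    stats::chisq.test(obs, p = expectp[keep] / sum(expectp[keep]))$p.value)
  expect_gt(pv, 0.001)
})

test_that("finite-site benchmark settings yield on the order of 2000 true SNVs", {
  set.seed(17)
  counts <- vapply(1:5, function(r) {
    gen <- simulate_genealogy(sim_config(n_cells = 100, mutation_model = "gtnr",
                                         seed = 500 + r))
    simulate_mutations_finite(gen, n_sites = 10000)$n_true_snvs
  }, 0)
  expect_gt(mean(counts), 1000)
  expect_lt(mean(counts), 4000)
})

test_that("genotype-level errors behave like the observation kernel", {
  set.seed(10)
  sim <- simulate_dataset(sim_config(n_cells = 8, n_snvs = 200, seed = 77))
  d <- sim$truth$data
  expect_identical(apply_genotype_errors(d, 0, 0)$genotypes, d$genotypes)
  # delta = 1: no heterozygote survives
  al10 <- gt10_alleles()
  forced <- apply_genotype_errors(d, 1, 0)$genotypes
  expect_true(all(al10[forced, 1] == al10[forced, 2]))
  # the het -> hom conversion rate matches delta (3 sigma, binomial)
  delta <- 0.3
  gm <- matrix(rep(2L, 1e5), 1, 1e5,     # all A/C heterozygotes
               dimnames = list("c1", NULL))
  dd <- genotype_data(genotypes = gm)
  obs <- apply_genotype_errors(dd, delta, 0)$genotypes
  hom <- mean(al10[obs, 1] == al10[obs, 2])
  expect_lt(abs(hom - delta), 3 * sqrt(delta * (1 - delta) / 1e5))
})

test_that("read simulation matches depth and calling expectations", {
  set.seed(44)
  gm <- matrix(rep(2L, 400), 2, 200, dimnames = list(c("a", "b"), NULL))  # A/C
  d <- genotype_data(genotypes = gm)
  # enormous depth, no errors: calls recover the truth everywhere
  rd <- simulate_reads(d, depth = 2000, overdispersion = 1e6)
  expect_true(all(rd$ml_data$genotypes == gm))
  # mean depth ~ 5 without ADO, ~ 2.5 with forced ADO
  rd5 <- simulate_reads(d, depth = 5, overdispersion = 2, delta = 0)
  expect_lt(abs(mean(apply(rd5$read_counts, c(1, 2), sum)) - 5), 0.6)
  rda <- simulate_reads(d, depth = 5, overdispersion = 2, delta = 1)
  expect_lt(abs(mean(apply(rda$read_counts, c(1, 2), sum)) - 2.5), 0.5)
  expect_true(all(rda$ado))
  # the true genotype ranks top-1 more often at 30x than at 5x
  set.seed(45)
  sim <- simulate_dataset(sim_config(n_cells = 6, n_snvs = 300, seed = 91))
  truth <- sim$truth$data
  top1 <- function(depth) {
    rd <- simulate_reads(truth, depth = depth, overdispersion = 2,
                         amplification_error = 0.05, sequencing_error = 0.01,
                         delta = 0.1)
    mean(rd$ml_data$genotypes == truth$genotypes, na.rm = TRUE)
  }
  expect_gt(top1(30), top1(5))
})

test_that("doublet injection merges cells as specified", {
  gm <- matrix(c(1L, 1L, 5L, 5L), 2, 2, byrow = FALSE,
               dimnames = list(c("a", "b"), NULL))   # a: A/A,A/A; b: C/C,C/C
  d <- genotype_data(genotypes = gm)
  expect_identical(inject_doublets(d, 0)$genotypes, d$genotypes)
  set.seed(3)
  merged <- inject_doublets(d, 1)
  # pooled alleles {A,A,C,C}: sampled diploid genotype is A/A, A/C or C/C,
  # and with rate 1 both cells are replaced
  expect_true(all(merged$genotypes %in% c(1L, 2L, 5L)))
  expect_equal(nrow(attr(merged, "doublets")), 2)
  expect_error(inject_doublets(genotype_data(genotypes = gm[1, , drop = FALSE]), 0.5),
               "at least 2")
  # doublet count is binomial in the rate (3 sigma)
  set.seed(9)
  n <- 400; nc <- 20; rate <- 0.2
  gm2 <- matrix(sample(1:10, nc * 5, replace = TRUE), nc, 5,
                dimnames = list(paste0("c", 1:nc), NULL))
  d2 <- genotype_data(genotypes = gm2)
  cnt <- vapply(seq_len(n), function(i) nrow(attr(inject_doublets(d2, rate), "doublets")), 0)
  expect_lt(abs(mean(cnt) - rate * nc),
            3 * sqrt(nc * rate * (1 - rate) / n))
})
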