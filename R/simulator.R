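# Benchmark data generator: coalescent genealogies from an exponentially
# growing population, true diploid genotypes under infinite-site or
# finite-site (GTnR) mutation, observed genotypes with ADO and
# amplification/sequencing error, overdispersed read counts with genotype
# likelihoods, and cell doublets. Every simulation records its ground
# truth, which the inference tests consume.

#' Simulation configuration
#'
#' Defaults follow the benchmark design: cells sampled from an
#' exponentially growing population (rate 1e-4 per generation, present-day
#' effective size 10,000), a root branch of 0.1 (coalescent units) above
#' the ingroup MRCA whose mutations are shared by all cells, a healthy
#' outgroup cell attached at the MRCA with branch length zero (identical
#' genotypes to the MRCA), branch-rate Gamma multipliers with mean 1, and a
#' mutation rate of 1e-6 per site per generation for finite-site runs.
#'
#' @param n_cells number of sampled (ingroup) cells.
#' @param effective_size present-day effective population size N.
#' @param growth_rate exponential growth rate per generation.
#' @param root_branch root (stem) branch length above the MRCA, coalescent
#'   units (2N generations).
#' @param outgroup_branch outgroup branch length (coalescent units).
#' @param branch_rate_gamma_shape shape of the mean-1 Gamma branch-rate
#'   multipliers; `Inf` disables rate variation.
#' @param mutation_model `"ism"` or `"gtnr"` (finite-site).
#' @param n_snvs number of SNVs for ISM runs.
#' @param n_sites genome size for finite-site runs.
#' @param mutation_rate per-site per-generation mutation rate.
#' @param site_rate_gamma_shape shape of mean-1 Gamma site-rate multipliers
#'   (finite-site only); `Inf` disables.
#' @param delta ADO rate applied to observations.
#' @param genotype_error amplification/sequencing error rate applied to
#'   observed genotypes (genotype-observation route).
#' @param observation `"genotype"` (errors added directly to genotypes) or
#'   `"reads"` (read counts simulated, genotypes called by ML).
#' @param depth mean sequencing depth (reads route).
#' @param depth_overdispersion negative-binomial size parameter.
#' @param amplification_error,sequencing_error per-read error rates (reads
#'   route).
#' @param doublet_rate fraction of cells replaced by doublets.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 40, effective_size = 1e4, growth_rate = 1e-4,
                       root_branch = 0.1, outgroup_branch = 0,
                       branch_rate_gamma_shape = 5,
                       mutation_model = c("ism", "gtnr"),
                       n_snvs = 1000, n_sites = 10000, mutation_rate = 1e-6,
                       site_rate_gamma_shape = 1,
                       delta = 0, genotype_error = 0,
                       observation = c("genotype", "reads"),
                       depth = 5, depth_overdispersion = 2,
                       amplification_error = 0, sequencing_error = 0,
                       doublet_rate = 0, seed = 1) {
  mutation_model <- match.arg(mutation_model)
  observation <- match.arg(observation)
  stopifnot(n_cells >= 2, effective_size > 0, growth_rate >= 0,
            root_branch >= 0, outgroup_branch >= 0,
            delta >= 0, delta <= 1, genotype_error >= 0, genotype_error <= 1,
            depth > 0, doublet_rate >= 0, doublet_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a coalescent cell genealogy
#'
#' Coalescent under exponential growth, with the stem (root) branch
#' prepended, a zero-length healthy outgroup attached at the MRCA, and
#' independent Gamma(shape, shape) rate multipliers on every branch.
#' Branch lengths of the returned tree are in expected mutations per site
#' (coalescent time in units of 2N generations times `2N *
#' mutation_rate`); the unscaled coalescent-time tree is also returned.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (mutation-unit `ape::phylo`, tips `cell1..N` +
#'   `healthy`), `coal_tree` (coalescent units, before rate multipliers),
#'   `stem_length` (mutation units) and `scale` (mutation units per
#'   coalescent unit).
#' @export
simulate_genealogy <- function(config) {
  n <- config$n_cells
  alpha <- 2 * config$effective_size * config$growth_rate
  # coalescent node heights (units of 2N generations)
  active <- seq_len(n)
  height <- numeric(2 * n - 1)
  parent <- integer(2 * n - 1)
  child1 <- integer(2 * n - 1); child2 <- integer(2 * n - 1)
  tau <- 0; nxt <- n + 1L
  while (length(active) > 1) {
    k <- length(active)
    cr <- k * (k - 1) / 2
    u <- stats::runif(1)
    dt <- if (alpha > 0) {
      log(exp(alpha * tau) - alpha * log(u) / cr) / alpha - tau
    } else {
      -log(u) / cr
    }
    tau <- tau + dt
    pair <- sample(length(active), 2)
    a <- active[pair[1]]; b <- active[pair[2]]
    height[nxt] <- tau
    parent[a] <- nxt; parent[b] <- nxt
    child1[nxt] <- a; child2[nxt] <- b
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  root <- nxt - 1L
  shape <- config$branch_rate_gamma_shape
  mult <- function(k = 1) {
    if (is.infinite(shape)) rep(1, k) else stats::rgamma(k, shape = shape, rate = shape)
  }
  scale <- 2 * config$effective_size * config$mutation_rate
  # newick with per-branch multipliers applied (mutation units)
  desc <- function(v) {
    len <- (height[parent[v]] - height[v]) * mult() * scale
    if (v <= n) {
      sprintf("cell%d:%.12g", v, len)
    } else {
      sprintf("(%s,%s):%.12g", desc(child1[v]), desc(child2[v]), len)
    }
  }
  og_len <- config$outgroup_branch * mult() * scale
  nwk <- sprintf("(%s,%s,healthy:%.12g);", desc(child1[root]), desc(child2[root]), og_len)
  tree <- ape::read.tree(text = nwk)
  desc_coal <- function(v) {
    if (v <= n) {
      sprintf("cell%d:%.12g", v, height[parent[v]] - height[v])
    } else {
      sprintf("(%s,%s):%.12g", desc_coal(child1[v]), desc_coal(child2[v]),
              height[parent[v]] - height[v])
    }
  }
  coal <- ape::read.tree(text = sprintf("(%s,%s,healthy:%.12g);",
                                        desc_coal(child1[root]),
                                        desc_coal(child2[root]),
                                        config$outgroup_branch))
  list(tree = tree, coal_tree = coal,
       stem_length = config$root_branch * mult() * scale,
       scale = scale, mrca_height = tau)
}

# tips below each edge (rows of phy$edge), as a list of tip index vectors
edge_descendants <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(phy)
  below <- vector("list", ntip + phy$Nnode)
  for (v in seq_len(ntip)) below[[v]] <- v
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  list(phy = phy, below = below)
}

#' Simulate mutations under the diploid infinite-site model
#'
#' Each SNV mutates exactly once: on a branch drawn with probability
#' proportional to branch length (the stem branch included), on the
#' maternal or paternal allele with probability 1/2, from a uniformly drawn
#' reference base to a uniformly drawn alternative. Cells below the branch
#' are heterozygous at that site; all others are homozygous reference.
#'
#' @param sim result of [simulate_genealogy()].
#' @param n_snvs number of variant sites.
#' @param n_genome_sites optional genome size cap (reject if `n_snvs`
#'   exceeds it).
#' @return list with `data` (true genotypes as a GT-mode
#'   [genotype_data()]) and `truth` (per-site branch, haplotype, ref, alt).
#' @export
simulate_mutations_ism <- function(sim, n_snvs, n_genome_sites = NULL) {
  if (!is.null(n_genome_sites) && n_snvs > n_genome_sites) {
    stop("requested ", n_snvs, " SNVs but the genome has only ",
         n_genome_sites, " sites")
  }
  ed <- edge_descendants(sim$tree)
  phy <- ed$phy
  ntip <- ape::Ntip(phy)
  lens <- c(phy$edge.length, sim$stem_length)
  nb <- length(lens)
  branch <- sample.int(nb, n_snvs, replace = TRUE, prob = lens)
  hap <- sample.int(2, n_snvs, replace = TRUE)
  refb <- sample.int(4, n_snvs, replace = TRUE)
  altb <- vapply(refb, function(r) sample(setdiff(1:4, r), 1), 0L)
  al10 <- gt10_alleles()
  hom_idx <- vapply(1:4, function(a) which(al10[, 1] == a & al10[, 2] == a), 0L)
  het_idx <- matrix(0L, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    p <- sort(c(a, b))
    het_idx[a, b] <- which(al10[, 1] == p[1] & al10[, 2] == p[2])
  }
  gm <- matrix(0L, ntip, n_snvs)
  for (i in seq_len(n_snvs)) {
    gm[, i] <- hom_idx[refb[i]]
    tips <- if (branch[i] > nrow(phy$edge)) seq_len(ntip) else
      ed$below[[phy$edge[branch[i], 2]]]
    gm[tips, i] <- het_idx[refb[i], altb[i]]
  }
  rownames(gm) <- phy$tip.label
  nuc <- c("A", "C", "G", "T")
  sites <- paste0("snv", seq_len(n_snvs))
  colnames(gm) <- sites
  branch_label <- vapply(branch, function(b) {
    if (b > nrow(phy$edge)) return("stem")
    ch <- phy$edge[b, 2]
    if (ch <= ntip) phy$tip.label[ch] else paste0("node", ch - ntip)
  }, "")
  list(data = genotype_data(genotypes = gm, ref = nuc[refb], alt = nuc[altb]),
       truth = data.frame(site = sites, branch = branch_label,
                          haplotype = hap, ref = nuc[refb], alt = nuc[altb]))
}

#' Simulate mutations under the finite-site GTnR model
#'
#' Both alleles evolve independently along the genealogy under the
#' (generally non-reversible) DNA rate matrix, scaled by the branch lengths
#' (expected mutations per site) and per-site Gamma rate multipliers;
#' multiple hits are allowed. Simulation uses the uniformization (jump
#' chain) representation of the Markov process, which is exact.
#'
#' @param sim result of [simulate_genealogy()].
#' @param dna_model a `gtnr_matrix` from [build_gtnr_matrix()].
#' @param n_sites genome size.
#' @param site_rate_gamma_shape mean-1 Gamma shape for site rates (`Inf`
#'   disables).
#' @return list with `data` (true genotypes), `ref` (root base per site),
#'   `n_true_snvs` (sites where any cell differs from homozygous
#'   reference), and the per-haplotype base matrices.
#' @export
simulate_mutations_finite <- function(sim, dna_model = build_gtnr_matrix(gtnr_signature1_rates()),
                                      n_sites = 10000,
                                      site_rate_gamma_shape = 1) {
  phy <- ape::reorder.phylo(sim$tree, "postorder")
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  q <- dna_model$Q
  omega <- max(-diag(q))
  jump <- diag(4) + q / omega            # row-stochastic jump matrix
  rates <- if (is.infinite(site_rate_gamma_shape)) rep(1, n_sites) else
    stats::rgamma(n_sites, shape = site_rate_gamma_shape, rate = site_rate_gamma_shape)
  evolve <- function(states, t) {
    if (t <= 0) return(states)
    k <- stats::rpois(n_sites, omega * t * rates)
    for (i in which(k > 0)) {
      st <- states[i]
      for (j in seq_len(k[i])) st <- sample.int(4, 1, prob = jump[st, ])
      states[i] <- st
    }
    states
  }
  root <- ntip + 1L
  ref <- sample.int(4, n_sites, replace = TRUE, prob = dna_model$pi)
  hap <- array(0L, dim = c(ntot, n_sites, 2))
  for (h in 1:2) hap[root, , h] <- evolve(ref, sim$stem_length)
  for (k in rev(seq_len(nrow(phy$edge)))) {   # preorder
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    for (h in 1:2) hap[ch, , h] <- evolve(hap[par, , h], phy$edge.length[k])
  }
  al10 <- gt10_alleles()
  g10 <- matrix(0L, 4, 4)
  for (j in 1:10) {
    g10[al10[j, 1], al10[j, 2]] <- j
    g10[al10[j, 2], al10[j, 1]] <- j
  }
  gm <- matrix(g10[cbind(as.vector(hap[seq_len(ntip), , 1]),
                         as.vector(hap[seq_len(ntip), , 2]))],
               ntip, n_sites)
  rownames(gm) <- phy$tip.label
  colnames(gm) <- paste0("site", seq_len(n_sites))
  nuc <- c("A", "C", "G", "T")
  hom_ref <- vapply(seq_len(n_sites), function(i) g10[ref[i], ref[i]], 0L)
  variable <- colSums(gm != rep(hom_ref, each = ntip)) > 0
  list(data = genotype_data(genotypes = gm, ref = nuc[ref]),
       ref = nuc[ref], n_true_snvs = sum(variable), variable = variable,
       haplotypes = hap[seq_len(ntip), , , drop = FALSE])
}

# 10x10 observation kernel on unphased genotypes, rows = true
unphased_error_kernel <- function(params) {
  k16 <- genotype_error_kernel(params)
  u2p <- unphased_to_phased()
  k10 <- matrix(0, 10, 10, dimnames = list(gt10_states(), gt10_states()))
  for (x in 1:10) {
    row <- k16[u2p[[x]][1], ]            # either phasing: symmetric
    for (y in 1:10) k10[x, y] <- sum(row[u2p[[y]]])
  }
  k10
}

#' Add ADO and amplification/sequencing errors to true genotypes
#'
#' Each cell/site genotype is independently replaced by a draw from the
#' observation kernel with the given ADO rate `delta` and error rate: with
#' probability `delta` one random allele drops (the observed genotype is
#' the surviving homozygote) and at most one allele may additionally be
#' misread. Missing entries stay missing.
#'
#' @param data GT-mode [genotype_data()] of true genotypes.
#' @param delta ADO rate.
#' @param error_rate amplification/sequencing error rate.
#' @return a [genotype_data()] of observed genotypes.
#' @export
apply_genotype_errors <- function(data, delta, error_rate) {
  stopifnot(inherits(data, "genotype_data"), !is.null(data$genotypes))
  if (delta == 0 && error_rate == 0) return(data)
  k10 <- unphased_error_kernel(error_params(delta, error_rate))
  gm <- data$genotypes
  out <- gm
  for (j in 1:10) {
    sel <- which(gm == j)
    if (!length(sel)) next
    out[sel] <- sample.int(10, length(sel), replace = TRUE, prob = k10[j, ])
  }
  res <- data
  res$genotypes <- out
  res
}

#' Simulate NGS read counts, genotype likelihoods and ML genotype calls
#'
#' Per cell and site: ADO is applied first (probability `delta`, one
#' random allele drops); total depth is negative-binomial with the
#' configured mean (halved when one allele dropped) and dispersion; each
#' read originates from a surviving allele with equal probability and is
#' then subjected to amplification and sequencing error (independent
#' uniform miscalls). Genotype log10-likelihoods for the ten unphased
#' genotypes use a symmetric per-read error model with total error rate
#' `min(amplification + sequencing, 0.75)`; the ML genotype is called per
#' site, ties broken uniformly at random. Zero-depth sites are missing.
#'
#' @param data GT-mode [genotype_data()] of true genotypes.
#' @param depth mean sequencing depth.
#' @param overdispersion negative-binomial size parameter.
#' @param amplification_error,sequencing_error per-read error rates.
#' @param delta ADO rate.
#' @return list with `read_counts` (cells x sites x 4), `gl_data` (GL-mode
#'   [genotype_data()]), `ml_data` (called genotypes, GT mode), `ado`
#'   (logical matrix of dropout events).
#' @export
simulate_reads <- function(data, depth = 5, overdispersion = 2,
                           amplification_error = 0, sequencing_error = 0,
                           delta = 0) {
  stopifnot(inherits(data, "genotype_data"), !is.null(data$genotypes))
  gm <- data$genotypes
  nc <- nrow(gm); ns <- ncol(gm)
  al10 <- gt10_alleles()
  err_read <- min(amplification_error + sequencing_error, 0.75)
  # log10 P(read base | true allele) table: 4 alleles x 4 bases
  pmatch_ <- matrix(err_read / 3, 4, 4)
  diag(pmatch_) <- 1 - err_read
  lp <- log10(pmatch_)
  counts <- array(0L, dim = c(nc, ns, 4),
                  dimnames = list(data$cells, data$sites, c("A", "C", "G", "T")))
  gl <- array(NA_real_, dim = c(nc, ns, 10),
              dimnames = list(data$cells, data$sites, gt10_states()))
  ml <- matrix(NA_integer_, nc, ns, dimnames = dimnames(gm))
  ado <- matrix(FALSE, nc, ns)
  amp <- amplification_error; seqe <- sequencing_error
  for (ci in seq_len(nc)) {
    dropped <- stats::runif(ns) < delta
    which_drop <- sample.int(2, ns, replace = TRUE)
    mu <- ifelse(dropped, depth / 2, depth)
    dp <- stats::rnbinom(ns, size = overdispersion, mu = mu)
    for (sj in seq_len(ns)) {
      g <- gm[ci, sj]
      if (is.na(g)) next
      alleles <- al10[g, ]
      if (dropped[sj] && alleles[1] != alleles[2]) ado[ci, sj] <- TRUE
      if (dropped[sj]) alleles <- rep(alleles[which_drop[sj]], 2)
      n <- dp[sj]
      if (n == 0) next
      reads <- alleles[sample.int(2, n, replace = TRUE)]
      if (amp > 0) {
        flip <- stats::runif(n) < amp
        if (any(flip)) reads[flip] <- vapply(reads[flip], function(b)
          sample(setdiff(1:4, b), 1), 0L)
      }
      if (seqe > 0) {
        flip <- stats::runif(n) < seqe
        if (any(flip)) reads[flip] <- vapply(reads[flip], function(b)
          sample(setdiff(1:4, b), 1), 0L)
      }
      bc <- tabulate(reads, nbins = 4)
      counts[ci, sj, ] <- bc
      sel <- bc > 0
      # genotype log10-likelihoods: mean over the two alleles per read
      ll <- vapply(1:10, function(j) {
        a <- al10[j, 1]; b <- al10[j, 2]
        sum(bc[sel] * log10((10^lp[a, sel] + 10^lp[b, sel]) / 2))
      }, 0)
      gl[ci, sj, ] <- ll
      best <- which(ll == max(ll))
      ml[ci, sj] <- if (length(best) == 1) best else sample(best, 1)
    }
  }
  list(read_counts = counts,
       gl_data = genotype_data(gl = gl, cells = data$cells, sites = data$sites,
                               ref = data$ref, alt = data$alt),
       ml_data = genotype_data(genotypes = ml, ref = data$ref, alt = data$alt),
       ado = ado)
}

#' Inject cell doublets
#'
#' Each cell is, with probability `rate`, replaced by a merge of itself
#' and another uniformly chosen cell. Genotype mode merges by pooling the
#' four alleles and sampling two without replacement; read mode sums read
#' counts and recomputes genotype likelihoods and ML calls.
#'
#' @param data GT-mode [genotype_data()] (genotype route), or the list
#'   returned by [simulate_reads()] (read route).
#' @param rate doublet rate in \[0, 1\].
#' @param err_read total per-read error rate used to recompute likelihoods
#'   in read mode.
#' @return object of the same shape as `data`, with attribute `doublets`
#'   naming the affected cells and their partners.
#' @export
inject_doublets <- function(data, rate, err_read = 0) {
  read_mode <- !inherits(data, "genotype_data")
  nc <- if (read_mode) dim(data$read_counts)[1] else nrow(data$genotypes)
  if (nc < 2) stop("need at least 2 cells to form doublets")
  if (rate == 0) return(data)
  is_dbl <- stats::runif(nc) < rate
  partner <- vapply(seq_len(nc), function(i)
    if (is_dbl[i]) sample(setdiff(seq_len(nc), i), 1) else NA_integer_, 0L)
  al10 <- gt10_alleles()
  g10 <- matrix(0L, 4, 4)
  for (j in 1:10) {
    g10[al10[j, 1], al10[j, 2]] <- j; g10[al10[j, 2], al10[j, 1]] <- j
  }
  if (!read_mode) {
    gm <- data$genotypes
    for (i in which(is_dbl)) {
      j <- partner[i]
      for (sj in seq_len(ncol(gm))) {
        gi <- gm[i, sj]; gj <- gm[j, sj]
        if (is.na(gi) && is.na(gj)) next
        if (is.na(gi)) { gm[i, sj] <- gj; next }
        if (is.na(gj)) next
        pool <- c(al10[gi, ], al10[gj, ])
        pick <- sort(sample(pool, 2))
        gm[i, sj] <- g10[pick[1], pick[2]]
      }
    }
    out <- data; out$genotypes <- gm
  } else {
    out <- data
    e <- min(max(err_read, 1e-6), 0.75)
    lp <- matrix(e / 3, 4, 4); diag(lp) <- 1 - e; lp <- log10(lp)
    for (i in which(is_dbl)) {
      j <- partner[i]
      out$read_counts[i, , ] <- data$read_counts[i, , ] + data$read_counts[j, , ]
      for (sj in seq_len(dim(out$read_counts)[2])) {
        bc <- out$read_counts[i, sj, ]
        if (sum(bc) == 0) next
        ll <- vapply(1:10, function(g) {
          a <- al10[g, 1]; b <- al10[g, 2]
          sum(bc * log10((10^lp[a, ] + 10^lp[b, ]) / 2))
        }, 0)
        out$gl_data$gl[i, sj, ] <- ll
        best <- which(ll == max(ll))
        out$ml_data$genotypes[i, sj] <- if (length(best) == 1) best else sample(best, 1)
      }
    }
  }
  attr(out, "doublets") <- data.frame(cell = which(is_dbl),
                                      partner = partner[is_dbl])
  out
}

#' Simulate a complete benchmark dataset
#'
#' Runs the full generator: genealogy, true genotypes (ISM or finite-site),
#' then either direct genotype errors or read counts with genotype
#' likelihoods and ML calls, and optional doublets. All randomness flows
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `tree` (true genealogy, mutation units,
#'   tips include the healthy outgroup), `stem_length`, `truth` (true
#'   genotypes and per-site records), `observed` (GT-mode
#'   [genotype_data()]), and for the reads route `gl_data`, `reads`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  gen <- simulate_genealogy(config)
  if (config$mutation_model == "ism") {
    mu <- simulate_mutations_ism(gen, config$n_snvs)
    truth <- mu
  } else {
    mu <- simulate_mutations_finite(gen, n_sites = config$n_sites,
                                    site_rate_gamma_shape = config$site_rate_gamma_shape)
    truth <- mu
  }
  out <- list(config = config, tree = gen$tree, coal_tree = gen$coal_tree,
              stem_length = gen$stem_length, truth = truth)
  if (config$observation == "genotype") {
    out$observed <- apply_genotype_errors(truth$data, config$delta,
                                          config$genotype_error)
  } else {
    rd <- simulate_reads(truth$data, depth = config$depth,
                         overdispersion = config$depth_overdispersion,
                         amplification_error = config$amplification_error,
                         sequencing_error = config$sequencing_error,
                         delta = config$delta)
    if (config$doublet_rate > 0) {
      rd <- inject_doublets(rd, config$doublet_rate,
                            err_read = config$amplification_error +
                              config$sequencing_error)
    }
    out$reads <- rd$read_counts
    out$gl_data <- rd$gl_data
    out$observed <- rd$ml_data
  }
  if (config$observation == "genotype" && config$doublet_rate > 0) {
    out$observed <- inject_doublets(out$observed, config$doublet_rate)
  }
  out
}
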