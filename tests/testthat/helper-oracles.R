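# Independent oracles and small fixture builders shared across tests.

# scaling-and-squaring Taylor-series matrix exponential (independent of the
# eigendecomposition path used by the package)
taylor_expm <- function(q, t, terms = 30, squarings = 20) {
  x <- q * t / 2^squarings
  acc <- diag(nrow(q))
  term <- diag(nrow(q))
  for (k in seq_len(terms)) {
    term <- term %*% x / k
    acc <- acc + term
  }
  for (i in seq_len(squarings)) acc <- acc %*% acc
  acc
}

# brute-force likelihood of a 4-cell unrooted tree
# ((c1,c2)u,(c3,c4)w) by exhaustive summation over the two internal
# genotype assignments
brute_force_loglik_4cell <- function(tips, model, lens) {
  P <- function(t) transition_probabilities(model, t)
  p1 <- P(lens[1]); p2 <- P(lens[2]); p3 <- P(lens[3]); p4 <- P(lens[4])
  puw <- P(lens[5])
  s <- dim(tips)[2]
  ns <- nrow(model$Q)
  sl <- numeric(s)
  for (i in seq_len(s)) {
    tot <- 0
    for (u in seq_len(ns)) {
      a <- sum(p1[u, ] * tips[, i, 1]) * sum(p2[u, ] * tips[, i, 2])
      for (w in seq_len(ns)) {
        tot <- tot + model$pi[u] * a * puw[u, w] *
          sum(p3[w, ] * tips[, i, 3]) * sum(p4[w, ] * tips[, i, 4])
      }
    }
    sl[i] <- log(tot)
  }
  sl
}

# fixed 4-cell, 3-site fixture with heterozygotes and missing data
fixture_4cell <- function(delta = 0.1, epsilon = 0.05) {
  gm <- matrix(c("A", "M", "C",
                 "A", "C", "C",
                 "G", "M", "T",
                 "G", "A", "?"), 4, 3, byrow = TRUE,
               dimnames = list(paste0("c", 1:4), NULL))
  data <- genotype_data(genotypes = gm)
  tips <- build_tip_clvs(data, error_params(delta, epsilon), TRUE)
  tree <- ape::read.tree(text = "((c1:0.1,c2:0.2):0.15,c3:0.3,c4:0.05);")
  list(data = data, tips = tips, tree = tree,
       lens = c(0.1, 0.2, 0.3, 0.05, 0.15))
}

# all 15 unrooted topologies on 5 labels: attach the fifth tip to every
# edge of each of the 3 quartet topologies, deduplicate by bipartitions
all_topologies_5 <- function(labels) {
  stopifnot(length(labels) == 5)
  base <- labels[1:4]
  quartets <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  out <- list()
  for (q in quartets) {
    qt <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                        base[q[1]], base[q[2]],
                                        base[q[3]], base[q[4]]))
    qt$edge.length <- rep(0.1, nrow(qt$edge))
    tip <- ape::read.tree(text = sprintf("(%s:0.1);", labels[5]))
    for (k in seq_len(nrow(qt$edge))) {
      t2 <- ape::bind.tree(qt, tip, where = qt$edge[k, 2], position = 0.05)
      t2 <- ape::unroot(t2)
      t2$edge.length <- rep(0.1, nrow(t2$edge))
      out[[length(out) + 1L]] <- t2
    }
  }
  keys <- vapply(out, function(tr) {
    paste(sort(vapply(scphylo:::tree_bipartition_masks(tr, sort(labels)),
                      function(m) paste(which(m), collapse = ","), "")),
          collapse = ";")
  }, "")
  out[!duplicated(keys)]
}

# evolve phased genotypes down a tree under a reversible genotype model;
# returns a tips x sites matrix of phased state indices
simulate_gt16_matrix <- function(tree, model, s) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  states <- matrix(0L, ntot, s)
  root <- phy$edge[nrow(phy$edge), 1]
  states[root, ] <- sample.int(16, s, replace = TRUE, prob = model$pi)
  for (k in rev(seq_len(nrow(phy$edge)))) {     # preorder
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    p <- transition_probabilities(model, phy$edge.length[k])
    for (a in unique(states[par, ])) {
      idx <- which(states[par, ] == a)
      states[ch, idx] <- sample.int(16, length(idx), replace = TRUE, prob = p[a, ])
    }
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}

# canonical key for the bipartition separating `taxa` from the rest:
# the side that excludes the first taxon in sorted reference order
bipartition_key_for <- function(tree, taxa) {
  ref <- sort(tree$tip.label)
  side <- sort(match(taxa, ref))
  if (1 %in% side) side <- setdiff(seq_along(ref), side)
  paste(side, collapse = ",")
}

topology_key <- function(tree) {
  ref <- sort(tree$tip.label)
  paste(sort(vapply(scphylo:::tree_bipartition_masks(tree, ref),
                    function(m) paste(which(m), collapse = ","), "")),
        collapse = ";")
}
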