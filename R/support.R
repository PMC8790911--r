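# Bipartition machinery, bootstrap branch support (standard and transfer),
# and the normalized Robinson-Foulds distance used as the accuracy metric.

# Nontrivial bipartitions of a (possibly multifurcating) tree as logical
# membership vectors over a reference taxon order, canonicalized so the
# side excluding the first reference taxon is stored.
tree_bipartition_masks <- function(tree, ref_labels = NULL, trivial = FALSE) {
  if (is.null(ref_labels)) ref_labels <- sort(tree$tip.label)
  n <- length(ref_labels)
  if (!setequal(tree$tip.label, ref_labels)) {
    stop("tree taxa do not match the reference taxon set")
  }
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  glob <- match(phy$tip.label, ref_labels)
  masks <- matrix(FALSE, ntot, n)
  masks[cbind(seq_len(ntip), glob)] <- TRUE
  for (k in seq_len(nrow(phy$edge))) {
    e <- phy$edge[k, ]
    masks[e[1], ] <- masks[e[1], ] | masks[e[2], ]
  }
  root <- phy$edge[nrow(phy$edge), 1]
  keep <- setdiff(unique(phy$edge[, 2]), seq_len(ntip))  # internal non-root nodes
  out <- lapply(keep, function(v) {
    m <- masks[v, ]
    if (m[1]) !m else m
  })
  if (trivial) {
    triv <- lapply(seq_len(n), function(i) {
      m <- rep(FALSE, n); m[i] <- TRUE
      if (m[1]) !m else m
    })
    out <- c(out, triv)
  }
  sizes <- vapply(out, sum, 0)
  sel <- if (trivial) sizes >= 1 & sizes <= n - 1 else sizes >= 2 & sizes <= n - 2
  unique(out[sel])
}

# also used by root_with_outgroup: bipartitions as tip-index vectors
tree_bipartitions <- function(tree) {
  ref <- tree$tip.label                  # native order
  masks <- tree_bipartition_masks(tree, ref_labels = ref)
  lapply(masks, which)
}

bipartition_keys <- function(masks) {
  vapply(masks, function(m) paste(which(m), collapse = ","), "")
}

#' Bootstrap resampling of SNV sites
#'
#' Generates replicate datasets by sampling site columns independently and
#' uniformly with replacement; genotype and genotype-likelihood columns are
#' resampled jointly.
#'
#' @param data a [genotype_data()].
#' @param n number of replicates.
#' @param seed optional integer seed.
#' @return list of [genotype_data()] replicates; each carries the sampled
#'   column indices as attribute `"indices"`.
#' @export
bootstrap_replicates <- function(data, n, seed = NULL) {
  stopifnot(inherits(data, "genotype_data"), n >= 1)
  s <- n_sites(data)
  if (s == 0) stop("dataset has no sites to resample")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    idx <- sample.int(s, s, replace = TRUE)
    rep <- data
    if (!is.null(rep$genotypes)) rep$genotypes <- rep$genotypes[, idx, drop = FALSE]
    if (!is.null(rep$gl)) rep$gl <- rep$gl[, idx, , drop = FALSE]
    rep$sites <- data$sites[idx]
    if (!is.null(rep$ref)) rep$ref <- rep$ref[idx]
    if (!is.null(rep$alt)) rep$alt <- rep$alt[idx]
    attr(rep, "indices") <- idx
    rep
  })
}

# attach per-internal-edge support values as node labels on the tree
annotate_support <- function(ml_tree, masks_ml, support) {
  phy <- ape::reorder.phylo(ml_tree, "postorder")
  ref <- sort(phy$tip.label)
  ntip <- ape::Ntip(phy)
  keys <- bipartition_keys(masks_ml)
  lab <- rep("", phy$Nnode)
  masks <- matrix(FALSE, ntip + phy$Nnode, length(ref))
  masks[cbind(seq_len(ntip), match(phy$tip.label, ref))] <- TRUE
  for (k in seq_len(nrow(phy$edge))) {
    e <- phy$edge[k, ]
    masks[e[1], ] <- masks[e[1], ] | masks[e[2], ]
  }
  for (v in setdiff(unique(phy$edge[, 2]), seq_len(ntip))) {
    m <- masks[v, ]
    if (m[1]) m <- !m
    key <- paste(which(m), collapse = ",")
    hit <- match(key, keys)
    if (!is.na(hit)) lab[v - ntip] <- as.character(round(support[hit]))
  }
  phy$node.label <- lab
  phy
}

#' Standard (Felsenstein) bootstrap branch support
#'
#' For every internal branch of the ML tree, the percentage of bootstrap
#' trees containing exactly the same bipartition.
#'
#' @param ml_tree `ape::phylo`.
#' @param bootstrap_trees list of `ape::phylo` (or `multiPhylo`) on the
#'   same taxon set.
#' @return list with `support` (data frame: bipartition, clade size,
#'   percent) and `tree` (ML tree with integer support node labels).
#' @export
felsenstein_support <- function(ml_tree, bootstrap_trees) {
  ref <- sort(ml_tree$tip.label)
  masks_ml <- tree_bipartition_masks(ml_tree, ref)
  keys_ml <- bipartition_keys(masks_ml)
  counts <- numeric(length(keys_ml))
  for (bt in bootstrap_trees) {
    keys_bt <- bipartition_keys(tree_bipartition_masks(bt, ref))
    counts <- counts + (keys_ml %in% keys_bt)
  }
  pct <- 100 * counts / length(bootstrap_trees)
  list(support = data.frame(bipartition = keys_ml,
                            size = vapply(masks_ml, function(m) min(sum(m), sum(!m)), 0),
                            support = pct),
       tree = annotate_support(ml_tree, masks_ml, pct))
}

#' Transfer bootstrap expectation (TBE) branch support
#'
#' For a branch b whose lighter side has p taxa, each replicate contributes
#' `1 - d/(p-1)` where d is the minimum transfer distance: the smallest
#' Hamming distance between b and any branch (trivial ones included) of the
#' replicate tree. Equals the standard bootstrap proportion when every
#' match is exact, and is never smaller.
#'
#' @inheritParams felsenstein_support
#' @return as [felsenstein_support()].
#' @export
transfer_support <- function(ml_tree, bootstrap_trees) {
  ref <- sort(ml_tree$tip.label)
  n <- length(ref)
  masks_ml <- tree_bipartition_masks(ml_tree, ref)
  p <- vapply(masks_ml, function(m) min(sum(m), sum(!m)), 0)
  if (!length(masks_ml)) stop("ML tree has no internal branches")
  tot <- numeric(length(masks_ml))
  for (bt in bootstrap_trees) {
    masks_bt <- tree_bipartition_masks(bt, ref, trivial = TRUE)
    bmat <- do.call(rbind, masks_bt)               # branches x taxa
    for (i in seq_along(masks_ml)) {
      if (p[i] < 2) next
      h1 <- rowSums(bmat != rep(masks_ml[[i]], each = nrow(bmat)))
      d <- min(pmin(h1, n - h1))
      tot[i] <- tot[i] + (1 - d / (p[i] - 1))
    }
  }
  pct <- 100 * tot / length(bootstrap_trees)
  keep <- p >= 2
  list(support = data.frame(bipartition = bipartition_keys(masks_ml)[keep],
                            size = p[keep], support = pct[keep]),
       tree = annotate_support(ml_tree, masks_ml[keep], pct[keep]))
}

#' Normalized Robinson-Foulds distance
#'
#' The count of bipartitions found in only one of the two trees, divided by
#' the total number of internal branches present in both trees (so
#' unresolved trees reduce the denominator). Phylogenetic accuracy is
#' reported as `1 - nRF`.
#'
#' @param tree1,tree2 `ape::phylo` with identical taxon sets (>= 4 taxa).
#' @return value in \[0, 1\].
#' @export
nrf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees have different taxon sets")
  }
  if (length(tree1$tip.label) < 4) stop("need at least 4 taxa")
  ref <- sort(tree1$tip.label)
  k1 <- bipartition_keys(tree_bipartition_masks(tree1, ref))
  k2 <- bipartition_keys(tree_bipartition_masks(tree2, ref))
  denom <- length(k1) + length(k2)
  if (denom == 0) return(0)
  rf <- sum(!k1 %in% k2) + sum(!k2 %in% k1)
  rf / denom
}
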