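# Felsenstein pruning over the genotype state space, with per-node
# rescaling for underflow control. Messages ("directed conditional
# likelihood vectors") are cached per directed edge so that branch-length
# optimization, SPR scoring and ancestral reconstruction reuse them.

# fast transition-probability path (no argument validation)
ptr <- function(model, t) {
  e <- model$eigen
  if (!is.null(e)) {
    p <- e$A %*% (exp(e$values * t) * e$Ainv)
    p[p < 0] <- 0
    p
  } else {
    p <- as.matrix(Matrix::expm(model$Q * t))
    p[p < 0] <- 0
    p
  }
}

# messages: list M[[node]][[slot]] = nstates x s matrix (CLV of the subtree
# behind `node` seen from neighbor in that slot), sc likewise per-site log
# scalers. Tips have a single slot.
compute_messages <- function(ct, tips, model) {
  ntip <- ct$ntip; ntot <- ct$ntot
  ns <- nrow(model$Q)
  s <- dim(tips)[2]
  M <- vector("list", ntot); SC <- vector("list", ntot)
  for (v in seq_len(ntot)) {
    k <- length(ct$adj[[v]])
    M[[v]] <- vector("list", k)
    SC[[v]] <- vector("list", k)
  }
  if (ntip == 2) {
    for (v in 1:2) { M[[v]][[1]] <- tips[, , v]; SC[[v]][[1]] <- numeric(s) }
    return(list(M = M, SC = SC))
  }
  root <- ntip + 1L
  b <- ct_bfs(ct, root)
  # inward pass (reverse BFS): message v -> parent
  for (v in rev(b$order)) {
    u <- b$parent[v]
    if (u == 0L) next
    slot <- ct_slot(ct, v, u)
    if (v <= ntip) {
      M[[v]][[slot]] <- tips[, , v]
      SC[[v]][[slot]] <- numeric(s)
    } else {
      res <- combine_messages(ct, v, exclude = u, M, SC, model)
      M[[v]][[slot]] <- res$m; SC[[v]][[slot]] <- res$sc
    }
  }
  # outward pass (BFS order): message v -> child
  for (v in b$order) {
    if (v <= ntip) next
    for (w in ct$adj[[v]]) {
      if (w == b$parent[v]) next
      slot <- ct_slot(ct, v, w)
      res <- combine_messages(ct, v, exclude = w, M, SC, model)
      M[[v]][[slot]] <- res$m; SC[[v]][[slot]] <- res$sc
    }
  }
  list(M = M, SC = SC)
}

# product over neighbors != exclude of P(t) %*% M_{w -> v}, rescaled
combine_messages <- function(ct, v, exclude, M, SC, model) {
  nb <- ct$adj[[v]]; ln <- ct$alen[[v]]
  m <- NULL; sc <- NULL
  for (j in seq_along(nb)) {
    w <- nb[j]
    if (w == exclude) next
    mw <- M[[w]][[ct_slot(ct, w, v)]]
    contrib <- ptr(model, ln[j]) %*% mw
    if (is.null(m)) {
      m <- contrib; sc <- SC[[w]][[ct_slot(ct, w, v)]]
    } else {
      m <- m * contrib
      sc <- sc + SC[[w]][[ct_slot(ct, w, v)]]
    }
  }
  mx <- .colSums(m, nrow(m), ncol(m))   # any positive per-column scale works
  mx[mx <= 0] <- 1
  list(m = m / rep(mx, each = nrow(m)), sc = sc + log(mx))
}

# single inward pass (no cache retained): fastest full evaluation
loglik_inward <- function(ct, tips, model, weights = NULL) {
  ntip <- ct$ntip
  s <- dim(tips)[2]
  if (is.null(weights)) weights <- rep(1, s)
  if (ntip == 2) {
    t12 <- ct_brlen(ct, 1, 2)
    v <- colSums((model$pi * tips[, , 1]) * (ptr(model, t12) %*% tips[, , 2]))
    sl <- log(v)
    return(list(loglik = sum(weights * sl), site_loglik = sl))
  }
  root <- ntip + 1L
  b <- ct_bfs(ct, root)
  if (!is.null(model$eigen)) {
    ord <- rev(b$order)
    ord <- ord[ord != root]
    lens <- vapply(seq_along(ord), function(i) {
      v <- ord[i]
      ct$alen[[v]][match(b$parent[v], ct$adj[[v]])]
    }, 0)
    e <- model$eigen
    res <- .cpp_loglik_inward(cbind(ord, b$parent[ord]), lens, ntip, tips,
                              e$A, e$Ainv, e$values, model$pi, weights)
    return(list(loglik = res$loglik, site_loglik = as.numeric(res$site_loglik)))
  }
  M <- vector("list", ct$ntot)
  SC <- vector("list", ct$ntot)
  for (v in rev(b$order)) {
    u <- b$parent[v]
    if (v <= ntip) {
      M[[v]] <- tips[, , v]; SC[[v]] <- numeric(s)
      next
    }
    m <- NULL; sc <- numeric(s)
    for (j in seq_along(ct$adj[[v]])) {
      w <- ct$adj[[v]][j]
      if (w == u) next
      contrib <- ptr(model, ct$alen[[v]][j]) %*% M[[w]]
      if (is.null(m)) m <- contrib else m <- m * contrib
      sc <- sc + SC[[w]]
      M[w] <- list(NULL)                # free child memory
    }
    mx <- colSums(m); mx[mx <= 0] <- 1
    M[[v]] <- m / rep(mx, each = nrow(m))
    SC[[v]] <- sc + log(mx)
  }
  sl <- log(colSums(model$pi * M[[root]])) + SC[[root]]
  list(loglik = sum(weights * sl), site_loglik = sl)
}

#' Phylogenetic log-likelihood of a cell tree
#'
#' Computes the log-likelihood of an unrooted binary cell tree given tip
#' likelihood vectors and a genotype substitution model, by Felsenstein
#' pruning with a virtual root and per-node rescaling to avoid underflow.
#' Per-site log-likelihoods are summed (optionally with pattern weights).
#'
#' @param tree an `ape::phylo` tree whose tip labels match the third
#'   dimension names of `tips`.
#' @param tips numeric array `nstates x sites x cells` of tip likelihood
#'   vectors (see [build_tip_clvs()]); `dimnames[[3]]` must name the cells.
#' @param model a `rate_matrix` from [build_gt16_rate_matrix()] or
#'   [build_gt10_rate_matrix()].
#' @param weights optional per-site pattern weights.
#' @return list with `loglik` (total) and `site_loglik` (per site/pattern).
#' @export
tree_loglikelihood <- function(tree, tips, model, weights = NULL) {
  ct <- ctree_from_phylo(tree)
  tips <- match_tips(ct, tips, nrow(model$Q))
  res <- loglik_inward(ct, tips, model, weights)
  if (!is.finite(res$loglik)) {
    bad <- which(!is.finite(res$site_loglik))[1]
    stop("non-finite log-likelihood (first offending site: ",
         if (!is.null(dimnames(tips)[[2]])) dimnames(tips)[[2]][bad] else bad, ")")
  }
  res
}

# reorder (and project) the tip array to the ctree's tip numbering
match_tips <- function(ct, tips, nstates = 16) {
  cn <- dimnames(tips)[[3]]
  if (is.null(cn)) {
    if (dim(tips)[3] != ct$ntip) stop("tip array does not match tree tips")
    out <- tips
  } else {
    idx <- match(ct$labels, cn)
    if (any(is.na(idx))) {
      stop("cells missing from tip data: ",
           paste(ct$labels[is.na(idx)], collapse = ", "))
    }
    out <- if (identical(idx, seq_along(cn))) tips else tips[, , idx, drop = FALSE]
  }
  if (dim(out)[1] == nstates) return(out)
  if (dim(out)[1] == 16 && nstates == 10) return(project_tips_gt10(out))
  stop("tip state dimension (", dim(out)[1], ") does not match model (", nstates, ")")
}

# collapse phased tip vectors to the 10 unphased states (max of phasings,
# which for phase-symmetric inputs equals either one)
project_tips_gt10 <- function(tips) {
  u2p <- unphased_to_phased()
  out <- array(0, dim = c(10, dim(tips)[2], dim(tips)[3]),
               dimnames = c(list(gt10_states()), dimnames(tips)[2:3]))
  for (j in 1:10) {
    sel <- tips[u2p[[j]], , , drop = FALSE]
    out[j, , ] <- if (length(u2p[[j]]) == 1) sel[1, , ] else pmax(sel[1, , ], sel[2, , ])
  }
  out
}

#' Root an unrooted cell tree with an outgroup
#'
#' Places the root on the edge separating the outgroup cells from the rest.
#' The outgroup must form a clade (one side of some bipartition of the
#' unrooted tree).
#'
#' @param tree an `ape::phylo` unrooted tree.
#' @param outgroup character vector of tip labels.
#' @return rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label)) {
    stop("outgroup labels not in tree: ",
         paste(setdiff(outgroup, tree$tip.label), collapse = ", "))
  }
  if (length(outgroup) > 1) {
    bip <- tree_bipartitions(tree)
    og <- sort(match(outgroup, tree$tip.label))
    ok <- any(vapply(bip, function(side) {
      identical(sort(side), og) ||
        identical(sort(setdiff(seq_along(tree$tip.label), side)), og)
    }, logical(1)))
    if (!ok) {
      stop("outgroup {", paste(outgroup, collapse = ","),
           "} is not monophyletic in the tree")
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Read and write cell trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()].
#'
#' @param path file path.
#' @param tree an `ape::phylo`.
#' @return `read_newick` returns an `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Collapse identical site patterns
#'
#' Identical columns of a genotype matrix (or genotype-likelihood array)
#' contribute proportionally to the log-likelihood, so they are collapsed
#' into unique patterns with multiplicity weights.
#'
#' @param data a `genotype_data` object.
#' @return list with `data` (patterns only) and `weights`.
#' @export
compress_patterns <- function(data) {
  stopifnot(inherits(data, "genotype_data"))
  if (data$mode == "GL") {
    return(list(data = data, weights = rep(1, n_sites(data))))
  }
  gm <- data$genotypes
  key <- apply(gm, 2, function(col) paste(ifelse(is.na(col), "m", col), collapse = ","))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  w <- tabulate(idx, nbins = sum(first))
  sub <- data
  sub$genotypes <- gm[, first, drop = FALSE]
  sub$sites <- data$sites[first]
  list(data = sub, weights = w, pattern_of_site = idx)
}
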