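# Internal unrooted-tree representation used by the likelihood engine and
# the SPR search: plain adjacency lists, nodes 1..ntip are tips (degree 1),
# the remaining ntip-2 nodes have degree 3. Branch lengths are stored on
# both directions of each edge.

BRLEN_MIN <- 1e-9
BRLEN_MAX <- 100

ctree_from_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected an ape phylo object")
  if (ape::is.rooted(phy) && ape::Ntip(phy) > 2) {
    phy <- ape::unroot(phy)
  }
  ntip <- ape::Ntip(phy)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  if (ntip == 2) {
    len <- sum(phy$edge.length)
    ct <- list(ntip = 2L, ntot = 2L, labels = phy$tip.label,
               adj = list(2L, 1L), alen = list(len, len))
    class(ct) <- "ctree"
    return(ct)
  }
  ntot <- ntip + phy$Nnode
  adj <- vector("list", ntot)
  alen <- vector("list", ntot)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]; l <- phy$edge.length[k]
    adj[[a]] <- c(adj[[a]], b); alen[[a]] <- c(alen[[a]], l)
    adj[[b]] <- c(adj[[b]], a); alen[[b]] <- c(alen[[b]], l)
  }
  ct <- list(ntip = ntip, ntot = ntot, labels = phy$tip.label,
             adj = adj, alen = alen)
  class(ct) <- "ctree"
  ct
}

phylo_from_ctree <- function(ct) {
  ntip <- ct$ntip
  if (ntip == 2) {
    phy <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                edge.length = c(ct$alen[[1]][1] / 2, ct$alen[[1]][1] / 2),
                Nnode = 1L, tip.label = ct$labels)
    class(phy) <- "phylo"
    return(phy)
  }
  root <- ntip + 1L
  nedge <- ct$ntot - 1L
  edge <- matrix(0L, nedge, 2)
  elen <- numeric(nedge)
  newid <- integer(ct$ntot)
  newid[seq_len(ntip)] <- seq_len(ntip)
  nexti <- ntip + 1L
  k <- 0L
  # iterative preorder from root
  stack <- list(c(root, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1]; parent <- top[2]
    if (v > ntip) { newid[v] <- nexti; nexti <- nexti + 1L }
    nb <- ct$adj[[v]]; ln <- ct$alen[[v]]
    for (j in seq_along(nb)) {
      w <- nb[j]
      if (w == parent) next
      k <- k + 1L
      edge[k, ] <- c(v, w)           # fill with old ids, remap after
      elen[k] <- ln[j]
      stack[[length(stack) + 1L]] <- c(w, v)
    }
  }
  edge[, 1] <- newid[edge[, 1]]
  edge[, 2] <- newid[edge[, 2]]
  phy <- list(edge = edge, edge.length = elen, Nnode = ct$ntot - ntip,
              tip.label = ct$labels)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# slot of neighbor `to` in adj[[from]]
ct_slot <- function(ct, from, to) {
  s <- match(to, ct$adj[[from]])
  if (is.na(s)) stop("nodes ", from, " and ", to, " are not adjacent")
  s
}

ct_brlen <- function(ct, a, b) ct$alen[[a]][ct_slot(ct, a, b)]

ct_set_brlen <- function(ct, a, b, len) {
  ct$alen[[a]][ct_slot(ct, a, b)] <- len
  ct$alen[[b]][ct_slot(ct, b, a)] <- len
  ct
}

# edge list as a matrix (a < b once per edge) with lengths
ct_edges <- function(ct) {
  out <- NULL
  for (a in seq_len(ct$ntot)) {
    nb <- ct$adj[[a]]
    sel <- nb > a
    if (any(sel)) {
      out <- rbind(out, cbind(a = a, b = nb[sel], len = ct$alen[[a]][sel]))
    }
  }
  out
}

# BFS orientation from a root node: returns list(order, parent)
ct_bfs <- function(ct, root) {
  parent <- integer(ct$ntot)
  order <- integer(ct$ntot)
  order[1] <- root; parent[root] <- 0L
  seen <- logical(ct$ntot); seen[root] <- TRUE
  head <- 1L; n <- 1L
  while (head <= n) {
    v <- order[head]; head <- head + 1L
    for (w in ct$adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE; n <- n + 1L
        order[n] <- w; parent[w] <- v
      }
    }
  }
  list(order = order[seq_len(n)], parent = parent)
}

# Prune the subtree behind `r` attached at internal node `p` (a neighbor of
# r), dissolve p, and regraft onto the edge (x, y); the pendant branch keeps
# its length, the target edge is split in half.
ct_spr <- function(ct, r, p, x, y, pendant = NULL) {
  if (p <= ct$ntip) stop("attachment node must be internal")
  nb <- setdiff(ct$adj[[p]], r)
  if (length(nb) != 2) stop("attachment node is not degree 3")
  if (x == p || y == p) stop("target edge touches the dissolved node")
  # the target edge must lie outside the pruned subtree (behind r, away
  # from p); otherwise the surgery would disconnect the tree
  inside <- logical(ct$ntot)
  inside[p] <- TRUE
  stack <- r
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (inside[v]) next
    inside[v] <- TRUE
    stack <- c(stack, ct$adj[[v]][!inside[ct$adj[[v]]]])
  }
  inside[p] <- FALSE
  if (inside[x] || inside[y]) stop("target edge lies inside the pruned subtree")
  x1 <- nb[1]; x2 <- nb[2]
  t1 <- ct_brlen(ct, p, x1); t2 <- ct_brlen(ct, p, x2)
  tp <- if (is.null(pendant)) ct_brlen(ct, p, r) else pendant
  # disconnect p from x1, x2 and join x1-x2
  for (w in c(x1, x2)) {
    s <- ct_slot(ct, w, p)
    ct$adj[[w]] <- ct$adj[[w]][-s]; ct$alen[[w]] <- ct$alen[[w]][-s]
  }
  ct$adj[[x1]] <- c(ct$adj[[x1]], x2); ct$alen[[x1]] <- c(ct$alen[[x1]], t1 + t2)
  ct$adj[[x2]] <- c(ct$adj[[x2]], x1); ct$alen[[x2]] <- c(ct$alen[[x2]], t1 + t2)
  txy <- ct_brlen(ct, x, y)
  # splice p into edge (x, y)
  sx <- ct_slot(ct, x, y); sy <- ct_slot(ct, y, x)
  ct$adj[[x]][sx] <- p; ct$alen[[x]][sx] <- txy / 2
  ct$adj[[y]][sy] <- p; ct$alen[[y]][sy] <- txy / 2
  ct$adj[[p]] <- c(r, x, y)
  ct$alen[[p]] <- c(tp, txy / 2, txy / 2)
  s <- ct_slot(ct, r, p)
  ct$alen[[r]][s] <- tp
  ct
}
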