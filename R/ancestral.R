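# Marginal ancestral genotype reconstruction on a rooted cell tree and
# mutation mapping onto branches.

#' Marginal ancestral genotype reconstruction
#'
#' Computes, for every node (internal nodes and tips) and every site, the
#' marginal posterior distribution over genotypes given the full dataset,
#' via upward (pruning) and downward passes, and reports the
#' maximum-posterior genotype. Ties are broken by state-order precedence
#' (first state in [gt16_states()] order wins), which makes the output
#' reproducible.
#'
#' @param tree rooted `ape::phylo` (see [root_with_outgroup()]).
#' @param data a [genotype_data()].
#' @param model a `rate_matrix`.
#' @param error [error_params()] for genotype input with the error model;
#'   ignored for GL input.
#' @param error_model_active logical.
#' @return list with `ml_genotype` (nodes x sites matrix of state indices;
#'   rows 1..ntip are tips in tree tip order, then internal nodes in ape
#'   numbering), `posterior` (states x sites x nodes array), `states`, and
#'   the input `tree`.
#' @export
marginal_ancestral_genotypes <- function(tree, data, model,
                                         error = error_params(),
                                         error_model_active = TRUE) {
  stopifnot(inherits(data, "genotype_data"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted (use root_with_outgroup)")
  n_states <- nrow(model$Q)
  tips_arr <- build_tip_clvs(data, error, error_model_active && data$mode == "GT")
  cn <- dimnames(tips_arr)[[3]]
  idx <- match(tree$tip.label, cn)
  if (any(is.na(idx))) stop("tree/tip label mismatch")
  tips_arr <- tips_arr[, , idx, drop = FALSE]
  if (n_states == 10 && dim(tips_arr)[1] == 16) {
    tips_arr <- project_tips_gt10(tips_arr)
  }
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(phy)
  ntot <- ntip + phy$Nnode
  s <- dim(tips_arr)[2]
  root <- phy$edge[nrow(phy$edge), 1]
  # upward pass: up[[v]] = P(data below v | state at v), rescaled
  up <- vector("list", ntot)
  upsc <- vector("list", ntot)
  for (v in seq_len(ntip)) { up[[v]] <- tips_arr[, , v]; upsc[[v]] <- numeric(s) }
  pmats <- vector("list", nrow(phy$edge))
  for (k in seq_len(nrow(phy$edge))) {
    pmats[[k]] <- ptr(model, max(phy$edge.length[k], 0))
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    contrib <- pmats[[k]] %*% up[[ch]]
    if (is.null(up[[par]])) {
      up[[par]] <- contrib; upsc[[par]] <- upsc[[ch]]
    } else {
      up[[par]] <- up[[par]] * contrib
      upsc[[par]] <- upsc[[par]] + upsc[[ch]]
    }
    mx <- colSums(up[[par]]); mx[mx <= 0] <- 1
    up[[par]] <- up[[par]] / rep(mx, each = n_states)
    upsc[[par]] <- upsc[[par]] + log(mx)
  }
  # downward pass: out[[v]] picks up the prior and the data outside v's
  # subtree; computed from sibling contributions (no division)
  out <- vector("list", ntot)
  out[[root]] <- matrix(model$pi, n_states, s)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])   # edge rows per parent
  for (k in rev(seq_len(nrow(phy$edge)))) {               # preorder
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    above <- out[[par]]
    for (k2 in kids[[as.character(par)]]) {
      if (k2 == k) next
      above <- above * (pmats[[k2]] %*% up[[phy$edge[k2, 2]]])
    }
    o <- crossprod(pmats[[k]], above)            # t(P) %*% above
    mx <- colSums(o); mx[mx <= 0] <- 1
    out[[ch]] <- o / rep(mx, each = n_states)
  }
  post <- array(0, dim = c(n_states, s, ntot))
  ml <- matrix(0L, ntot, s)
  for (v in seq_len(ntot)) {
    m <- up[[v]] * out[[v]]
    tot <- colSums(m)
    tot[tot <= 0] <- 1
    post[, , v] <- m / rep(tot, each = n_states)
    ml[v, ] <- apply(post[, , v, drop = FALSE][, , 1], 2, which.max)
  }
  dimnames(post) <- list(model$states, data$sites[seq_len(s)], NULL)
  colnames(ml) <- data$sites[seq_len(s)]
  list(ml_genotype = ml, posterior = post, states = model$states, tree = phy)
}

# unphased projection of state indices for change comparison
state_to_unphased <- function(idx, n_states) {
  if (n_states == 10) return(idx)
  phased_to_unphased()[idx]
}

#' Map mutations onto tree branches
#'
#' Compares maximum-posterior genotypes at the two ends of every branch
#' (unphased comparison, so a phase flip is not a mutation) and records the
#' SNVs whose genotypes differ. When the tree is rooted with a zero-length
#' outgroup branch, changes assigned to the two root-adjacent branches are
#' merged onto the ingroup branch.
#'
#' @param anc result of [marginal_ancestral_genotypes()].
#' @return object of class `mutation_map`: data frame `mutations` (branch
#'   label, site, from, to), per-branch list `by_branch`, and `tree` with
#'   branch labels (`nodeN` for internal nodes, tip names for pendant
#'   branches).
#' @export
map_mutations <- function(anc) {
  phy <- anc$tree
  ntip <- ape::Ntip(phy)
  n_states <- length(anc$states)
  ml_u <- matrix(state_to_unphased(anc$ml_genotype, n_states),
                 nrow(anc$ml_genotype), ncol(anc$ml_genotype))
  sites <- colnames(anc$ml_genotype)
  branch_label <- function(v) {
    if (v <= ntip) phy$tip.label[v] else paste0("node", v - ntip)
  }
  root <- ntip + 1L
  rows <- list()
  u10 <- gt10_states()
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    diffs <- which(ml_u[par, ] != ml_u[ch, ])
    if (!length(diffs)) next
    rows[[length(rows) + 1L]] <- data.frame(
      branch = branch_label(ch),
      site = sites[diffs],
      from = u10[ml_u[par, diffs]],
      to = u10[ml_u[ch, diffs]])
  }
  mut <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = character(), site = character(),
               from = character(), to = character())
  # merge root-adjacent branches when one is a zero-length outgroup branch
  rchild <- phy$edge[phy$edge[, 1] == root, 2]
  if (length(rchild) == 2) {
    lens <- phy$edge.length[match(rchild, phy$edge[, 2])]
    zero <- which(rchild <= ntip & lens <= 1e-12)
    if (length(zero) == 1) {
      oglab <- branch_label(rchild[zero])
      inlab <- branch_label(rchild[-zero])
      mut$branch[mut$branch == oglab] <- inlab
    }
  }
  by_branch <- split(mut, mut$branch)
  structure(list(mutations = mut, by_branch = by_branch, tree = phy),
            class = "mutation_map")
}

#' @export
print.mutation_map <- function(x, ...) {
  cat("mutation map:", nrow(x$mutations), "mutations on",
      length(x$by_branch), "branches\n")
  invisible(x)
}

#' Write a mutation map to files
#'
#' Writes a branch-labeled Newick tree (`<prefix>.mutmap.nwk`, node labels
#' are branch identifiers) and a text list (`<prefix>.mutmap.txt`) with one
#' line per branch: label, TAB, comma-separated `site:from>to` entries.
#'
#' @param mm a `mutation_map`.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_mutation_map <- function(mm, prefix) {
  phy <- mm$tree
  phy$node.label <- paste0("node", seq_len(phy$Nnode))
  nwk <- paste0(prefix, ".mutmap.nwk")
  txt <- paste0(prefix, ".mutmap.txt")
  ape::write.tree(phy, file = nwk)
  lines <- vapply(names(mm$by_branch), function(b) {
    m <- mm$by_branch[[b]]
    paste0(b, "\t", paste(sprintf("%s:%s>%s", m$site, m$from, m$to),
                          collapse = ","))
  }, "")
  writeLines(lines, txt)
  invisible(c(nwk, txt))
}
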