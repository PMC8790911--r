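# Parameter optimization: per-edge Brent for branch lengths (with frozen
# directed messages), L-BFGS-B for exchangeabilities and frequencies, and
# cyclic Brent for the ADO / amplification-error rates.

#' Search configuration
#'
#' @param n_parsimony_starts,n_random_starts number of starting trees.
#' @param spr_radius maximum topological distance (edges) an SPR regraft may
#'   move a pruned subtree per round; a vector is used as an escalating
#'   schedule.
#' @param loglik_epsilon log-likelihood improvement threshold for the outer
#'   optimization loop (log units).
#' @param final_epsilon threshold for the final polishing phase.
#' @param max_outer maximum outer iterations per starting tree.
#' @param seed integer seed controlling all randomness of a run.
#' @param profile_error use profile-likelihood error-rate optimization
#'   (branch lengths re-optimized at every candidate rate) in the final
#'   polish; slower, but escapes the flat error-rate/branch-length ridge
#'   on nearly error-free data.
#' @return list of class `search_config`.
#' @export
search_config <- function(n_parsimony_starts = 10, n_random_starts = 10,
                          spr_radius = c(5, 10), loglik_epsilon = 0.1,
                          final_epsilon = 0.001, max_outer = 10, seed = 42,
                          profile_error = FALSE) {
  stopifnot(n_parsimony_starts + n_random_starts >= 1, loglik_epsilon > 0)
  structure(list(n_parsimony_starts = n_parsimony_starts,
                 n_random_starts = n_random_starts,
                 spr_radius = spr_radius,
                 loglik_epsilon = loglik_epsilon,
                 final_epsilon = final_epsilon,
                 max_outer = max_outer, seed = seed,
                 profile_error = profile_error),
            class = "search_config")
}

# one pass of per-edge Brent with messages frozen at sweep start; sweeps
# repeat until the full log-likelihood gain drops below eps. The sweep is
# reverted if the (approximate) per-edge updates decreased the exact
# log-likelihood, so the reported score never decreases.
opt_branch_ct <- function(ct, tips, model, weights, eps = 0.01, max_sweeps = 8) {
  cur <- loglik_inward(ct, tips, model, weights)$loglik
  if (!is.finite(cur)) return(list(ct = ct, loglik = cur))
  lb <- log(BRLEN_MIN); ub <- log(BRLEN_MAX)
  for (sweep in seq_len(max_sweeps)) {
    cache <- compute_messages(ct, tips, model)
    ed <- ct_edges(ct)
    ct2 <- ct
    for (k in seq_len(nrow(ed))) {
      a <- ed[k, "a"]; b <- ed[k, "b"]
      sa <- ct_slot(ct2, a, b); sb <- ct_slot(ct2, b, a)
      pia <- model$pi * cache$M[[a]][[sa]]   # scalers are constant in t
      mb <- cache$M[[b]][[sb]]
      ns <- nrow(pia); s <- ncol(pia)
      f <- function(lt) {
        sum(weights * log(.colSums(pia * (ptr(model, exp(lt)) %*% mb), ns, s)))
      }
      # full interval on the first sweep; a warm window afterwards
      if (sweep == 1) {
        iv <- c(lb, ub)
      } else {
        lt0 <- log(ed[k, "len"])
        iv <- c(max(lb, lt0 - 2), min(ub, lt0 + 2))
      }
      o <- stats::optimize(f, iv, maximum = TRUE, tol = 1e-4)
      ct2 <- ct_set_brlen(ct2, a, b, exp(o$maximum))
    }
    new <- loglik_inward(ct2, tips, model, weights)$loglik
    if (!is.finite(new) || new < cur) break   # overshoot: keep incumbent
    gained <- new - cur
    ct <- ct2; cur <- new
    if (gained < eps) break
  }
  list(ct = ct, loglik = cur)
}

#' Optimize branch lengths by maximum likelihood
#'
#' Iterates one-dimensional Brent optimization over every branch (on the
#' log scale, bounds 1e-9..100) with conditional-likelihood messages frozen
#' per sweep, until the log-likelihood improvement falls below `epsilon`.
#' The returned score is never below the starting score.
#'
#' @param tree `ape::phylo`.
#' @param tips tip likelihood array (see [build_tip_clvs()]).
#' @param model a `rate_matrix`.
#' @param weights optional site pattern weights.
#' @param epsilon convergence threshold in log units.
#' @return list with `tree` (updated lengths) and `loglik`.
#' @export
optimize_branch_lengths <- function(tree, tips, model, weights = NULL,
                                    epsilon = 0.01) {
  ct <- ctree_from_phylo(tree)
  tips <- match_tips(ct, tips, nrow(model$Q))
  if (is.null(weights)) weights <- rep(1, dim(tips)[2])
  res <- opt_branch_ct(ct, tips, model, weights, eps = epsilon)
  list(tree = phylo_from_ctree(res$ct), loglik = res$loglik)
}

# empirical stationary frequencies from observed genotypes (phased counts
# split evenly between the two phasings), floored and renormalized
empirical_frequencies <- function(data, n_states = 16) {
  stopifnot(inherits(data, "genotype_data"))
  if (data$mode == "GL") {
    counts10 <- rep(1, 10)
    ml <- apply(data$gl, c(1, 2), function(v) if (all(is.na(v))) NA else which.max(v))
    tab <- tabulate(ml[!is.na(ml)], nbins = 10)
    counts10 <- counts10 + tab
  } else {
    counts10 <- 1 + tabulate(data$genotypes[!is.na(data$genotypes)], nbins = 10)
  }
  if (n_states == 10) {
    f <- counts10 / sum(counts10)
  } else {
    u2p <- unphased_to_phased()
    f <- numeric(16)
    for (j in 1:10) f[u2p[[j]]] <- counts10[j] / length(u2p[[j]])
    f <- f / sum(f)
  }
  f <- pmax(f, 1e-6)
  f / sum(f)
}

build_model <- function(params, n_states) {
  if (n_states == 16) build_gt16_rate_matrix(params) else build_gt10_rate_matrix(params)
}

#' Optimize substitution model parameters
#'
#' Box-constrained quasi-Newton (L-BFGS-B) maximization of the
#' log-likelihood over log-transformed exchangeabilities and (for
#' `frequency_mode = "optimized"`) softmax-transformed stationary
#' frequencies, holding tree and branch lengths fixed. The incumbent is
#' kept if the optimizer fails to improve.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param tips tip likelihood array.
#' @param params current [substitution_params()].
#' @param weights optional site pattern weights.
#' @param maxit L-BFGS-B iteration cap per block.
#' @param optimize_freqs also optimize the stationary frequencies (only
#'   meaningful for `frequency_mode = "optimized"`).
#' @return list with `params`, `model` and `loglik`.
#' @export
optimize_substitution_params <- function(tree, tips, params, weights = NULL,
                                         maxit = 10, optimize_freqs = TRUE) {
  ct <- ctree_from_phylo(tree)
  n_states <- length(params$frequencies)
  tips <- match_tips(ct, tips, n_states)
  if (is.null(weights)) weights <- rep(1, dim(tips)[2])
  score <- function(p) {
    m <- try(build_model(p, n_states), silent = TRUE)
    if (inherits(m, "try-error")) return(-Inf)
    loglik_inward(ct, tips, m, weights)$loglik
  }
  cur <- score(params)
  if (dim(tips)[2] < 2) {
    warning("too few site patterns to identify substitution parameters")
    return(list(params = params, model = build_model(params, n_states), loglik = cur))
  }
  # exchangeabilities on the log scale
  obj_ex <- function(le) {
    p <- params; p$exchangeabilities <- exp(le)
    -score(p)
  }
  o <- try(stats::optim(log(params$exchangeabilities), obj_ex, method = "L-BFGS-B",
                        lower = log(1e-4), upper = log(1e4),
                        control = list(maxit = maxit, factr = 1e10)), silent = TRUE)
  if (!inherits(o, "try-error") && -o$value >= cur) {
    params$exchangeabilities <- exp(o$par)
    cur <- -o$value
  }
  # frequencies via softmax with the last logit fixed at 0
  if (optimize_freqs && params$frequency_mode == "optimized") {
    to_freq <- function(w) {
      f <- exp(c(w, 0)); f <- f / sum(f)
      f <- pmax(f, 1e-6); f / sum(f)
    }
    w0 <- log(params$frequencies / params$frequencies[n_states])[-n_states]
    obj_f <- function(w) {
      p <- params; p$frequencies <- to_freq(w)
      -score(p)
    }
    o <- try(stats::optim(w0, obj_f, method = "L-BFGS-B",
                          lower = -20, upper = 20,
                          control = list(maxit = maxit, factr = 1e10)), silent = TRUE)
    if (!inherits(o, "try-error") && -o$value >= cur) {
      params$frequencies <- to_freq(o$par)
      cur <- -o$value
    }
  }
  if (!is.finite(cur)) warning("substitution parameter optimization failed to improve")
  list(params = params, model = build_model(params, n_states), loglik = cur)
}

#' Optimize ADO and amplification/sequencing error rates
#'
#' One-dimensional Brent maximization of delta, then epsilon (cyclically),
#' re-initializing all tip likelihood vectors from the observation kernel
#' at every evaluation. Requires genotype-matrix input with the error model
#' active; genotype-likelihood input has no error parameters to estimate.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param data a GT-mode [genotype_data()] (pattern-compressed or not).
#' @param model a `rate_matrix`.
#' @param error current [error_params()].
#' @param weights optional site pattern weights.
#' @param epsilon stop when a full delta+epsilon cycle gains less.
#' @param max_cycles cycle cap (conditional mode).
#' @param profile use profile likelihood: branch lengths are re-optimized
#'   at every candidate rate and the two rates are optimized jointly, which
#'   resolves the near-flat rate/branch-length ridge on almost error-free
#'   data. Slower; the returned list then also carries the re-fitted
#'   `tree`.
#' @return list with `error`, `loglik` and the updated `tips` array.
#' @export
optimize_error_params <- function(tree, data, model, error = error_params(0.05, 0.05),
                                  weights = NULL, epsilon = 0.01, max_cycles = 4,
                                  profile = FALSE) {
  stopifnot(inherits(data, "genotype_data"))
  if (data$mode == "GL") {
    stop("error-rate estimation requires genotype input (GL mode supplies ",
         "per-genotype likelihoods directly)")
  }
  ct <- ctree_from_phylo(tree)
  n_states <- nrow(model$Q)
  if (is.null(weights)) weights <- rep(1, n_sites(data))
  ord <- match(ct$labels, data$cells)
  if (any(is.na(ord))) stop("tree/data cell mismatch")
  data$genotypes <- data$genotypes[ord, , drop = FALSE]
  data$cells <- data$cells[ord]
  # profile = TRUE re-optimizes branch lengths at every candidate rate:
  # the error rates and the pendant branch lengths are weakly confounded,
  # and the conditional (fixed-branch) likelihood stalls on that ridge
  sc_cond <- function(d, e) {
    d <- min(max(d, 0), 1); e <- min(max(e, 0), 1)
    tips <- match_tips(ct, build_tip_clvs(data, error_params(d, e), TRUE), n_states)
    val <- loglik_inward(ct, tips, model, weights)$loglik
    if (!is.finite(val)) val <- -1e12    # boundary rates can zero out patterns
    val
  }
  sc <- function(d, e) {
    if (!profile) return(sc_cond(d, e))
    d <- min(max(d, 0), 1); e <- min(max(e, 0), 1)
    tips <- match_tips(ct, build_tip_clvs(data, error_params(d, e), TRUE), n_states)
    val <- opt_branch_ct(ct, tips, model, weights, eps = epsilon, max_sweeps = 2)$loglik
    if (!is.finite(val)) val <- -1e12
    val
  }
  d <- error$delta; e <- error$epsilon
  cur <- sc(d, e)
  if (profile) {
    # delta and epsilon act oppositely on the expected heterozygote count,
    # so the profile surface has a diagonal valley: first a joint
    # quasi-Newton step to descend the valley, then cyclic Brent to polish
    # each coordinate (with branch lengths refreshed in between)
    o <- try(stats::optim(c(d, e), function(p) -sc(p[1], p[2]),
                          method = "L-BFGS-B", lower = 0, upper = 1,
                          control = list(maxit = 25, factr = 1e9)),
             silent = TRUE)
    if (!inherits(o, "try-error") && -o$value >= cur) {
      d <- o$par[1]; e <- o$par[2]; cur <- -o$value
    }
    tips <- match_tips(ct, build_tip_clvs(data, error_params(d, e), TRUE), n_states)
    ct <- opt_branch_ct(ct, tips, model, weights, eps = epsilon,
                        max_sweeps = 6)$ct
    cur <- sc_cond(d, e)
    for (cyc in 1:2) {
      od <- stats::optimize(function(x) sc_cond(x, e), c(0, 1), maximum = TRUE, tol = 1e-5)
      if (od$objective >= cur) { d <- od$maximum; cur <- od$objective }
      oe <- stats::optimize(function(x) sc_cond(d, x), c(0, 1), maximum = TRUE, tol = 1e-5)
      if (oe$objective >= cur) { e <- oe$maximum; cur <- oe$objective }
    }
    # boundary refinement: when a rate's true optimum is 0, the coordinate
    # polish creeps toward it geometrically; test the boundary directly
    # (with a thorough branch-length refit) and snap if not worse
    sc_strong <- function(d2, e2) {
      tips <- match_tips(ct, build_tip_clvs(data, error_params(d2, e2), TRUE),
                         n_states)
      val <- opt_branch_ct(ct, tips, model, weights, eps = epsilon / 2,
                           max_sweeps = 10)$loglik
      if (!is.finite(val)) -1e12 else val
    }
    v0 <- sc_strong(0, e)
    if (v0 >= cur - epsilon) { d <- 0; cur <- max(v0, cur) }
    v0 <- sc_strong(d, 0)
    if (v0 >= cur - epsilon) { e <- 0; cur <- max(v0, cur) }
  } else {
    prev <- -Inf
    for (cyc in seq_len(max_cycles)) {
      od <- stats::optimize(function(x) sc(x, e), c(0, 1), maximum = TRUE, tol = 1e-4)
      if (od$objective >= cur) { d <- od$maximum; cur <- od$objective }
      oe <- stats::optimize(function(x) sc(d, x), c(0, 1), maximum = TRUE, tol = 1e-4)
      if (oe$objective >= cur) { e <- oe$maximum; cur <- oe$objective }
      if (cur - prev < epsilon) break
      prev <- cur
    }
  }
  err <- error_params(d, e)
  tips <- match_tips(ct, build_tip_clvs(data, err, TRUE), n_states)
  if (profile) {
    bo <- opt_branch_ct(ct, tips, model, weights, eps = epsilon, max_sweeps = 4)
    ct <- bo$ct
    cur <- bo$loglik
    return(list(error = err, loglik = cur, tips = tips,
                tree = phylo_from_ctree(ct)))
  }
  list(error = err, loglik = cur, tips = tips)
}
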