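# Starting trees and the per-start maximum-likelihood search: the outer
# loop alternates branch-length, substitution-parameter and error-rate
# optimization with SPR topology improvement until the log-likelihood gain
# drops below the configured threshold.

DEFAULT_BRLEN <- 0.1

#' Random starting tree
#'
#' Uniformly sampled unrooted binary topology over the given cell labels
#' (every labeled topology equiprobable), with all branch lengths set to a
#' default value.
#'
#' @param labels unique cell names (>= 3).
#' @param seed optional integer seed.
#' @param brlen default branch length.
#' @return unrooted `ape::phylo`.
#' @export
starting_tree_random <- function(labels, seed = NULL, brlen = DEFAULT_BRLEN) {
  if (anyDuplicated(labels)) stop("duplicate cell labels")
  if (length(labels) < 3) stop("need at least 3 cells")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtopology(length(labels), rooted = FALSE, tip.label = labels)
  tr$edge.length <- rep(brlen, nrow(tr$edge))
  tr
}

# phangorn USER-typed alignment over the 10 unphased genotype codes;
# missing data is fully ambiguous
as_phyDat_genotypes <- function(data) {
  ch <- genotype_chars(data, missing = "?")
  phangorn::phyDat(ch, type = "USER",
                   levels = names(genotype_alphabet()$char_codes),
                   ambiguity = "?")
}

# maximum-likelihood genotype per cell/site from a GL-mode dataset
ml_genotypes_from_gl <- function(data, tie_break_random = TRUE) {
  gl <- data$gl
  gm <- matrix(NA_integer_, dim(gl)[1], dim(gl)[2],
               dimnames = list(data$cells, data$sites))
  for (ci in seq_len(dim(gl)[1])) {
    for (sj in seq_len(dim(gl)[2])) {
      v <- gl[ci, sj, ]
      if (all(is.na(v))) next
      best <- which(v == max(v, na.rm = TRUE))
      gm[ci, sj] <- if (length(best) == 1 || !tie_break_random) best[1] else sample(best, 1)
    }
  }
  genotype_data(genotypes = gm, ref = data$ref, alt = data$alt)
}

#' Parsimony starting tree by randomized stepwise addition
#'
#' Builds a starting topology with the Fitch-parsimony randomized stepwise
#' addition order routine over the 10-letter genotype alphabet (missing
#' data fully ambiguous). Genotype-likelihood input is first reduced to
#' per-site maximum-likelihood genotypes for parsimony scoring.
#'
#' @param data a [genotype_data()].
#' @param seed optional integer seed (controls the addition order).
#' @param brlen default branch length for the returned tree.
#' @return unrooted `ape::phylo`.
#' @export
starting_tree_parsimony <- function(data, seed = NULL, brlen = DEFAULT_BRLEN) {
  if (!is.null(seed)) set.seed(seed)
  gt <- if (data$mode == "GL") ml_genotypes_from_gl(data) else data
  empty <- rowSums(!is.na(gt$genotypes)) == 0
  if (any(empty)) {
    warning("cell(s) with no observed genotypes placed by random addition: ",
            paste(gt$cells[empty], collapse = ", "))
  }
  pd <- as_phyDat_genotypes(gt)
  tr <- phangorn::random.addition(pd)
  tr <- ape::unroot(tr)
  tr$edge.length <- rep(brlen, nrow(tr$edge))
  tr
}

#' Fitch parsimony score of a tree over the genotype alphabet
#'
#' @param tree `ape::phylo`.
#' @param data a GT-mode [genotype_data()].
#' @return integer parsimony score.
#' @export
parsimony_score <- function(tree, data) {
  gt <- if (data$mode == "GL") ml_genotypes_from_gl(data) else data
  phangorn::parsimony(tree, as_phyDat_genotypes(gt))
}

#' Maximum-likelihood SPR search from one starting tree
#'
#' Alternates SPR topology improvement (escalating radius schedule) with
#' re-optimization of branch lengths, substitution parameters, stationary
#' frequencies, and — for genotype input with the error model active — the
#' ADO and error rates, until no phase improves the log-likelihood by more
#' than `config$loglik_epsilon`; a final polish then re-optimizes branch
#' lengths and parameters at `config$final_epsilon`.
#'
#' @param start unrooted `ape::phylo` starting tree.
#' @param data a [genotype_data()].
#' @param model_cfg parsed model configuration from [parse_model_string()].
#' @param config a [search_config()].
#' @param params,error optional initial parameter values.
#' @return list with `tree`, `loglik`, `params`, `error`, `moves`.
#' @export
spr_search <- function(start, data, model_cfg = parse_model_string("GT16+FO+E"),
                       config = search_config(), params = NULL, error = NULL) {
  comp <- compress_patterns(data)
  dc <- comp$data; w <- comp$weights
  n_states <- model_cfg$n_states
  if (is.null(params)) {
    f0 <- switch(model_cfg$frequency_mode,
                 equal = rep(1 / n_states, n_states),
                 empirical_frequencies(dc, n_states))
    params <- substitution_params(frequencies = f0,
                                  frequency_mode = model_cfg$frequency_mode)
  }
  err_active <- model_cfg$error_model && data$mode == "GT"
  if (is.null(error)) error <- error_params(0.05, 0.05)
  model <- build_model(params, n_states)
  tips0 <- build_tip_clvs(dc, error, err_active)
  ct <- ctree_from_phylo(start)
  tips <- match_tips(ct, tips0, n_states)
  cur <- loglik_inward(ct, tips, model, w)$loglik
  moves <- 0L
  radii <- config$spr_radius
  for (iter in seq_len(config$max_outer)) {
    before <- cur
    bo <- opt_branch_ct(ct, tips, model, w, eps = config$loglik_epsilon / 2)
    ct <- bo$ct; cur <- bo$loglik
    os <- optimize_substitution_params(phylo_from_ctree(ct), tips, params,
                                       weights = w,
                                       optimize_freqs = (iter == 1))
    if (os$loglik >= cur) { params <- os$params; model <- os$model; cur <- os$loglik }
    if (err_active) {
      oe <- optimize_error_params(phylo_from_ctree(ct), dc, model, error,
                                  weights = w, epsilon = config$loglik_epsilon / 2)
      if (oe$loglik >= cur) {
        error <- oe$error
        tips <- match_tips(ct, oe$tips, n_states)
        cur <- oe$loglik
      }
    }
    radius <- radii[min(iter, length(radii))]
    sp <- spr_rounds(ct, tips, model, w, radius, eps = config$loglik_epsilon / 2)
    ct <- sp$ct; cur <- sp$loglik; moves <- moves + sp$moves
    if (cur - before < config$loglik_epsilon) break
  }
  # final polish: the error rates and pendant branch lengths are weakly
  # confounded near the optimum, so alternate until the gain vanishes
  bo <- opt_branch_ct(ct, tips, model, w, eps = config$final_epsilon, max_sweeps = 10)
  ct <- bo$ct; cur <- bo$loglik
  os <- optimize_substitution_params(phylo_from_ctree(ct), tips, params,
                                     weights = w)
  if (os$loglik >= cur) { params <- os$params; model <- os$model; cur <- os$loglik }
  if (err_active) {
    if (isTRUE(config$profile_error)) {
      oe <- optimize_error_params(phylo_from_ctree(ct), dc, model, error,
                                  weights = w, epsilon = 0.01, max_cycles = 2,
                                  profile = TRUE)
      if (oe$loglik >= cur) {
        error <- oe$error
        ct <- ctree_from_phylo(oe$tree)
        tips <- match_tips(ct, oe$tips, n_states)
        cur <- oe$loglik
      }
    } else {
      oe <- optimize_error_params(phylo_from_ctree(ct), dc, model, error,
                                  weights = w, epsilon = config$final_epsilon)
      if (oe$loglik >= cur) {
        error <- oe$error
        tips <- match_tips(ct, oe$tips, n_states)
        cur <- oe$loglik
      }
    }
    bo <- opt_branch_ct(ct, tips, model, w, eps = config$final_epsilon,
                        max_sweeps = 4)
    ct <- bo$ct; cur <- bo$loglik
  }
  list(tree = phylo_from_ctree(ct), loglik = cur, params = params,
       error = if (err_active) error else NULL, moves = moves)
}

# parse "pars{N}", "rand{N}", or combinations like "pars{1},rand{2}"
parse_tree_spec <- function(spec, config) {
  if (inherits(spec, "phylo")) return(list(user = spec))
  out <- list(pars = 0L, rand = 0L)
  for (tok in strsplit(spec, ",", fixed = TRUE)[[1]]) {
    m <- regmatches(tok, regexec("^(pars|rand)\\{(\\d+)\\}$", trimws(tok)))[[1]]
    if (length(m) != 3) stop("bad starting-tree specifier: ", tok)
    out[[m[2]]] <- out[[m[2]]] + as.integer(m[3])
  }
  out
}

#' Infer a maximum-likelihood cell tree
#'
#' Top-level inference: generates the requested starting trees (parsimony
#' stepwise-addition and/or random), runs the SPR maximum-likelihood search
#' from each, and returns the best-scoring result together with the fitted
#' substitution and error parameters.
#'
#' @param data a [genotype_data()] (genotype matrix or genotype
#'   likelihoods).
#' @param model model string, e.g. `"GT16+FO+E"` (see
#'   [parse_model_string()]). The error model (`+E`) applies only to
#'   genotype input.
#' @param tree starting-tree specification: `"pars{N}"`, `"rand{N}"`, a
#'   combination (`"pars{1},rand{1}"`), or an `ape::phylo` to start from.
#' @param config a [search_config()]; `config$seed` drives all randomness.
#' @return object of class `scphylo_fit`: the best `tree`, its `loglik`,
#'   `params`, `error` (NULL if the error model is off), the model string,
#'   and a per-start summary table.
#' @export
infer_tree <- function(data, model = "GT16+FO+E", tree = "pars{1}",
                       config = search_config()) {
  stopifnot(inherits(data, "genotype_data"))
  model_cfg <- parse_model_string(model)
  if (model_cfg$error_model && data$mode == "GL") {
    stop("model '", model, "' requests error-rate estimation but the input ",
         "is genotype likelihoods; use GT16+FO (no +E) for GL input")
  }
  set.seed(config$seed)
  spec <- parse_tree_spec(tree, config)
  starts <- list()
  if (!is.null(spec$user)) {
    starts <- list(user = spec$user)
  } else {
    if (spec$pars > 0) {
      for (i in seq_len(spec$pars)) {
        starts[[paste0("pars", i)]] <-
          starting_tree_parsimony(data, seed = sample.int(2^31 - 1, 1))
      }
    }
    if (spec$rand > 0) {
      for (i in seq_len(spec$rand)) {
        starts[[paste0("rand", i)]] <-
          starting_tree_random(data$cells, seed = sample.int(2^31 - 1, 1))
      }
    }
  }
  best <- NULL
  tab <- data.frame(start = names(starts), loglik = NA_real_, moves = NA_integer_)
  for (i in seq_along(starts)) {
    res <- spr_search(starts[[i]], data, model_cfg, config)
    tab$loglik[i] <- res$loglik
    tab$moves[i] <- res$moves
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  structure(list(tree = best$tree, loglik = best$loglik, params = best$params,
                 error = best$error, model = model, starts = tab,
                 seed = config$seed,
                 n_cells = n_cells(data), n_sites = n_sites(data)),
            class = "scphylo_fit")
}

#' @export
print.scphylo_fit <- function(x, ...) {
  cat("scphylo fit:", x$model, "|", x$n_cells, "cells x", x$n_sites, "sites\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10), "\n")
  cat("  exchangeabilities:",
      paste(format(x$params$exchangeabilities, digits = 3), collapse = " "), "\n")
  if (!is.null(x$error)) {
    cat("  ADO rate (delta):", format(x$error$delta, digits = 4),
        " error rate (epsilon):", format(x$error$epsilon, digits = 4), "\n")
  }
  invisible(x)
}
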