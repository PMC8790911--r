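#' Single-cell observation error parameters
#'
#' Two free parameters describe how an observed single-cell genotype differs
#' from the true one: `delta`, the allelic-dropout (ADO) rate — the
#' probability that one of the two alleles failed to amplify so a
#' heterozygote is observed as a homozygote — and `epsilon`, the
#' amplification/sequencing error rate — the probability that one allele is
#' observed as a different nucleotide. At most one amplification error per
#' genotype is modeled (the two-error probability epsilon^2 is negligible),
#' but ADO and an error may co-occur.
#'
#' @param delta ADO rate in \[0, 1\].
#' @param epsilon amplification/sequencing error rate in \[0, 1\].
#' @return object of class `error_params`.
#' @export
error_params <- function(delta = 0, epsilon = 0) {
  for (v in c(delta, epsilon)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop("delta and epsilon must be single values in [0, 1]")
    }
  }
  structure(list(delta = delta, epsilon = epsilon), class = "error_params")
}

#' Genotype observation kernel P(Y | X)
#'
#' The 16 x 16 matrix of probabilities of observing phased genotype Y given
#' true phased genotype X under ADO rate delta and error rate epsilon. For a
#' true homozygote a|a: the correct call has probability `1 - eps + (1/2)
#' delta eps`, each of the six phased heterozygotes containing a has
#' `(1-delta) eps/6`, and each other homozygote b|b has `delta eps/6`. For a
#' true heterozygote a|b: the correct (same-phase) call has
#' `(1-delta)(1-eps)`, the two matching homozygotes each
#' `delta/2 + eps/6 - delta eps/3`, third-allele homozygotes `delta eps/6`,
#' and single-error heterozygotes a|c and c|b each `(1-delta) eps/6`.
#' Dropout or error never swaps maternal/paternal phase, so observing b|a
#' from true a|b has probability 0. Every row sums to 1.
#'
#' @param params an [error_params()] object.
#' @return 16 x 16 row-stochastic matrix, rows = true genotype X, columns =
#'   observed genotype Y, in [gt16_states()] order.
#' @export
genotype_error_kernel <- function(params) {
  stopifnot(inherits(params, "error_params"))
  d <- params$delta; e <- params$epsilon
  st <- gt16_states()
  al <- gt16_alleles()
  k <- matrix(0, 16, 16, dimnames = list(true = st, observed = st))
  for (x in 1:16) {
    a <- al[x, 1]; b <- al[x, 2]
    if (a == b) {
      for (y in 1:16) {
        oa <- al[y, 1]; ob <- al[y, 2]
        if (oa == a && ob == a) {
          k[x, y] <- 1 - e + d * e / 2
        } else if (oa == ob) {
          k[x, y] <- d * e / 6
        } else if (oa == a || ob == a) {
          k[x, y] <- (1 - d) * e / 6
        }
      }
    } else {
      for (y in 1:16) {
        oa <- al[y, 1]; ob <- al[y, 2]
        if (oa == a && ob == b) {
          k[x, y] <- (1 - d) * (1 - e)
        } else if (oa == ob && (oa == a || oa == b)) {
          k[x, y] <- d / 2 + e / 6 - d * e / 3
        } else if (oa == ob) {
          k[x, y] <- d * e / 6
        } else if (oa == a && ob != b) {
          k[x, y] <- (1 - d) * e / 6      # paternal allele misread
        } else if (ob == b && oa != a) {
          k[x, y] <- (1 - d) * e / 6      # maternal allele misread
        }
      }
    }
  }
  rs <- rowSums(k)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("observation kernel rows do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  k
}

#' Probability of one observed genotype given a true genotype
#'
#' @param true,observed phased genotype labels (e.g. `"A|C"`) or indices in
#'   [gt16_states()] order.
#' @param params an [error_params()] object.
#' @return a single probability.
#' @examples
#' observation_probability("A|C", "A|C", error_params(0.1, 0.05))  # 0.855
#' @export
observation_probability <- function(true, observed, params) {
  st <- gt16_states()
  xi <- if (is.character(true)) match(true, st) else as.integer(true)
  yi <- if (is.character(observed)) match(observed, st) else as.integer(observed)
  if (is.na(xi) || is.na(yi) || xi < 1 || xi > 16 || yi < 1 || yi > 16) {
    stop("true and observed must be phased genotypes from the 16-state alphabet")
  }
  genotype_error_kernel(params)[xi, yi]
}

# 16 x 11 matrix of tip likelihood vectors: column j (j in 1..10) is the
# tip vector for observed unphased genotype j; column 11 is missing data.
tip_vector_table <- function(params, error_model_active = TRUE) {
  u2p <- unphased_to_phased()
  tab <- matrix(0, 16, 11)
  if (error_model_active) {
    k <- genotype_error_kernel(params)
    for (j in 1:10) tab[, j] <- rowSums(k[, u2p[[j]], drop = FALSE])
  } else {
    for (j in 1:10) tab[u2p[[j]], j] <- 1
  }
  tab[, 11] <- 1
  tab
}

#' Tip genotype-likelihood vector from an observed genotype
#'
#' With the error model active, entry X holds P(Y_obs | X) under the
#' observation kernel; an unphased observed heterozygote sums over its two
#' phasings. With the error model off, the vector is the indicator of the
#' observed genotype (both phasings for a heterozygote). Missing data gives
#' a vector of sixteen ones (all genotypes equally likely).
#'
#' @param observed single genotype character code (see
#'   [genotype_alphabet()]), or `NA` for missing.
#' @param params an [error_params()] object.
#' @param error_model_active logical.
#' @return numeric(16) relative-likelihood vector.
#' @export
tip_likelihoods_from_genotype <- function(observed, params = error_params(),
                                          error_model_active = TRUE) {
  idx <- if (is.na(observed)) NA_integer_ else decode_genotypes(observed)
  tab <- tip_vector_table(params, error_model_active)
  v <- tab[, if (is.na(idx)) 11L else idx]
  names(v) <- gt16_states()
  v
}

#' Tip likelihood vector from unphased genotype log10-likelihoods
#'
#' Expands a 10-vector of log10 genotype likelihoods (order of
#' [gt10_states()]) to the 16 phased states: both phasings of a heterozygote
#' receive the same value. The vector is rescaled so its maximum is 1.
#' `-Inf` marks impossible genotypes; an all-`NA` vector means missing data
#' (all ones).
#'
#' @param log10_likelihoods numeric(10) of log10 likelihoods.
#' @return numeric(16) relative-likelihood vector with maximum 1.
#' @export
tip_likelihoods_from_gl <- function(log10_likelihoods) {
  g <- log10_likelihoods
  if (length(g) != 10) stop("need 10 genotype log10-likelihood values")
  if (all(is.na(g))) {
    v <- rep(1, 16); names(v) <- gt16_states(); return(v)
  }
  if (any(is.na(g)) || any(is.nan(g)) || any(g == Inf)) {
    stop("genotype likelihoods must be finite or -Inf")
  }
  u2p <- unphased_to_phased()
  v <- numeric(16)
  g <- g - max(g)                       # best genotype scaled to 1
  for (j in 1:10) v[u2p[[j]]] <- 10^g[j]
  names(v) <- gt16_states()
  v
}

#' Tip likelihood vector from a Phred-scaled PL triplet
#'
#' For a biallelic site with alleles REF and ALT, the VCF PL field holds
#' Phred-scaled likelihoods (PL0, PL1, PL2) for REF/REF, REF/ALT and
#' ALT/ALT. Likelihoods are `10^(-PL/10)`; both phasings of the
#' heterozygote receive PL1, and every genotype involving any other allele
#' has likelihood 0. A missing call (`NA` triplet) yields all ones.
#'
#' @param pl numeric(3) of nonnegative Phred values, or `NA` for missing.
#' @param ref,alt single nucleotide characters (distinct).
#' @return numeric(16) relative-likelihood vector.
#' @export
tip_likelihoods_from_pl <- function(pl, ref, alt) {
  nuc <- c("A", "C", "G", "T")
  r <- match(toupper(ref), nuc); a <- match(toupper(alt), nuc)
  if (is.na(r) || is.na(a) || r == a) stop("ref and alt must be distinct nucleotides")
  if (all(is.na(pl))) {
    v <- rep(1, 16); names(v) <- gt16_states(); return(v)
  }
  if (length(pl) != 3 || any(is.na(pl)) || any(pl < 0)) {
    stop("PL must be 3 nonnegative Phred-scaled values (biallelic layout)")
  }
  v <- numeric(16)
  v[phased_index(r, r)] <- 10^(-0.1 * pl[1])
  v[phased_index(r, a)] <- 10^(-0.1 * pl[2])
  v[phased_index(a, r)] <- 10^(-0.1 * pl[2])
  v[phased_index(a, a)] <- 10^(-0.1 * pl[3])
  names(v) <- gt16_states()
  v
}

#' Tip conditional-likelihood array for a dataset
#'
#' Builds the 16 x sites x cells array of tip likelihood vectors consumed by
#' the pruning engine, from either observed genotypes (with or without the
#' error model) or per-site genotype likelihoods.
#'
#' @param data a `genotype_data` object (see [genotype_data()]).
#' @param params [error_params()] used when `error_model_active`.
#' @param error_model_active logical; ignored (treated as FALSE) in GL mode.
#' @return numeric array `dim = c(16, n_sites, n_cells)`.
#' @export
build_tip_clvs <- function(data, params = error_params(), error_model_active = TRUE) {
  stopifnot(inherits(data, "genotype_data"))
  cells <- data$cells
  if (data$mode == "GL") {
    arr <- array(1, dim = c(16, dim(data$gl)[2], dim(data$gl)[1]))
    u2p <- unphased_to_phased()
    for (ci in seq_along(cells)) {
      g <- data$gl[ci, , ]               # sites x 10
      mx <- suppressWarnings(apply(g, 1, max, na.rm = TRUE))
      mx[!is.finite(mx)] <- 0
      gs <- 10^(g - mx)
      gs[is.na(gs)] <- 1
      for (j in 1:10) for (p in u2p[[j]]) arr[p, , ci] <- gs[, j]
      miss <- apply(is.na(g), 1, all)
      if (any(miss)) arr[, miss, ci] <- 1
    }
  } else {
    tab <- tip_vector_table(params, error_model_active)
    gm <- data$genotypes                 # cells x sites, unphased indices
    idx <- gm; idx[is.na(idx)] <- 11L
    arr <- array(tab[, t(idx)], dim = c(16, ncol(gm), nrow(gm)))
  }
  dimnames(arr) <- list(gt16_states(), data$sites, cells)
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
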