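#' Substitution model parameters for diploid genotype models
#'
#' The genotype substitution process is time-reversible and built from six
#' nucleotide exchangeabilities (alpha = A<->C, beta = A<->G, gamma = A<->T,
#' kappa = C<->G, lambda = C<->T, with mu = G<->T fixed to 1) and a vector of
#' stationary genotype frequencies (16 phased or 10 unphased).
#'
#' @param exchangeabilities numeric(5): alpha, beta, gamma, kappa, lambda
#'   (all > 0); the sixth rate G<->T is the reference and fixed to 1.
#' @param frequencies nonnegative numeric vector of length 16 or 10 summing
#'   to 1 (tolerance 1e-8; renormalized exactly).
#' @param frequency_mode one of `"optimized"`, `"empirical"`, `"equal"`.
#' @return object of class `substitution_params`.
#' @examples
#' substitution_params()                   # GT16, all rates equal, uniform pi
#' substitution_params(frequencies = rep(1/10, 10))
#' @export
substitution_params <- function(exchangeabilities = c(1, 1, 1, 1, 1),
                                frequencies = rep(1 / 16, 16),
                                frequency_mode = c("optimized", "empirical", "equal")) {
  frequency_mode <- match.arg(frequency_mode)
  if (length(exchangeabilities) != 5 || any(!is.finite(exchangeabilities)) ||
      any(exchangeabilities <= 0)) {
    stop("exchangeabilities must be 5 positive finite values (alpha..lambda)")
  }
  if (!length(frequencies) %in% c(10, 16)) {
    stop("frequencies must have length 16 (phased) or 10 (unphased)")
  }
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-8) {
    stop("frequencies must be nonnegative and sum to 1 (got ",
         format(sum(frequencies)), ")")
  }
  structure(list(exchangeabilities = as.numeric(exchangeabilities),
                 frequencies = frequencies / sum(frequencies),
                 frequency_mode = frequency_mode),
            class = "substitution_params")
}

# symmetric 4x4 nucleotide exchangeability matrix; order A,C,G,T
nuc_exchangeability_matrix <- function(ex) {
  r <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  r["A","C"] <- r["C","A"] <- ex[1]
  r["A","G"] <- r["G","A"] <- ex[2]
  r["A","T"] <- r["T","A"] <- ex[3]
  r["C","G"] <- r["G","C"] <- ex[4]
  r["C","T"] <- r["T","C"] <- ex[5]
  r["G","T"] <- r["T","G"] <- 1
  r
}

# shared constructor for reversible genotype rate matrices; `alleles` is the
# n x 2 allele-index table of the state space.
build_genotype_q <- function(params, alleles, states) {
  n <- nrow(alleles)
  if (length(params$frequencies) != n) {
    stop("expected ", n, " frequencies for the ", n, "-state model, got ",
         length(params$frequencies))
  }
  rex <- nuc_exchangeability_matrix(params$exchangeabilities)
  pi <- params$frequencies
  q <- matrix(0, n, n, dimnames = list(states, states))
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (x == y) next
      da <- alleles[x, 1] != alleles[y, 1]
      db <- alleles[x, 2] != alleles[y, 2]
      # only one of the two alleles may change in an instant
      if (da + db != 1L) next
      pair <- if (da) c(alleles[x, 1], alleles[y, 1]) else c(alleles[x, 2], alleles[y, 2])
      q[x, y] <- rex[pair[1], pair[2]] * pi[y]
    }
  }
  diag(q) <- -rowSums(q)
  scaling <- -sum(pi * diag(q))
  if (scaling <= 0) stop("degenerate rate matrix: zero expected rate at stationarity")
  q <- q / scaling
  eig <- reversible_eigensystem(q, pi)
  structure(list(Q = q, pi = pi, states = states, scaling = scaling,
                 eigen = eig, reversible = TRUE,
                 params = params),
            class = "rate_matrix")
}

# eigendecomposition of D^{1/2} Q D^{-1/2}; NULL when frequencies are too
# small for the similarity transform to be stable
reversible_eigensystem <- function(q, pi) {
  if (any(pi < 1e-10)) return(NULL)
  d <- sqrt(pi)
  b <- diag(d) %*% q %*% diag(1 / d)
  b <- (b + t(b)) / 2                   # enforce symmetry against round-off
  e <- eigen(b, symmetric = TRUE)
  list(values = e$values,
       A = diag(1 / d) %*% e$vectors,   # P(t) = A diag(e^{vt}) Ainv
       Ainv = t(e$vectors) %*% diag(d))
}

#' Build the 16-state phased diploid genotype rate matrix (GT16)
#'
#' Off-diagonal rates are `r(a<->b) * pi_Y` when states X and Y differ at
#' exactly one allele (the changing allele going a -> b), and 0 when both
#' alleles differ. The matrix is scaled so the expected substitution rate at
#' stationarity is 1, i.e. branch lengths are in expected mutations per SNV
#' site.
#'
#' @param params a [substitution_params()] with 16 frequencies.
#' @return object of class `rate_matrix` with elements `Q`, `pi`, `states`,
#'   `scaling` (the pre-normalization rate) and `eigen`.
#' @examples
#' m <- build_gt16_rate_matrix(substitution_params())
#' range(rowSums(m$Q))   # rows sum to zero
#' @export
build_gt16_rate_matrix <- function(params = substitution_params()) {
  build_genotype_q(params, gt16_alleles(), gt16_states())
}

#' Build the 10-state unphased genotype rate matrix (GT10)
#'
#' Reversible reduction of the phased model to the ten unphased genotypes.
#' Exchanges between homozygous and heterozygous genotypes share the same
#' nucleotide exchangeability in both directions (the model's reversibility
#' assumption), and the same single-allele-change rule applies.
#'
#' @param params a [substitution_params()] with 10 frequencies.
#' @return object of class `rate_matrix`.
#' @export
build_gt10_rate_matrix <- function(params = substitution_params(frequencies = rep(1/10, 10))) {
  build_genotype_q(params, gt10_alleles(), gt10_states())
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Uses the cached eigendecomposition of the symmetrized matrix for
#' reversible models; falls back to a dense matrix exponential
#' ([Matrix::expm()]) for non-reversible matrices or near-zero frequencies.
#'
#' @param model a `rate_matrix` (or `gtnr_matrix`) object.
#' @param t branch length, in expected mutations per site; must be >= 0.
#' @return stochastic matrix with nonnegative entries and unit row sums.
#' @examples
#' m <- build_gt16_rate_matrix()
#' p <- transition_probabilities(m, 0.1)
#' range(rowSums(p))
#' @export
transition_probabilities <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("branch length t must be a single finite value >= 0")
  }
  q <- model$Q
  if (t == 0) {
    p <- diag(nrow(q))
    dimnames(p) <- dimnames(q)
    return(p)
  }
  if (!is.null(model$eigen)) {
    e <- model$eigen
    p <- e$A %*% (exp(e$values * t) * e$Ainv)
  } else {
    p <- as.matrix(Matrix::expm(q * t))
  }
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- dimnames(q)
  p
}

#' Non-reversible 4-state DNA rate matrix (GTnR) for simulation
#'
#' Builds the simulator's mutation matrix from 12 nonnegative off-diagonal
#' instantaneous rates (row order A, C, G, T), with the diagonal set so rows
#' sum to zero and the matrix scaled to unit expected rate at its stationary
#' distribution.
#'
#' @param rates either a 4x4 matrix whose off-diagonals are the rates
#'   (diagonal ignored) or a length-12 vector filling the off-diagonals
#'   row-wise.
#' @return object of class `gtnr_matrix` with `Q`, `pi` (stationary
#'   distribution), `states` and `scaling`.
#' @examples
#' build_gtnr_matrix(rep(1, 12))$pi   # symmetric rates -> uniform
#' @export
build_gtnr_matrix <- function(rates) {
  nuc <- c("A", "C", "G", "T")
  if (is.matrix(rates)) {
    if (!all(dim(rates) == c(4, 4))) stop("rate matrix must be 4x4")
    q <- rates
    diag(q) <- 0
  } else {
    if (length(rates) != 12) stop("need 12 off-diagonal rates (row-wise, order A,C,G,T)")
    q <- matrix(0, 4, 4)
    k <- 1
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      q[i, j] <- rates[k]
      k <- k + 1
    }
  }
  if (any(q[row(q) != col(q)] < 0) || any(!is.finite(q))) {
    stop("GTnR rates must be finite and nonnegative")
  }
  dimnames(q) <- list(nuc, nuc)
  diag(q) <- -rowSums(q)
  # stationary distribution: left null vector of Q
  ns <- t(q)
  ns[4, ] <- 1
  pi <- solve(ns, c(0, 0, 0, 1))
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  scaling <- -sum(pi * diag(q))
  if (scaling > 0) q <- q / scaling
  structure(list(Q = q, pi = pi, states = nuc, scaling = scaling,
                 eigen = NULL, reversible = FALSE),
            class = c("gtnr_matrix", "rate_matrix"))
}

#' Single-nucleotide rates pooled from COSMIC mutational signature 1
#'
#' The default simulator mutation matrix: per-nucleotide instantaneous rates
#' obtained by pooling trinucleotide-context rates of COSMIC signature 1
#' (dominated by C>T / G>A transitions). Row order A, C, G, T.
#'
#' @return 4x4 numeric matrix of off-diagonal rates.
#' @export
gtnr_signature1_rates <- function() {
  matrix(c(0,    0.03, 0.12, 0.04,
           0.11, 0,    0.02, 0.68,
           6.68, 0.02, 0,    0.11,
           0.04, 0.12, 0.13, 0), 4, 4, byrow = TRUE,
         dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
}

#' Parse a model specifier string
#'
#' Accepts the command-line style model strings `"GT16+FO"`, `"GT16+FO+E"`,
#' `"GT10+FO+E"`, etc. `FO` = optimized frequencies (default), `FE` = equal,
#' `FC` = empirical counts; `E` activates the ADO/amplification error model.
#'
#' @param model character scalar.
#' @return list with `n_states` (16 or 10), `frequency_mode`, `error_model`.
#' @examples
#' parse_model_string("GT16+FO+E")
#' @export
parse_model_string <- function(model) {
  parts <- strsplit(toupper(model), "+", fixed = TRUE)[[1]]
  if (!parts[1] %in% c("GT16", "GT10")) {
    stop("unknown model '", model, "' (expected GT16 or GT10 base)")
  }
  flags <- parts[-1]
  bad <- setdiff(flags, c("FO", "FE", "FC", "E"))
  if (length(bad)) stop("unknown model flag(s): ", paste(bad, collapse = ", "))
  fmode <- "optimized"
  if ("FE" %in% flags) fmode <- "equal"
  if ("FC" %in% flags) fmode <- "empirical"
  list(n_states = if (parts[1] == "GT16") 16L else 10L,
       frequency_mode = fmode,
       error_model = "E" %in% flags)
}
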