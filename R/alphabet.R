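#' Genotype state spaces and character codes
#'
#' Diploid single-cell SNV genotypes are modeled over 16 phased states
#' (maternal|paternal, ordered A|A, A|C, ..., T|T) or, for unphased data,
#' 10 states (A/A, A/C, ..., T/T). Observed genotype matrices use a
#' single-character dialect: `A,C,G,T` for homozygotes, the IUPAC ambiguity
#' letters `M,R,W,S,Y,K` for the six unphased heterozygotes (AC, AG, AT,
#' CG, CT, GT), and `?` (also accepted: `N`, `-`) for missing.
#'
#' @return `gt16_states()` / `gt10_states()` return the ordered state label
#'   vectors; `genotype_alphabet()` returns a list bundling states, allele
#'   index tables and the character-code bijection.
#' @examples
#' gt16_states()[1:4]
#' genotype_alphabet()$char_codes
#' @export
gt16_states <- function() {
  nuc <- c("A", "C", "G", "T")
  as.vector(t(outer(nuc, nuc, function(m, p) paste(m, p, sep = "|"))))
}

#' @rdname gt16_states
#' @export
gt10_states <- function() {
  nuc <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in 1:4) for (j in i:4) out <- c(out, paste(nuc[i], nuc[j], sep = "/"))
  out
}

# 16 x 2 matrix of allele indices (1=A,2=C,3=G,4=T) per phased state
gt16_alleles <- function() {
  cbind(maternal = rep(1:4, each = 4), paternal = rep(1:4, times = 4))
}

gt10_alleles <- function() {
  idx <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  cbind(a = idx[ord, "row"], b = idx[ord, "col"])
}

#' @rdname gt16_states
#' @export
genotype_alphabet <- function() {
  codes <- c(A = "A/A", C = "C/C", G = "G/G", T = "T/T",
             M = "A/C", R = "A/G", W = "A/T", S = "C/G", Y = "C/T", K = "G/T")
  list(
    phased_states   = gt16_states(),
    unphased_states = gt10_states(),
    phased_alleles  = gt16_alleles(),
    unphased_alleles = gt10_alleles(),
    char_codes      = codes,
    missing_code    = "?",
    missing_aliases = c("?", "N", "-")
  )
}

# phased state index from allele indices
phased_index <- function(m, p) 4L * (m - 1L) + p

# map each unphased state (1..10) to its phased state indices (1 or 2)
unphased_to_phased <- function() {
  al <- gt10_alleles()
  lapply(seq_len(nrow(al)), function(i) {
    a <- al[i, 1]; b <- al[i, 2]
    if (a == b) phased_index(a, b) else c(phased_index(a, b), phased_index(b, a))
  })
}

# map phased state index (1..16) to unphased index (1..10)
phased_to_unphased <- function() {
  al <- gt16_alleles()
  key10 <- apply(gt10_alleles(), 1, function(x) paste(sort(x), collapse = ""))
  keys <- apply(al, 1, function(x) paste(sort(x), collapse = ""))
  match(keys, key10)
}

#' Decode genotype characters
#'
#' Maps single-character genotype codes to unphased state indices (1..10 in
#' the order of [gt10_states()]), with `NA` for missing. Lowercase input is
#' accepted and upper-cased.
#'
#' @param x character vector of single-character genotype codes.
#' @return integer vector of unphased state indices (`NA` = missing).
#' @export
decode_genotypes <- function(x) {
  ab <- genotype_alphabet()
  x <- toupper(x)
  x[x %in% ab$missing_aliases] <- NA_character_
  idx <- match(ab$char_codes[x], ab$unphased_states)
  bad <- !is.na(x) & is.na(idx)
  if (any(bad)) {
    stop("illegal genotype character(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " at position(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
  }
  idx
}

#' Encode unphased state indices back to genotype characters
#'
#' @param idx integer vector of unphased state indices (`NA` = missing).
#' @param missing character used for missing genotypes.
#' @return character vector of single-character codes.
#' @export
encode_genotypes <- function(idx, missing = "?") {
  ab <- genotype_alphabet()
  out <- names(ab$char_codes)[match(ab$unphased_states[idx], ab$char_codes)]
  out[is.na(idx)] <- missing
  out
}
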