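#' Genotype data container
#'
#' Holds an observed cells x sites matrix of unphased genotypes (`GT` mode)
#' and/or per-site genotype log10-likelihood vectors (`GL` mode), with cell
#' names and site identifiers.
#'
#' @param genotypes cells x sites matrix of single-character genotype codes
#'   (see [genotype_alphabet()]) or of unphased state indices (1..10, `NA`
#'   missing). Row names are cell names unless `cells` is given.
#' @param gl optional cells x sites x 10 array of log10 genotype
#'   likelihoods in [gt10_states()] order (`-Inf` = impossible, all-`NA`
#'   slice = missing); its presence selects `GL` mode.
#' @param cells,sites optional name vectors.
#' @param ref,alt optional per-site reference/alternate alleles.
#' @return object of class `genotype_data` with fields `genotypes` (integer
#'   matrix), `gl`, `cells`, `sites`, `ref`, `alt`, `mode`.
#' @export
genotype_data <- function(genotypes = NULL, gl = NULL, cells = NULL,
                          sites = NULL, ref = NULL, alt = NULL) {
  if (is.null(genotypes) && is.null(gl)) stop("need genotypes and/or gl")
  if (!is.null(genotypes)) {
    if (!is.matrix(genotypes)) stop("genotypes must be a cells x sites matrix")
    if (is.character(genotypes)) {
      gm <- matrix(decode_genotypes(genotypes), nrow(genotypes), ncol(genotypes))
    } else {
      gm <- genotypes
      storage.mode(gm) <- "integer"
      if (any(gm < 1 | gm > 10, na.rm = TRUE)) stop("genotype indices must be in 1..10")
    }
    if (is.null(cells)) cells <- rownames(genotypes)
    if (is.null(sites)) sites <- colnames(genotypes)
  } else {
    gm <- NULL
  }
  if (!is.null(gl)) {
    if (length(dim(gl)) != 3 || dim(gl)[3] != 10) {
      stop("gl must be a cells x sites x 10 array")
    }
    if (is.null(cells)) cells <- dimnames(gl)[[1]]
    if (is.null(sites)) sites <- dimnames(gl)[[2]]
  }
  nc <- if (!is.null(gm)) nrow(gm) else dim(gl)[1]
  ns <- if (!is.null(gm)) ncol(gm) else dim(gl)[2]
  if (is.null(cells)) cells <- paste0("cell", seq_len(nc))
  if (is.null(sites)) sites <- paste0("site", seq_len(ns))
  if (length(cells) != nc || anyDuplicated(cells)) {
    stop("cell names must be unique and match the number of rows")
  }
  if (length(sites) != ns) stop("site names must match the number of columns")
  if (!is.null(gm)) dimnames(gm) <- list(cells, sites)
  structure(list(genotypes = gm, gl = gl, cells = cells, sites = sites,
                 ref = ref, alt = alt,
                 mode = if (is.null(gl)) "GT" else "GL"),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", length(x$cells), "cells x", length(x$sites),
      "sites, mode", x$mode, "\n")
  invisible(x)
}

n_cells <- function(data) length(data$cells)
n_sites <- function(data) length(data$sites)

# character-code view of the genotype matrix
genotype_chars <- function(data, missing = "?") {
  gm <- data$genotypes
  out <- matrix(encode_genotypes(gm, missing), nrow(gm), ncol(gm),
                dimnames = dimnames(gm))
  out
}

#' Read a genotype matrix from FASTA or PHYLIP
#'
#' One sequence of single-character genotype codes per cell; lowercase is
#' accepted and upper-cased, `?`/`N`/`-` mean missing. PHYLIP is the relaxed
#' dialect: a `ncells nsites` header, then one `name sequence` record per
#' line (whitespace-separated).
#'
#' @param path input file.
#' @param format `"auto"` (by extension/leading character), `"fasta"` or
#'   `"phylip"`.
#' @return a [genotype_data()] in GT mode.
#' @export
read_genotype_matrix <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                               set.attributes = FALSE)
    nm <- names(seqs)
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1) {
      stop("ragged FASTA records: lengths ", paste(unique(lens), collapse = ","))
    }
    gm <- do.call(rbind, lapply(seqs, function(x) toupper(x)))
  } else {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    hdr <- scan(text = ln[1], what = integer(), quiet = TRUE)
    if (length(hdr) != 2) stop("malformed PHYLIP header: ", ln[1])
    recs <- strsplit(trimws(ln[-1]), "\\s+")
    if (length(recs) != hdr[1]) {
      stop("expected ", hdr[1], " records, found ", length(recs))
    }
    nm <- vapply(recs, `[`, "", 1)
    seqs <- vapply(recs, function(r) paste(r[-1], collapse = ""), "")
    lens <- nchar(seqs)
    if (any(lens != hdr[2])) {
      stop("row length mismatch at record(s): ",
           paste(nm[lens != hdr[2]], collapse = ", "),
           " (expected ", hdr[2], " sites)")
    }
    gm <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (anyDuplicated(nm)) {
    stop("duplicate cell names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  rownames(gm) <- nm
  genotype_data(genotypes = gm)
}

#' Write a genotype matrix to FASTA or PHYLIP
#'
#' @param data a GT-mode [genotype_data()].
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(data, path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "genotype_data"), !is.null(data$genotypes))
  ch <- genotype_chars(data)
  if (format == "fasta") {
    seqinr::write.fasta(lapply(seq_len(nrow(ch)), function(i) ch[i, ]),
                        names = data$cells, file.out = path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(nrow(ch), ncol(ch)), con)
    writeLines(paste(data$cells, apply(ch, 1, paste, collapse = "")), con)
  }
  invisible(path)
}

#' Read single-cell genotypes from a VCF file
#'
#' `GT` mode extracts called genotypes: `0/1` and `0|1` both map to the
#' unphased heterozygote code, `./.` to missing. `PL` mode extracts
#' Phred-scaled likelihood triplets for biallelic SNVs and converts them to
#' per-site genotype log10-likelihood vectors; multi-allelic records are
#' skipped (and counted), records lacking PL raise an error naming the
#' record. Indels are skipped in both modes with a reported count.
#'
#' @param path VCF file (may be bgzipped).
#' @param mode `"GT"` or `"PL"`.
#' @return a [genotype_data()]; attribute `skipped` reports skipped record
#'   counts.
#' @export
read_vcf <- function(path, mode = c("GT", "PL")) {
  mode <- match.arg(mode)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  sites <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_indel <- nchar(ref) != 1 |
    vapply(alt_list, function(a) any(nchar(a) != 1 & a != "<NON_REF>"), logical(1))
  multi <- lengths(alt_list) > 1
  skipped <- c(indel = sum(is_indel), multiallelic = 0L)
  keep <- !is_indel
  if (mode == "PL") {
    skipped["multiallelic"] <- sum(multi & !is_indel)
    keep <- keep & !multi
  }
  if (!any(keep)) stop("no usable SNV records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  cells <- colnames(gt)
  if (mode == "GT") {
    gm <- matrix(NA_integer_, length(cells), sum(keep),
                 dimnames = list(cells, sites[keep]))
    cols <- which(keep)
    al10 <- gt10_alleles()
    nucs <- c("A", "C", "G", "T")
    for (j in seq_along(cols)) {
      k <- cols[j]
      alleles <- c(ref[k], alt_list[[k]])
      a_idx <- match(alleles, nucs)
      calls <- gt[k, ]
      toks <- strsplit(calls, "[/|]")
      for (ci in seq_along(cells)) {
        tk <- toks[[ci]]
        if (length(tk) != 2 || any(tk == ".") || any(is.na(tk))) next
        ai <- a_idx[as.integer(tk) + 1]
        if (any(is.na(ai))) next
        ai <- sort(ai)
        gm[ci, j] <- which(al10[, 1] == ai[1] & al10[, 2] == ai[2])
      }
    }
    out <- genotype_data(genotypes = gm, ref = ref[keep],
                         alt = vapply(alt_list[keep], `[`, "", 1))
  } else {
    plm <- tryCatch(vcfR::extract.gt(vcf, element = "PL"),
                    error = function(e) NULL)
    if (is.null(plm)) stop("VCF has no PL field: ", path)
    cols <- which(keep)
    gl <- array(NA_real_, dim = c(length(cells), length(cols), 10),
                dimnames = list(cells, sites[cols], gt10_states()))
    al10 <- gt10_alleles()
    nucs <- c("A", "C", "G", "T")
    for (j in seq_along(cols)) {
      k <- cols[j]
      r <- match(ref[k], nucs); a <- match(alt_list[[k]][1], nucs)
      if (is.na(r) || is.na(a)) next
      g_hom_ref <- which(al10[, 1] == r & al10[, 2] == r)
      g_hom_alt <- which(al10[, 1] == a & al10[, 2] == a)
      het <- sort(c(r, a))
      g_het <- which(al10[, 1] == het[1] & al10[, 2] == het[2])
      for (ci in seq_along(cells)) {
        v <- plm[k, ci]
        if (is.na(v) || v == ".") {
          gcall <- gt[k, ci]
          if (is.na(gcall) || grepl("\\.", gcall)) next   # stays missing
          stop("record ", sites[k], " cell ", cells[ci], " lacks PL")
        }
        pl <- suppressWarnings(as.numeric(strsplit(v, ",", fixed = TRUE)[[1]]))
        if (length(pl) != 3 || any(is.na(pl))) {
          stop("record ", sites[k], " cell ", cells[ci],
               ": PL is not a biallelic triplet (", v, ")")
        }
        gl[ci, j, ] <- -Inf
        gl[ci, j, g_hom_ref] <- -0.1 * pl[1]
        gl[ci, j, g_het]     <- -0.1 * pl[2]
        gl[ci, j, g_hom_alt] <- -0.1 * pl[3]
      }
    }
    out <- genotype_data(gl = gl, ref = ref[cols],
                         alt = vapply(alt_list[cols], `[`, "", 1))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Convert an SC-Caller four-value PL field to a standard triplet
#'
#' SC-Caller stores Phred likelihoods for (sequencing noise, amplification
#' artifact, heterozygous, homozygous-alternative). The homozygous-reference
#' likelihood is taken as the better (smaller Phred) of the first two
#' values; the result is shifted so its minimum is 0.
#'
#' @param pl numeric(4), or a matrix with 4 columns.
#' @return numeric(3) (or 3-column matrix) standard PL.
#' @export
convert_sccaller_pl <- function(pl) {
  if (is.matrix(pl)) {
    if (ncol(pl) != 4) stop("SC-Caller PL must have 4 values")
    out <- cbind(pmin(pl[, 1], pl[, 2]), pl[, 3], pl[, 4])
    return(out - apply(out, 1, min))
  }
  if (length(pl) != 4) stop("SC-Caller PL must have 4 values")
  out <- c(min(pl[1], pl[2]), pl[3], pl[4])
  out - min(out)
}

#' Recode DNA genotypes to ternary (0/1/2/3) genotypes
#'
#' Recoding used to interface with presence/absence-style tools: 0 =
#' homozygous reference, 1 = heterozygous, 2 = homozygous alternative, 3 =
#' missing. Multi-allelic sites are handled per `mode`: `"keep"` retains all
#' sites (any heterozygote is 1, any non-reference homozygote is 2),
#' `"remove"` drops sites with more than two alleles (reference included),
#' and `"missing"` keeps all sites but marks genotypes carrying a minor
#' (non-major) alternative allele as missing.
#'
#' @param data a GT-mode [genotype_data()].
#' @param ref character vector of per-site reference nucleotides (defaults
#'   to `data$ref`).
#' @param mode `"keep"`, `"remove"` or `"missing"`.
#' @return cells x sites integer matrix over 0..3.
#' @export
recode_ternary <- function(data, ref = NULL, mode = c("keep", "remove", "missing")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "genotype_data"), !is.null(data$genotypes))
  if (is.null(ref)) ref <- data$ref
  if (is.null(ref)) stop("per-site reference alleles are required")
  nucs <- c("A", "C", "G", "T")
  refi <- match(toupper(ref), nucs)
  if (length(refi) != n_sites(data) || any(is.na(refi))) {
    stop("ref must supply one nucleotide per site")
  }
  gm <- data$genotypes
  al10 <- gt10_alleles()
  out <- matrix(3L, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  dropped <- logical(ncol(gm))
  for (j in seq_len(ncol(gm))) {
    g <- gm[, j]
    obs <- g[!is.na(g)]
    alleles <- unique(c(refi[j], al10[obs, 1], al10[obs, 2]))
    if (!refi[j] %in% c(al10[obs, 1], al10[obs, 2]) && length(obs)) {
      warning("reference allele unobserved at site ", data$sites[j])
    }
    altc <- tabulate(c(al10[obs, 1], al10[obs, 2]), nbins = 4)
    altc[refi[j]] <- 0L
    major_alt <- if (any(altc > 0)) which.max(altc) else NA_integer_
    if (mode == "remove" && length(alleles) > 2) {
      dropped[j] <- TRUE
      next
    }
    for (ci in seq_len(nrow(gm))) {
      if (is.na(g[ci])) next
      a <- al10[g[ci], 1]; b <- al10[g[ci], 2]
      if (mode == "missing" &&
          any(!c(a, b) %in% c(refi[j], major_alt))) next      # minor alt -> 3
      out[ci, j] <- if (a != b) 1L else if (a == refi[j]) 0L else 2L
    }
  }
  if (mode == "remove") out <- out[, !dropped, drop = FALSE]
  out
}

#' Drop sites with excessive missing data
#'
#' Optional utility; no automatic filtering is applied anywhere else.
#'
#' @param data a GT-mode [genotype_data()].
#' @param max_missing maximum tolerated fraction of missing cells per site.
#' @return filtered [genotype_data()].
#' @export
filter_missing_sites <- function(data, max_missing = 0.5) {
  stopifnot(inherits(data, "genotype_data"), !is.null(data$genotypes))
  frac <- colMeans(is.na(data$genotypes))
  keep <- frac <= max_missing
  out <- data
  out$genotypes <- data$genotypes[, keep, drop = FALSE]
  out$sites <- data$sites[keep]
  if (!is.null(out$ref)) out$ref <- out$ref[keep]
  if (!is.null(out$alt)) out$alt <- out$alt[keep]
  out
}
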