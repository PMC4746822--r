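#' SNP matrix container
#'
#' A `snp_matrix` holds the polymorphic sites of a haplotype sample: an
#' `n x S` genotype matrix of state codes, the base-pair position of each
#' SNP, and an alphabet tag. Binary data (infinite-sites convention,
#' ancestral = 0, derived = 1) are coded 0/1; DNA data are coded 1..4 for
#' A, C, G, T. Missing observations (alignment gaps, Ns, missing
#' genotypes) are `NA`; the complement of the `NA` pattern is the per-SNP
#' validity mask.
#'
#' Invariants enforced by the constructor: positions strictly increasing;
#' every SNP polymorphic among its valid samples (at least two distinct
#' states, each carried by at least one sample); at least two valid
#' samples per SNP.
#'
#' @param geno integer matrix, samples in rows, SNPs in columns. Codes
#'   0/1 for `alphabet = "binary"`, 1..4 (A,C,G,T) for `alphabet = "dna"`,
#'   `NA` for invalid observations.
#' @param positions numeric vector of strictly increasing base-pair
#'   coordinates (fractional values allowed), one per SNP.
#' @param alphabet `"binary"` or `"dna"`.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(geno, positions, alphabet = c("binary", "dna")) {
  alphabet <- match.arg(alphabet)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(geno) != length(positions)) {
    stop("number of SNP columns (", ncol(geno), ") does not match number of positions (",
         length(positions), ")")
  }
  if (ncol(geno) > 0L) {
    if (any(!is.finite(positions))) stop("positions must be finite")
    if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
    rng <- range(geno, na.rm = TRUE)
    if (alphabet == "binary" && (rng[1] < 0L || rng[2] > 1L)) {
      stop("binary snp_matrix codes must be 0/1")
    }
    if (alphabet == "dna" && (rng[1] < 1L || rng[2] > 4L)) {
      stop("dna snp_matrix codes must be in 1..4")
    }
    nv <- colSums(!is.na(geno))
    if (any(nv < 2L)) stop("every SNP needs at least 2 valid samples")
    poly <- vapply(seq_len(ncol(geno)), function(j) {
      s <- unique(geno[, j])
      length(s[!is.na(s)]) >= 2L
    }, logical(1))
    if (!all(poly)) {
      stop("monomorphic column(s) at index: ", paste(which(!poly), collapse = ", "))
    }
  }
  structure(
    list(geno = geno, positions = positions, alphabet = alphabet),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d samples x %d SNPs (%s)\n",
              n_samples(x), n_snps(x), x$alphabet))
  if (n_snps(x) > 0L) {
    cat(sprintf("  positions: %.2f .. %.2f\n",
                x$positions[1], x$positions[n_snps(x)]))
    nmiss <- sum(is.na(x$geno))
    if (nmiss > 0L) cat(sprintf("  missing observations: %d\n", nmiss))
  }
  invisible(x)
}

#' Number of SNPs / samples in a `snp_matrix`
#' @param x a `snp_matrix`
#' @return integer count
#' @export
n_snps <- function(x) ncol(x$geno)

#' @rdname n_snps
#' @export
n_samples <- function(x) nrow(x$geno)

#' Subset a snp_matrix to a set of SNP columns, keeping invariants
#' @noRd
snp_subset <- function(x, j) {
  snp_matrix(x$geno[, j, drop = FALSE], x$positions[j], x$alphabet)
}

dna_letters <- c("A", "C", "G", "T")

#' Haplotype alignment
#'
#' Light container for an intra-species multiple sequence alignment:
#' equal-length sequences over the symbols A, C, G, T, -, N (or 0/1 for
#' binary data), with record labels.
#'
#' @param sequences character vector of equal-length sequences.
#' @param labels character vector of identifiers (recycled default).
#' @return An object of class `haplotype_alignment` with elements
#'   `sequences`, `labels`, and `length` (the site count).
#' @export
haplotype_alignment <- function(sequences, labels = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 2L) stop("an alignment needs at least 2 sequences")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(sort(len), collapse = ", "))
  }
  if (len < 1L) stop("alignment length must be >= 1")
  bad <- grepl("[^ACGTN01-]", sequences)
  if (any(bad)) stop("unsupported symbols in sequence(s): ",
                     paste(which(bad), collapse = ", "))
  if (is.null(labels)) labels <- paste0("seq", seq_along(sequences))
  structure(list(sequences = sequences, labels = as.character(labels), length = len),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment: %d sequences x %d sites\n",
              length(x$sequences), x$length))
  invisible(x)
}

#' Extract SNPs from a haplotype alignment
#'
#' Keeps exactly the alignment columns with at least two distinct valid
#' states among non-gap/non-N samples (and at least two valid samples).
#' Positions are the 1-based alignment column indices. `-` and `N` are
#' treated identically as invalid observations.
#'
#' @param aln a [haplotype_alignment]
#' @return A [snp_matrix], alphabet `"binary"` when the alignment is over
#'   0/1, `"dna"` otherwise.
#' @export
extract_snps <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  chars <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  binary <- all(chars %in% c("0", "1", "-", "N"))
  code <- if (binary) {
    m <- matrix(NA_integer_, nrow(chars), ncol(chars))
    m[chars == "0"] <- 0L
    m[chars == "1"] <- 1L
    m
  } else {
    m <- matrix(match(chars, dna_letters), nrow(chars), ncol(chars))
    m
  }
  keep <- vapply(seq_len(ncol(code)), function(j) {
    v <- code[, j]
    v <- v[!is.na(v)]
    length(v) >= 2L && length(unique(v)) >= 2L
  }, logical(1))
  snp_matrix(code[, keep, drop = FALSE], which(keep),
             alphabet = if (binary) "binary" else "dna")
}

#' Deduce a binary representation of DNA SNPs
#'
#' Maps, per SNP, the majority state to 0 and every other valid state
#' to 1. Ties in the majority count are broken alphabetically (A before C
#' before G before T), so the deduction is deterministic. SNPs that end
#' up monomorphic are removed; the validity mask is preserved.
#'
#' @param snps a DNA [snp_matrix]
#' @return A binary [snp_matrix].
#' @export
deduce_binary <- function(snps) {
  stopifnot(inherits(snps, "snp_matrix"))
  if (snps$alphabet != "dna") stop("deduce_binary expects a DNA snp_matrix")
  S <- n_snps(snps)
  out <- matrix(NA_integer_, n_samples(snps), S)
  for (j in seq_len(S)) {
    v <- snps$geno[, j]
    tab <- tabulate(v, nbins = 4L)
    # which.max picks the first (alphabetically smallest) among ties
    major <- which.max(tab)
    out[, j] <- ifelse(is.na(v), NA_integer_, ifelse(v == major, 0L, 1L))
  }
  keep <- vapply(seq_len(S), function(j) {
    v <- out[, j]
    v <- v[!is.na(v)]
    length(unique(v)) >= 2L
  }, logical(1))
  snp_matrix(out[, keep, drop = FALSE], snps$positions[keep], "binary")
}

#' Remove singleton SNPs
#'
#' Drops SNPs whose minor state is carried by exactly one valid sample:
#' for binary data, a minor-state count of 1; for DNA data, sites where
#' all but one valid sample share one state. Sites with two or more
#' minor-state samples are kept even when each individual minor state is
#' a singleton.
#'
#' @param snps a [snp_matrix]
#' @return A [snp_matrix] without singleton sites.
#' @export
filter_singletons <- function(snps) {
  stopifnot(inherits(snps, "snp_matrix"))
  S <- n_snps(snps)
  if (S == 0L) return(snps)
  keep <- vapply(seq_len(S), function(j) {
    v <- snps$geno[, j]
    v <- v[!is.na(v)]
    tab <- table(v)
    (length(v) - max(tab)) != 1L
  }, logical(1))
  snp_subset(snps, which(keep))
}
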