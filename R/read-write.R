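#' Read a multi-record FASTA alignment
#'
#' Sequences are uppercased; `-` and `N` are preserved (they become
#' invalid observations when SNPs are extracted). Plain or
#' gzip-compressed files are accepted.
#'
#' @param path path to a FASTA file
#' @return A [haplotype_alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2L) stop("FASTA must contain at least 2 records")
  haplotype_alignment(as.character(seqs), labels = names(seqs))
}

#' Read Hudson's ms-format replicates
#'
#' Parses the ms dialect: replicates delimited by `//`, then
#' `segsites: k`, `positions: p1 ... pk` with fractional positions on
#' \[0,1\], then one 0/1 row per haplotype. Fractional positions are
#' scaled to base pairs by `region_length`. Non-monotone position lists
#' are sorted with a warning (ties broken by input order); duplicate
#' positions are perturbed by `+1e-6 * region_length` so downstream
#' windows see strictly increasing coordinates.
#'
#' @param path path to an ms-format file (plain or gzipped)
#' @param region_length region length in bp used to scale positions
#'   (default 1e6)
#' @return A list of binary [snp_matrix] objects, one per replicate.
#'   A `segsites: 0` replicate yields a 0-SNP matrix.
#' @export
read_ms <- function(path, region_length = 1e6) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(region_length > 0)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  delim <- which(trimws(lines) == "//")
  if (length(delim) == 0L) stop("not an ms file: no '//' replicate delimiter found")
  bounds <- c(delim, length(lines) + 1L)
  lapply(seq_along(delim), function(r) {
    from <- bounds[r] + 1L
    to <- bounds[r + 1L] - 1L
    block <- if (from > to) character(0) else lines[from:to]
    parse_ms_block(block, region_length)
  })
}

parse_ms_block <- function(block, region_length) {
  block <- block[!vapply(block, function(l) grepl("^\\s*$", l), logical(1))]
  seg_i <- grep("^segsites:", block)
  if (length(seg_i) != 1L) stop("ms replicate without a single 'segsites:' line")
  k <- as.integer(sub("^segsites:\\s*", "", block[seg_i]))
  if (is.na(k) || k < 0L) stop("bad segsites count")
  if (k == 0L) {
    return(snp_matrix(matrix(integer(0), nrow = 0, ncol = 0), numeric(0), "binary"))
  }
  pos_i <- grep("^positions:", block)
  if (length(pos_i) != 1L) stop("ms replicate without a 'positions:' line")
  p <- as.numeric(strsplit(trimws(sub("^positions:", "", block[pos_i])), "\\s+")[[1]])
  if (length(p) != k) stop("positions count (", length(p), ") != segsites (", k, ")")
  rows <- block[seq.int(pos_i + 1L, length(block))]
  rows <- rows[grepl("^[01]+$", rows)]
  if (length(rows) < 2L) stop("ms replicate with fewer than 2 haplotype rows")
  if (any(nchar(rows) != k)) stop("haplotype row length mismatch with segsites")
  geno <- matrix(as.integer(unlist(strsplit(rows, "", fixed = TRUE))),
                 nrow = length(rows), ncol = k, byrow = TRUE)
  if (is.unsorted(p)) {
    warning("ms positions not monotone; sorting (ties keep input order)")
    o <- order(p)
    p <- p[o]
    geno <- geno[, o, drop = FALSE]
  }
  pos <- p * region_length
  # perturb later duplicates so positions are strictly increasing
  while (any(dup <- duplicated(pos))) {
    pos[dup] <- pos[dup] + 1e-6 * region_length
    pos <- sort(pos)
  }
  snp_matrix(geno, pos, "binary")
}

#' Write binary replicates in ms format
#'
#' Emits the dialect [read_ms()] consumes: a `//` delimiter per
#' replicate, `segsites:`, `positions:` (fractions of `region_length`,
#' 6 decimals), and 0/1 haplotype rows. Round-trips through [read_ms()]
#' exactly to 6 decimals.
#'
#' @param reps a [snp_matrix] or list of binary snp_matrix objects
#' @param path output file path
#' @param region_length bp length used to rescale positions to \[0,1\]
#' @param header logical; write the customary 2-line ms header
#' @return `path`, invisibly.
#' @export
write_ms <- function(reps, path, region_length = 1e6, header = TRUE) {
  if (inherits(reps, "snp_matrix")) reps <- list(reps)
  for (r in reps) {
    if (!inherits(r, "snp_matrix") || r$alphabet != "binary") {
      stop("write_ms expects binary snp_matrix replicates")
    }
  }
  con <- file(path, "wt")
  on.exit(close(con))
  if (header) {
    n <- if (length(reps) && n_snps(reps[[1]]) > 0) n_samples(reps[[1]]) else 0L
    writeLines(c(sprintf("ms %d %d", n, length(reps)), ""), con)
  }
  for (r in reps) {
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", n_snps(r)), con)
    if (n_snps(r) > 0L) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", r$positions / region_length),
                             collapse = " ")), con)
      writeLines(apply(r$geno, 1L, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a VCF subset into a DNA snp_matrix
#'
#' Uses only biallelic SNP records (single-nucleotide REF and ALT);
#' multi-allelic and indel records are skipped with a message. Every
#' diploid sample contributes two haplotypes, so the output has twice as
#' many rows as the VCF has samples. Unphased heterozygotes (`0/1`) are
#' split as (0,1) in sample order; missing genotypes (`./.`) mark both
#' haplotypes invalid at that SNP.
#'
#' @param path path to a VCF (v4.x, plain or bgzipped) with GT fields
#' @return A DNA [snp_matrix].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no genotype columns")
  fmt <- v@gt[, 1L]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1)))) {
    stop("VCF records without a GT field")
  }
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  pos <- as.numeric(v@fix[, "POS"])
  biallelic <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% dna_letters & alt %in% dna_letters
  nskip <- sum(!biallelic)
  if (nskip > 0L) {
    message(nskip, " non-biallelic-SNP record(s) skipped")
  }
  keep <- which(biallelic)
  if (length(keep) == 0L) stop("no biallelic SNP records in VCF")
  gt <- v@gt[keep, -1L, drop = FALSE]
  gt_field <- function(x) sub(":.*$", "", x)
  nsam <- ncol(gt)
  nhap <- 2L * nsam
  S <- length(keep)
  geno <- matrix(NA_integer_, nhap, S)
  ref_code <- match(ref[keep], dna_letters)
  alt_code <- match(alt[keep], dna_letters)
  for (j in seq_len(S)) {
    g <- gt_field(gt[j, ])
    al <- strsplit(g, "[|/]")
    h <- matrix(NA_integer_, 2L, nsam)
    for (s in seq_len(nsam)) {
      a <- suppressWarnings(as.integer(al[[s]]))
      if (length(a) == 2L && !anyNA(a)) h[, s] <- a
    }
    code <- ifelse(is.na(h), NA_integer_,
                   ifelse(h == 0L, ref_code[j], alt_code[j]))
    geno[, j] <- as.vector(code)  # haplotypes (s1.a, s1.b, s2.a, ...)
  }
  o <- order(pos[keep])
  snp_matrix(geno[, o, drop = FALSE], pos[keep][o], "dna")
}
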