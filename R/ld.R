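#' State-pair counts for a SNP pair
#'
#' Tabulates, over the samples valid at *both* SNPs, the per-state counts
#' at each SNP and the joint state-pair counts. These are the
#' ingredients of the squared correlation coefficient: marginal
#' frequencies p_s and joint frequencies p_st, all with the
#' jointly-valid sample count as denominator.
#'
#' @param snps a [snp_matrix]
#' @param i,j distinct SNP column indices
#' @return A list of class `state_pair_counts`: `n_valid_pairs`,
#'   `count_i`, `count_j` (named per-state counts), `count_ij` (joint
#'   count matrix, states of SNP i in rows), `n_total` (sample size n),
#'   and `degenerate` (`TRUE` when fewer than 2 jointly-valid samples).
#' @export
pair_counts <- function(snps, i, j) {
  stopifnot(inherits(snps, "snp_matrix"), i != j)
  states <- if (snps$alphabet == "binary") c("0", "1") else dna_letters
  vi <- snps$geno[, i]
  vj <- snps$geno[, j]
  ok <- !is.na(vi) & !is.na(vj)
  vi <- vi[ok]
  vj <- vj[ok]
  off <- if (snps$alphabet == "binary") 1L else 0L
  k <- length(states)
  ci <- tabulate(vi + off, nbins = k)
  cj <- tabulate(vj + off, nbins = k)
  cij <- matrix(tabulate((vi + off - 1L) * k + (vj + off), nbins = k * k),
                nrow = k, ncol = k, byrow = TRUE,
                dimnames = list(states, states))
  names(ci) <- names(cj) <- states
  structure(list(n_valid_pairs = length(vi), count_i = ci, count_j = cj,
                 count_ij = cij, n_total = n_samples(snps),
                 degenerate = length(vi) < 2L),
            class = "state_pair_counts")
}

#' Squared correlation coefficient for binary SNPs
#'
#' r2 between the derived (state 1) indicators of two binary SNPs:
#' r2 = (p11 - p1 p1')^2 / (p1 (1-p1) p1' (1-p1')), frequencies taken
#' over the jointly-valid samples. A SNP monomorphic over that
#' intersection yields 0 rather than an error so scans can proceed.
#'
#' @param c a `state_pair_counts` from [pair_counts()] on binary data
#' @return r2 in \[0, 1\].
#' @export
r2_binary <- function(c) {
  stopifnot(inherits(c, "state_pair_counts"))
  if (c$degenerate) return(0)
  n <- c$n_valid_pairs
  p1 <- c$count_i[["1"]] / n
  p2 <- c$count_j[["1"]] / n
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) return(0)
  p12 <- c$count_ij["1", "1"] / n
  d <- p12 - p1 * p2
  (d * d) / (p1 * p2 * (1 - p1) * (1 - p2))
}

#' Squared correlation coefficient for DNA SNPs
#'
#' Multi-state extension of [r2_binary()]: sums the per-state-pair r2
#' terms over state pairs segregating at both member states, scaled by
#' `(v_i - 1)(v_j - 1) v_ij / (v_i v_j)` where `v_i`, `v_j` are the
#' numbers of states present at each SNP (over jointly-valid samples)
#' and `v_ij` is the *fraction* of samples valid at both SNPs. With that
#' normalization the value equals [r2_binary()] exactly on gap-free
#' biallelic data; it can exceed 1 for multi-allelic sites.
#'
#' @param c a `state_pair_counts` from [pair_counts()] on DNA data
#' @return non-negative real; 0 when either SNP has fewer than 2 states
#'   over the jointly-valid samples.
#' @export
r2_dna <- function(c) {
  stopifnot(inherits(c, "state_pair_counts"))
  if (c$degenerate) return(0)
  n <- c$n_valid_pairs
  vi <- sum(c$count_i > 0L)
  vj <- sum(c$count_j > 0L)
  if (vi < 2L || vj < 2L) return(0)
  vij <- n / c$n_total
  acc <- 0
  for (a in seq_along(c$count_i)) {
    pa <- c$count_i[[a]] / n
    if (pa <= 0 || pa >= 1) next
    for (b in seq_along(c$count_j)) {
      pb <- c$count_j[[b]] / n
      if (pb <= 0 || pb >= 1) next
      pab <- c$count_ij[a, b] / n
      d <- pab - pa * pb
      acc <- acc + (d * d) / (pa * pb * (1 - pa) * (1 - pb))
    }
  }
  (vi - 1) * (vj - 1) * vij / (vi * vj) * acc
}

#' r2 for one SNP pair, dispatching on kernel
#' @noRd
r2_pair <- function(snps, i, j, kernel = c("binary", "dna")) {
  kernel <- match.arg(kernel)
  c <- pair_counts(snps, i, j)
  if (kernel == "binary") r2_binary(c) else r2_dna(c)
}

#' All pairwise r2 values of a snp_matrix
#'
#' Returns the symmetric S x S matrix of squared correlation
#' coefficients. Complete binary data take a vectorized cross-product
#' path (joint counts for all pairs at once); data with missing
#' observations or a DNA alphabet fall back to per-pair counting. Both
#' paths evaluate the identical frequency arithmetic.
#'
#' @param snps a [snp_matrix]
#' @param kernel `"binary"` or `"dna"`; default follows the alphabet
#' @return numeric S x S matrix, zero diagonal.
#' @export
ld_r2_matrix <- function(snps, kernel = snps$alphabet) {
  kernel <- match.arg(kernel, c("binary", "dna"))
  S <- n_snps(snps)
  if (S == 0L) return(matrix(numeric(0), 0, 0))
  if (kernel == "binary" && snps$alphabet == "binary" && !anyNA(snps$geno)) {
    X <- snps$geno
    storage.mode(X) <- "double"
    n <- nrow(X)
    n11 <- crossprod(X)               # joint '1,1' counts, exact integers
    c1 <- diag(n11)
    p1 <- c1 / n
    d <- n11 / n - outer(p1, p1)
    den <- outer(p1 * (1 - p1), p1 * (1 - p1))
    r2 <- (d * d) / den
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    return(unname(r2))
  }
  r2 <- matrix(0, S, S)
  for (i in seq_len(S - 1L)) {
    for (j in seq.int(i + 1L, S)) {
      r2[i, j] <- r2[j, i] <- r2_pair(snps, i, j, kernel)
    }
  }
  r2
}
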