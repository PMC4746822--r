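#' Unfolded site frequency spectrum of a window
#'
#' Counts derived ('1') alleles per site over a window of a binary SNP
#' matrix, following the infinite-sites convention that 0 is ancestral.
#' Sites with any invalid sample are excluded (the classical statistics
#' below assume complete columns). Sites fixed for 0 or 1 within the
#' window contribute nothing.
#'
#' @param snps a binary [snp_matrix]
#' @param window SNP column indices (default: all)
#' @return A list of class `sfs`: `n` (sample size), `counts` (length
#'   n-1; `counts[i]` = number of sites with i derived copies), `S`
#'   (segregating sites), `eta_s` (singletons).
#' @export
sfs <- function(snps, window = seq_len(n_snps(snps))) {
  stopifnot(inherits(snps, "snp_matrix"))
  if (snps$alphabet != "binary") stop("sfs expects a binary snp_matrix")
  n <- n_samples(snps)
  g <- snps$geno[, window, drop = FALSE]
  complete <- colSums(is.na(g)) == 0L
  dc <- colSums(g[, complete, drop = FALSE])
  dc <- dc[dc >= 1L & dc <= n - 1L]
  counts <- tabulate(dc, nbins = n - 1L)
  structure(list(n = n, counts = counts, S = sum(counts),
                 eta_s = counts[1L]),
            class = "sfs")
}

#' Build an sfs object directly from derived-allele counts
#' @param n sample size
#' @param counts length n-1 vector of site counts per derived count
#' @return an `sfs`
#' @export
sfs_from_counts <- function(n, counts) {
  stopifnot(length(counts) == n - 1L, all(counts >= 0))
  structure(list(n = n, counts = as.numeric(counts), S = sum(counts),
                 eta_s = counts[1L]),
            class = "sfs")
}

harmonic <- function(n, p = 1) sum(1 / seq_len(n)^p)

#' Theta estimators from the site frequency spectrum
#'
#' `theta_pi` is the mean number of pairwise differences
#' (sum_i counts\[i\] i (n - i) / C(n, 2)); `theta_w` is Watterson's
#' S / a_n with a_n = sum_{k<n} 1/k; `theta_h` is the site-homozygosity
#' estimator sum_i counts\[i\] 2 i^2 / (n (n - 1)); `theta_l` is the
#' mean derived-allele count sum_i counts\[i\] i / (n - 1). All are
#' unbiased for theta = 4 N mu under neutrality.
#'
#' @param spec an [sfs]
#' @return numeric scalar
#' @export
theta_pi <- function(spec) {
  i <- seq_len(spec$n - 1L)
  sum(spec$counts * i * (spec$n - i)) / choose(spec$n, 2)
}

#' @rdname theta_pi
#' @export
theta_w <- function(spec) spec$S / harmonic(spec$n - 1L)

#' @rdname theta_pi
#' @export
theta_h <- function(spec) {
  i <- seq_len(spec$n - 1L)
  sum(spec$counts * 2 * i^2) / (spec$n * (spec$n - 1L))
}

#' @rdname theta_pi
#' @export
theta_l <- function(spec) {
  i <- seq_len(spec$n - 1L)
  sum(spec$counts * i) / (spec$n - 1L)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity and Watterson
#' estimators of theta; negative in the proximity of a selective sweep
#' (excess of rare variants), with constants from Tajima (1989).
#'
#' @param spec an [sfs]
#' @return D, or NaN (with a warning) when S = 0.
#' @export
tajimas_d <- function(spec) {
  n <- spec$n
  S <- spec$S
  if (S < 1) {
    warning("Tajima's D undefined for S = 0")
    return(NaN)
  }
  a1 <- harmonic(n - 1L)
  a2 <- harmonic(n - 1L, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi(spec) - theta_w(spec)) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D* and F*
#'
#' Star (no-outgroup) versions of the Fu & Li (1993) tests, contrasting
#' the total number of mutations with the singleton count (D*) or with
#' pairwise diversity (F*), using the corrected variance constants of
#' Simonsen, Churchill and Aquadro (1995). Both go negative under the
#' singleton excess that follows a selective sweep.
#'
#' @param spec an [sfs]
#' @return the statistic, or NaN (with a warning) when S = 0.
#' @export
fu_li_dstar <- function(spec) {
  n <- spec$n
  S <- spec$S
  if (S < 1) {
    warning("Fu & Li D* undefined for S = 0")
    return(NaN)
  }
  k <- fu_li_constants(n)
  num <- (n / (n - 1)) * S - k$an * spec$eta_s
  num / sqrt(k$uD * S + k$vD * S^2)
}

#' @rdname fu_li_dstar
#' @export
fu_li_fstar <- function(spec) {
  n <- spec$n
  S <- spec$S
  if (S < 1) {
    warning("Fu & Li F* undefined for S = 0")
    return(NaN)
  }
  k <- fu_li_constants(n)
  num <- theta_pi(spec) - ((n - 1) / n) * spec$eta_s
  num / sqrt(k$uF * S + k$vF * S^2)
}

# Simonsen et al. (1995) corrected constants for the star statistics
fu_li_constants <- function(n) {
  an <- harmonic(n - 1L)
  bn <- harmonic(n - 1L, 2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           (4 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  list(an = an, bn = bn, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Normalized Fay and Wu's H
#'
#' The high-frequency-derived-allele test in the normalized form of
#' Zeng et al. (2006): (theta_pi - theta_L) / sqrt(Var), where theta_L
#' is the mean derived-allele count estimator. Since
#' theta_pi - theta_H = 2 (theta_pi - theta_L), the sign and zero set
#' agree with the classical H = theta_pi - theta_H; strongly negative
#' right after a selective sweep.
#'
#' @param spec an [sfs]
#' @return H', or NaN (with a warning) when S = 0.
#' @export
fay_wu_h_norm <- function(spec) {
  n <- spec$n
  S <- spec$S
  if (S < 1) {
    warning("normalized H undefined for S = 0")
    return(NaN)
  }
  an <- harmonic(n - 1L)
  bn <- harmonic(n - 1L, 2)
  bn1 <- bn + 1 / n^2                       # sum_{i<=n} 1/i^2
  th <- S / an
  th2 <- S * (S - 1) / (an^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th2
  (theta_pi(spec) - theta_l(spec)) / sqrt(v)
}

#' Depaulis and Veuille K and H
#'
#' Haplotype diversity over a window: K is the number of distinct
#' haplotypes; H is the haplotype heterozygosity
#' (1 - sum f_h^2) n / (n - 1). Both drop near a completed selective
#' sweep. Samples with missing data in the window are excluded.
#'
#' @param snps a [snp_matrix]
#' @param window SNP column indices (default: all)
#' @return list with elements `K` (integer) and `H` (numeric).
#' @export
dv_k_h <- function(snps, window = seq_len(n_snps(snps))) {
  stopifnot(inherits(snps, "snp_matrix"))
  g <- snps$geno[, window, drop = FALSE]
  ok <- rowSums(is.na(g)) == 0L
  g <- g[ok, , drop = FALSE]
  n <- nrow(g)
  if (n < 2L) stop("Depaulis-Veuille statistics need >= 2 complete samples")
  hap <- apply(g, 1L, paste, collapse = "")
  f <- table(hap) / n
  list(K = length(f), H = (1 - sum(f^2)) * n / (n - 1))
}

#' Hudson's C estimator of the population recombination rate
#'
#' Moment estimator in the spirit of Hudson (1987): the observed
#' variance of pairwise differences is matched to its neutral
#' expectation pi + pi^2 h(C), where
#' h(C) = 2 Int_0^1 (1 - u) g(C u) du and
#' g(rho) = (rho + 18) / (rho^2 + 13 rho + 18) is the classical
#' correlation of coalescence times at two loci rho apart. Low values
#' indicate strong linkage, as near a selective sweep. The estimate is
#' clamped to \[0, `cmax`\]; when even C = 0 cannot produce a variance as
#' large as observed, 0 is returned with a warning.
#'
#' @param snps a binary [snp_matrix]
#' @param window SNP column indices (default: all)
#' @param cmax upper bound of the search interval (default 1e7)
#' @return C >= 0, or NaN (with a warning) when S < 2 or n < 3.
#' @export
hudsons_c <- function(snps, window = seq_len(n_snps(snps)), cmax = 1e7) {
  stopifnot(inherits(snps, "snp_matrix"))
  g <- snps$geno[, window, drop = FALSE]
  complete <- colSums(is.na(g)) == 0L
  g <- g[, complete, drop = FALSE]
  n <- nrow(g)
  S <- ncol(g)
  if (S < 2L || n < 3L) {
    warning("Hudson's C needs S >= 2 and n >= 3")
    return(NaN)
  }
  d <- as.matrix(stats::dist(g, method = "manhattan"))
  k <- d[upper.tri(d)]
  pi_hat <- mean(k)
  var_obs <- stats::var(k)
  if (!is.finite(var_obs) || pi_hat <= 0) {
    warning("degenerate window for Hudson's C")
    return(NaN)
  }
  h_of_c <- function(C) {
    if (C == 0) return(1)
    f <- function(u) 2 * (1 - u) * (C * u + 18) / ((C * u)^2 + 13 * C * u + 18)
    stats::integrate(f, 0, 1, rel.tol = 1e-9)$value
  }
  expected <- function(C) pi_hat + pi_hat^2 * h_of_c(C)
  if (var_obs >= expected(0)) return(0)
  if (var_obs <= expected(cmax)) {
    warning("observed variance below the C -> ", cmax, " expectation; clamping")
    return(cmax)
  }
  stats::uniroot(function(C) expected(C) - var_obs, c(0, cmax),
                 tol = 1e-6)$root
}
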