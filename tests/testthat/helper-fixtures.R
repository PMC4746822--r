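# shared fixture builders; everything is generated in code

# binary snp_matrix from a character matrix of 0/1 rows
bin_snps <- function(rows, positions = NULL) {
  g <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  if (is.null(positions)) positions <- seq_len(ncol(g))
  snp_matrix(g, positions, "binary")
}

# DNA snp_matrix from rows of A/C/G/T (N or - become NA)
dna_snps <- function(rows, positions = NULL) {
  ch <- do.call(rbind, strsplit(rows, ""))
  g <- matrix(match(ch, c("A", "C", "G", "T")), nrow(ch), ncol(ch))
  if (is.null(positions)) positions <- seq_len(ncol(g))
  snp_matrix(g, positions, "dna")
}

# random polymorphic binary matrix (complete data)
random_bin_snps <- function(n, S, positions = sort(runif(S, 1, 1e5))) {
  g <- matrix(rbinom(n * S, 1L, runif(1, 0.2, 0.8)), n, S)
  for (j in seq_len(S)) {           # force polymorphism
    if (all(g[, j] == g[1L, j])) {
      g[sample(n, 1L), j] <- 1L - g[1L, j]
    }
  }
  snp_matrix(g, positions, "binary")
}

# brute-force LD sums over a window: direct double loops
brute_region_sums <- function(r2, s) {
  W <- nrow(r2)
  sumL <- 0; sumR <- 0; sumX <- 0
  for (a in seq_len(W - 1L)) for (b in seq.int(a + 1L, W)) {
    if (b <= s) sumL <- sumL + r2[a, b]
    else if (a > s) sumR <- sumR + r2[a, b]
    else sumX <- sumX + r2[a, b]
  }
  c(sumL = sumL, sumR = sumR, sumX = sumX)
}

brute_M_entry <- function(r2, i, j) {
  if (i <= j) return(0)
  tot <- 0
  for (a in j:(i - 1L)) for (b in (a + 1L):i) tot <- tot + r2[a, b]
  tot
}

# brute-force Eq-style r2 for binary columns (independent of pair_counts)
brute_r2_binary <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  p1 <- sum(x) / n; p2 <- sum(y) / n
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(0)
  p12 <- sum(x == 1 & y == 1) / n
  (p12 - p1 * p2)^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

# exhaustive omega maximisation over all admissible border pairs
brute_best_omega <- function(snps, pos, p) {
  S <- n_snps(snps)
  r2 <- ld_r2_matrix(snps)
  positions <- snps$positions
  left <- which(positions <= pos & positions >= pos - p$maxwin)
  right <- which(positions > pos & positions <= pos + p$maxwin)
  if (length(left) < 2 || length(right) < 2) return(list(omega = 0))
  s <- max(left)
  core_l <- left[positions[left] > pos - p$minwin]
  core_r <- right[positions[right] < pos + p$minwin]
  a_in <- if (length(core_l)) min(core_l) else max(left)
  b_in <- if (length(core_r)) max(core_r) else min(right)
  best <- list(omega = -1)
  for (a in min(left):min(a_in, s - 1L)) for (b in max(b_in, s + 2L):max(right)) {
    l <- s - a + 1L; r <- b - s; W <- l + r
    if (l < 2 || r < 2 || W < p$minsnps) next
    if (is.finite(p$balance) && abs(l - r) > p$balance) next
    sums <- brute_region_sums(r2[a:b, a:b, drop = FALSE], l)
    om <- ((sums[1] + sums[2]) / (choose(l, 2) + choose(r, 2))) /
      (max(sums[3], 1e-9) / (l * r))
    if (om > best$omega) best <- list(omega = unname(om), l = l, W = W,
                                      a = a, b = b)
  }
  if (best$omega < 0) list(omega = 0) else best
}

sim_small <- function(...) sim_params(n_samples = 10, pop_size = 200,
                                      theta_total = 10, rho_total = 0, ...)

snp_subset_test <- function(x, j) {
  snp_matrix(x$geno[, j, drop = FALSE], x$positions[j], x$alphabet)
}
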