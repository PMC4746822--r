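# independent transcription of the Tajima (1989) constants, kept local
# to the tests so the package implementation is checked against a
# second derivation
tajima_oracle <- function(n, S, pi_) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_ - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

test_that("the SFS counts derived alleles with ancestral state 0", {
  s <- bin_snps(c("11", "10", "01", "00"))
  sp <- sfs(s)
  expect_equal(sp$counts, c(0, 2, 0))
  expect_equal(sp$S, 2)
  expect_equal(sp$eta_s, 0)
  expect_equal(sfs(s, integer(0))$S, 0)
  s2 <- bin_snps(c("10", "00", "00", "01", "01"))
  expect_equal(sfs(s2)$eta_s, 1)
})

test_that("theta estimators match hand evaluation on the n = 4 fixture", {
  sp <- sfs_from_counts(4, c(0, 2, 0))
  expect_equal(theta_pi(sp), 4 / 3)
  expect_equal(theta_w(sp), 2 / (1 + 1 / 2 + 1 / 3))
  expect_equal(theta_h(sp), 4 / 3)
  expect_equal(theta_pi(sp) - theta_h(sp), 0)   # symmetric spectrum
})

test_that("Tajima's D matches an independent transcription and sign logic", {
  sp <- sfs_from_counts(4, c(0, 2, 0))
  expect_equal(tajimas_d(sp), tajima_oracle(4, 2, 4 / 3), tolerance = 1e-12)
  expect_equal(round(tajimas_d(sp), 2), 1.89)
  # singleton excess drives D negative
  lots <- sfs_from_counts(10, c(20, rep(0, 8)))
  expect_lt(tajimas_d(lots), 0)
  expect_warning(d0 <- tajimas_d(sfs_from_counts(4, c(0, 0, 0))), "S = 0")
  expect_true(is.nan(d0))
  # random spectra agree with the oracle
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    counts <- rpois(n - 1, 2)
    if (sum(counts) == 0) counts[1] <- 1
    sp <- sfs_from_counts(n, counts)
    expect_equal(tajimas_d(sp), tajima_oracle(n, sp$S, theta_pi(sp)),
                 tolerance = 1e-12)
  }
})

test_that("Fu & Li star statistics carry the expected signs", {
  all_single <- sfs_from_counts(10, c(12, rep(0, 8)))
  expect_lt(fu_li_dstar(all_single), 0)
  expect_lt(fu_li_fstar(all_single), 0)
  mid <- sfs_from_counts(10, c(0, 0, 0, 3, 4, 3, 0, 0, 0))
  expect_gt(fu_li_dstar(mid), 0)
  expect_gt(fu_li_fstar(mid), 0)
  expect_warning(x <- fu_li_dstar(sfs_from_counts(5, rep(0, 4))), "S = 0")
  expect_true(is.nan(x))
})

test_that("normalized Fay-Wu H is zero on symmetric spectra, negative on high-frequency excess", {
  sym <- sfs_from_counts(4, c(0, 2, 0))
  expect_equal(fay_wu_h_norm(sym), 0)
  high <- sfs_from_counts(10, c(0, 0, 0, 0, 0, 0, 2, 6, 8))
  expect_lt(fay_wu_h_norm(high), 0)
  # variance formula cross-checked against a separate transcription
  set.seed(5)
  for (i in 1:10) {
    n <- 10
    counts <- rpois(9, 1.5)
    if (sum(counts) == 0) counts[3] <- 2
    sp <- sfs_from_counts(n, counts)
    S <- sp$S
    an <- sum(1 / (1:9)); bn <- sum(1 / (1:9)^2); bn1 <- sum(1 / (1:10)^2)
    th <- S / an; th2 <- S * (S - 1) / (an^2 + bn)
    v <- (n - 2) / (6 * (n - 1)) * th +
      (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
        (9 * n * (n - 1)^2) * th2
    tl <- sum(seq_len(9) * sp$counts) / 9
    expect_equal(fay_wu_h_norm(sp), (theta_pi(sp) - tl) / sqrt(v),
                 tolerance = 1e-12)
  }
})

test_that("haplotype diversity counts distinct haplotypes", {
  s <- bin_snps(c("00", "01", "10", "11"))
  kh <- dv_k_h(s)
  expect_equal(kh$K, 4)
  expect_equal(kh$H, 1)
  same <- bin_snps(c("01", "01", "01", "10"))
  kh2 <- dv_k_h(same)
  expect_equal(kh2$K, 2)
  two <- bin_snps(c("11", "11", "00", "00"))
  kh3 <- dv_k_h(two)
  expect_equal(kh3$K, 2)
  expect_equal(kh3$H, (1 - 0.5) * 4 / 3)
})

test_that("Hudson's C rises from linked to independent data", {
  set.seed(14)
  n <- 20
  # perfectly linked: identical columns
  hap <- rbinom(n, 1, 0.5)
  while (sum(hap) %in% c(0, n)) hap <- rbinom(n, 1, 0.5)
  linked <- snp_matrix(matrix(hap, n, 12), 1:12, "binary")
  c_linked <- hudsons_c(linked)
  expect_lt(c_linked, 5)   # no-recombination end
  # shuffled columns destroy LD
  g <- matrix(hap, n, 30)
  for (j in 1:30) g[, j] <- sample(g[, j])
  shuffled <- snp_matrix(g, 1:30, "binary")
  c_shuffled <- suppressWarnings(hudsons_c(shuffled))
  expect_gt(c_shuffled, c_linked)
  # undefined below the preconditions
  one <- bin_snps(c("1", "1", "0"))
  expect_warning(x <- hudsons_c(one), "S >= 2")
  expect_true(is.nan(x))
})

test_that("statistics are invariant under sample reordering; relabeling flips only the unfolded ones", {
  set.seed(6)
  s <- random_bin_snps(12, 15)
  perm <- snp_matrix(s$geno[sample(12), ], s$positions, "binary")
  expect_equal(theta_pi(sfs(s)), theta_pi(sfs(perm)))
  expect_equal(tajimas_d(sfs(s)), tajimas_d(sfs(perm)))
  expect_equal(dv_k_h(s)$H, dv_k_h(perm)$H)
  flipped <- snp_matrix(1L - s$geno, s$positions, "binary")
  expect_equal(theta_pi(sfs(flipped)), theta_pi(sfs(s)))
  expect_equal(dv_k_h(flipped)$H, dv_k_h(s)$H)
  asym <- sfs_from_counts(8, c(5, 1, 0, 0, 0, 0, 2))
  flip_counts <- rev(asym$counts)
  expect_false(isTRUE(all.equal(theta_h(asym),
                                theta_h(sfs_from_counts(8, flip_counts)))))
})
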