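test_that("LD-sum table base cases and brute-force equivalence", {
  s2 <- bin_snps(c("11", "10", "01", "00"))
  M2 <- build_ld_sums(s2, 1, 2)
  expect_equal(M2$M[2, 1], r2_binary(pair_counts(s2, 1, 2)))
  expect_equal(M2$M[1, 1], 0)

  # three identical columns: all pairwise r2 = 1, M[3,1] counts 3 pairs
  s3 <- bin_snps(c("111", "111", "000", "000"))
  M3 <- build_ld_sums(s3, 1, 3)
  expect_equal(M3$M[3, 1], 3)

  set.seed(21)
  s6 <- random_bin_snps(10, 6)
  r2 <- ld_r2_matrix(s6)
  M6 <- build_ld_sums(s6, 1, 6, r2 = r2)
  for (i in 1:6) for (j in 1:i) {
    expect_equal(M6$M[i, j], brute_M_entry(r2, i, j), tolerance = 1e-10)
  }
})

test_that("region sums decompose the total and match brute force", {
  set.seed(5)
  s <- random_bin_snps(8, 7)
  r2 <- ld_r2_matrix(s)
  M <- build_ld_sums(s, 1, 7, r2 = r2)
  for (sp in 1:6) {
    rs <- region_sums(M, sp)
    expect_equal(rs, brute_region_sums(r2, sp), tolerance = 1e-10)
    expect_equal(unname(sum(rs)), M$M[7, 1], tolerance = 1e-12)
  }
  expect_equal(unname(region_sums(M, 1)["sumL"]), 0)
})

test_that("omega arithmetic follows the ratio definition", {
  expect_equal(omega_value(1, 1, 0.4, 2, 4), 10)
  # homogeneous LD: numerator and denominator averages cancel
  r <- 0.37
  for (l in 2:4) {
    W <- 7
    expect_equal(omega_value(choose(l, 2) * r, choose(W - l, 2) * r,
                             l * (W - l) * r, l, W), 1)
  }
  # zero cross sum floors at eps
  expect_equal(omega_value(1, 1, 0, 2, 4), 1 / (1e-9 / 4))
  expect_error(omega_value(1, 1, 1, 1, 4), "2 <= l")
  # scaling all sums leaves omega unchanged (ratio statistic)
  expect_equal(omega_value(3 * 2, 3 * 1.5, 3 * 0.7, 3, 8),
               omega_value(2, 1.5, 0.7, 3, 8))
})

test_that("grids are equidistant and inclusive", {
  expect_equal(make_grid(0, 1000, 5), c(0, 250, 500, 750, 1000))
  expect_equal(make_grid(0, 1000, 1), 500)
  expect_equal(make_grid(100, 101, 3), c(100, 100.5, 101))
})

test_that("scan_location finds the block boundary of a two-block sweep toy", {
  # two perfectly linked 5-SNP blocks; the cross-block D is exactly 0,
  # so the floored cross sum makes l = r = 5 the unique maximiser
  left <- c("1", "1", "1", "1", "0", "0", "0", "0")
  right <- c("1", "1", "0", "0", "1", "1", "0", "0")
  rows <- paste0(strrep(left, 5), strrep(right, 5))
  s <- bin_snps(rows, positions = c(100, 200, 300, 400, 450,
                                    551, 600, 700, 800, 900))
  p <- scan_params(grid_size = 1, minwin = 60, maxwin = 500, minsnps = 4)
  res <- scan_location(s, 500.5, p)
  expect_equal(res$best_l, 5L)
  expect_equal(res$best_W, 10L)
  oracle <- brute_best_omega(s, 500.5, p)
  expect_equal(res$omega_max, oracle$omega, tolerance = 1e-10)
  expect_equal(res$left_border, s$positions[oracle$a])
  expect_equal(res$right_border, s$positions[oracle$b])
})

test_that("scan_location equals the exhaustive oracle on random fixtures", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_bin_snps(10, 12, positions = sort(runif(12, 0, 1000)))
    p <- scan_params(grid_size = 1, minwin = runif(1, 20, 120),
                     maxwin = 900, minsnps = 4,
                     balance = sample(c(Inf, 4), 1))
    pos <- runif(1, 200, 800)
    res <- scan_location(s, pos, p)
    oracle <- brute_best_omega(s, pos, p)
    expect_equal(res$omega_max, oracle$omega, tolerance = 1e-10)
    if (oracle$omega > 0) expect_equal(res$best_W, oracle$W)
  }
})

test_that("too few flanking SNPs yields omega 0", {
  s <- bin_snps(c("1100", "1011", "0110", "0001"),
                positions = c(10, 20, 800, 900))
  p <- scan_params(grid_size = 1, minwin = 5, maxwin = 100, minsnps = 4)
  expect_equal(scan_location(s, 400, p)$omega_max, 0)
})

test_that("reuse of a shared LD table does not change results", {
  set.seed(8)
  s <- random_bin_snps(12, 20, positions = sort(runif(20, 0, 5000)))
  p <- scan_params(grid_size = 7, minwin = 100, maxwin = 2000, minsnps = 4)
  shared <- build_ld_sums(s, 1, 20)
  grid <- make_grid(s$positions[1], s$positions[20], 7)
  for (g in grid) {
    a <- scan_location(s, g, p)
    b <- scan_location(s, g, p, reuse = shared)
    expect_identical(a$omega_max, b$omega_max)
    expect_identical(a$left_border, b$left_border)
  }
})

test_that("omega_scan equals per-location scans and handles edge cases", {
  set.seed(12)
  s <- random_bin_snps(14, 25, positions = sort(runif(25, 0, 10000)))
  p <- scan_params(grid_size = 9, minwin = 200, maxwin = 4000, minsnps = 4)
  sc <- omega_scan(s, p)
  expect_equal(nrow(sc$report), 9)
  grid <- make_grid(s$positions[1], s$positions[25], 9)
  for (i in seq_along(grid)) {
    expect_identical(sc$report$omega[i],
                     scan_location(s, grid[i], p)$omega_max)
  }
  # D = 1 scans the midpoint
  p1 <- scan_params(grid_size = 1, minwin = 200, maxwin = 4000, minsnps = 4)
  sc1 <- omega_scan(s, p1)
  mid <- (s$positions[1] + s$positions[25]) / 2
  expect_equal(sc1$report$position, mid)
  expect_identical(sc1$report$omega, scan_location(s, mid, p1)$omega_max)

  empty <- snp_matrix(matrix(integer(0), 5, 0), numeric(0), "binary")
  expect_warning(sc0 <- omega_scan(empty, p), "empty")
  expect_equal(nrow(sc0$report), 0)
})

test_that("omega is invariant under sample permutation", {
  set.seed(77)
  s <- random_bin_snps(10, 15, positions = sort(runif(15, 0, 2000)))
  p <- scan_params(grid_size = 5, minwin = 100, maxwin = 1500, minsnps = 4)
  perm <- snp_matrix(s$geno[sample(10), ], s$positions, "binary")
  expect_equal(omega_scan(s, p)$report$omega,
               omega_scan(perm, p)$report$omega, tolerance = 1e-12)
})

test_that("homogeneous LD yields omega near 1", {
  # all columns identical: every r2 = 1
  rows <- c(rep("1111111111", 3), rep("0000000000", 3))
  s <- bin_snps(rows, positions = seq(100, 1000, by = 100))
  p <- scan_params(grid_size = 3, minwin = 150, maxwin = 900, minsnps = 4)
  sc <- omega_scan(s, p)
  om <- sc$report$omega
  expect_true(any(om > 0))
  expect_true(all(abs(om[om > 0] - 1) < 1e-9))
})
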