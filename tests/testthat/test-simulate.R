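test_that("identical seeds give identical replicates", {
  p <- sim_small()
  a <- simulate_neutral(p, 3, seed = 99)
  b <- simulate_neutral(p, 3, seed = 99)
  expect_identical(a, b)
  ps <- sim_params(n_samples = 8, pop_size = 100, theta_total = 20,
                   rho_total = 10,
                   sweep = list(position_fraction = 0.5, alpha = 200))
  sa <- simulate_sweep(ps, 2, seed = 7)
  sb <- simulate_sweep(ps, 2, seed = 7)
  expect_identical(sa, sb)
})

test_that("zero mutation rate yields zero SNPs", {
  p <- sim_params(n_samples = 6, pop_size = 100, theta_total = 0,
                  rho_total = 5)
  reps <- simulate_neutral(p, 5, seed = 1)
  expect_true(all(vapply(reps, n_snps, integer(1)) == 0L))
})

test_that("segregating sites match the coalescent expectation", {
  p <- sim_small()
  reps <- simulate_neutral(p, 400, seed = 123)
  S <- vapply(reps, n_snps, integer(1))
  expected <- 10 * sum(1 / (1:9))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("recombination weakens adjacent-SNP correlation", {
  adj <- function(r) {
    S <- n_snps(r)
    if (S < 2) return(NA_real_)
    m <- ld_r2_matrix(r)
    mean(m[cbind(1:(S - 1), 2:S)])
  }
  p0 <- sim_params(n_samples = 20, pop_size = 150, theta_total = 20,
                   rho_total = 0)
  p1 <- sim_params(n_samples = 20, pop_size = 150, theta_total = 20,
                   rho_total = 100)
  a0 <- mean(vapply(simulate_neutral(p0, 120, seed = 21), adj, numeric(1)),
             na.rm = TRUE)
  a1 <- mean(vapply(simulate_neutral(p1, 120, seed = 22), adj, numeric(1)),
             na.rm = TRUE)
  expect_gt(a0, a1)
})

test_that("conditioned trajectories start at one copy and end fixed", {
  p <- sim_params(n_samples = 10, pop_size = 100, theta_total = 10,
                  rho_total = 0,
                  sweep = list(position_fraction = 0.5, alpha = 500))
  set.seed(3)
  tr <- sample_trajectory(p)
  expect_equal(tr$counts[1], 1)
  expect_equal(tr$counts[length(tr$counts)], 200)
  expect_true(all(tr$counts >= 1))
  expect_equal(tr$L, length(tr$counts) - 1L)
  set.seed(11); t1 <- sample_trajectory(p)
  set.seed(11); t2 <- sample_trajectory(p)
  expect_identical(t1, t2)
})

test_that("stronger selection shortens the sojourn", {
  mk <- function(alpha) sim_params(n_samples = 10, pop_size = 100,
                                   theta_total = 10, rho_total = 0,
                                   sweep = list(position_fraction = 0.5,
                                                alpha = alpha))
  set.seed(5)
  weak <- replicate(60, sample_trajectory(mk(100))$L)
  strong <- replicate(60, sample_trajectory(mk(1000))$L)
  expect_lt(mean(strong), mean(weak))
})

test_that("a strong sweep removes diversity around its target", {
  ps <- sim_params(n_samples = 20, pop_size = 200, theta_total = 100,
                   rho_total = 100,
                   sweep = list(position_fraction = 0.5, alpha = 800))
  reps <- simulate_sweep(ps, 25, seed = 42)
  pi_in <- function(r, a, b) {
    idx <- which(r$positions >= a & r$positions <= b)
    if (!length(idx)) return(0)
    theta_pi(sfs(r, idx))
  }
  centre <- mean(vapply(reps, pi_in, numeric(1), 475e3, 525e3))
  flank <- mean(vapply(reps, pi_in, numeric(1), 0, 400e3))
  expect_lt(centre, flank)
  # the fixed beneficial site itself is absent
  expect_true(all(vapply(reps, function(r) {
    !any(abs(r$positions - 5e5) < 1e-6)
  }, logical(1))))
})

test_that("bottlenecks inflate the variance of S", {
  base <- sim_params(n_samples = 15, pop_size = 150, theta_total = 30,
                     rho_total = 0, demography = "constant")
  bn <- sim_params(n_samples = 15, pop_size = 150, theta_total = 30,
                   rho_total = 0, demography = "bottleneck3")
  Sc <- vapply(simulate_neutral(base, 150, seed = 8), n_snps, integer(1))
  Sb <- vapply(simulate_neutral(bn, 150, seed = 9), n_snps, integer(1))
  expect_gt(var(Sb) / mean(Sb), var(Sc) / mean(Sc))
})

test_that("simulated output round-trips through the ms dialect", {
  p <- sim_small()
  reps <- simulate_neutral(p, 2, seed = 31)
  f <- withr::local_tempfile()
  write_ms(reps, f, region_length = p$region_length)
  back <- read_ms(f, region_length = p$region_length)
  expect_equal(length(back), 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$geno, reps[[i]]$geno)
    expect_equal(back[[i]]$positions, reps[[i]]$positions, tolerance = 1)
  }
  expect_error(write_ms(dna_snps(c("AC", "CA")), f), "binary")
})
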