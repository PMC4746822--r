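test_that("SNP groups partition the sequence in order", {
  g <- build_snp_groups(300, 128)
  expect_equal(nrow(g), 3)
  expect_equal(g$size, c(128, 128, 44))
  expect_equal(g$first, c(1, 129, 257))
  expect_equal(nrow(build_snp_groups(128, 128)), 1)
  expect_equal(nrow(build_snp_groups(0, 128)), 0)
})

test_that("two neighbouring regions over three groups give five compute groups", {
  cl <- build_compute_list(list(c(1, 2), c(2, 3)))
  expect_equal(nrow(cl), 5)
  expect_equal(cl[, c("x", "y")],
               data.frame(x = c(1, 2, 3, 2, 3), y = c(1, 2, 3, 1, 2)),
               ignore_attr = TRUE)
  # one region over one group; duplicated regions deduplicate
  expect_equal(nrow(build_compute_list(list(c(2, 2)))), 1)
  expect_equal(build_compute_list(list(c(1, 3), c(1, 3))),
               build_compute_list(list(c(1, 3))))
})

test_that("overlapping regions share tiles and distant tiles are dropped", {
  a <- build_compute_list(list(c(1, 4)))
  b <- build_compute_list(list(c(3, 6)))
  both <- build_compute_list(list(c(1, 4), c(3, 6)))
  expect_lt(nrow(both), nrow(a) + nrow(b))
  expect_equal(anyDuplicated(both[, c("x", "y")]), 0)
  capped <- build_compute_list(list(c(1, 5)), max_diag = 2)
  expect_true(all(capped$x - capped$y <= 2))
})

test_that("diagonal batches respect the table dependencies", {
  cl <- build_compute_list(list(c(1, 4), c(3, 6)))
  batches <- split(cl, cl$diagonal)
  seen <- character(0)
  for (b in batches) {
    for (i in seq_len(nrow(b))) {
      x <- b$x[i]; y <- b$y[i]
      for (dep in list(c(x, y + 1), c(x - 1, y), c(x - 1, y + 1))) {
        key <- paste(dep, collapse = ".")
        in_plan <- any(cl$x == dep[1] & cl$y == dep[2] & dep[2] <= dep[1])
        if (in_plan) expect_true(key %in% seen)
      }
    }
    seen <- c(seen, paste(b$x, b$y, sep = "."))
  }
})

test_that("memory budgeting sets T and k as the layout allows", {
  set.seed(42)
  s <- random_bin_snps(8, 24, positions = sort(runif(24, 0, 2400)))
  p <- scan_params(grid_size = 8, minwin = 50, maxwin = 400, minsnps = 4)
  grid <- make_grid(s$positions[1], s$positions[24], 8)
  # unbounded budget: one iteration covers every location
  plan <- plan_iteration(grid, s, p, mem_limit = Inf, start = 1, G = 4)
  expect_equal(plan$k, 8)
  expect_equal(plan$locations, 1:8)
  # a budget below a single window errors with the needed amount
  expect_error(plan_iteration(grid, s, p, mem_limit = 64, start = 1, G = 4),
               "mem_limit too small")
  # a tight budget plans fewer locations
  small <- plan_iteration(grid, s, p,
                          mem_limit = nrow(plan$compute_list) * 16 * 8 / 2,
                          start = 1, G = 4)
  expect_lt(small$k, 8)
  expect_gte(small$k, 1)
})

test_that("a budget sized to the tiled layout reproduces T = 6, k = 4", {
  # 28 evenly spaced SNPs in groups of 4: the first four window regions
  # cover groups 1..6 (12 distinct tiles at diagonal cap 2); the fifth
  # window needs group 7, so a 12-tile budget stops the iteration at 4
  pos <- seq(50, 2750, by = 100)
  set.seed(3)
  s <- random_bin_snps(8, 28, positions = pos)
  p <- scan_params(grid_size = 5, minwin = 40, maxwin = 260, minsnps = 4)
  grid <- c(300, 800, 1300, 1800, 2300)
  budget <- 12 * 4^2 * 8
  plan <- plan_iteration(grid, s, p, mem_limit = budget, start = 1, G = 4)
  expect_equal(plan$T, 6L)
  expect_equal(plan$k, 4L)
  expect_equal(nrow(plan$compute_list), 12)
  # with one more tile of budget the fifth location fits as well
  plan5 <- plan_iteration(grid, s, p, mem_limit = 14 * 4^2 * 8,
                          start = 1, G = 4)
  expect_equal(plan5$k, 5L)
})

test_that("k adapts to SNP density at a fixed budget", {
  set.seed(11)
  dense_pos <- sort(runif(30, 0, 600))
  sparse_pos <- sort(runif(30, 0, 6000))
  dense <- random_bin_snps(8, 30, positions = dense_pos)
  sparse <- random_bin_snps(8, 30, positions = sparse_pos)
  p <- scan_params(grid_size = 6, minwin = 30, maxwin = 300, minsnps = 4)
  gd <- make_grid(dense_pos[1], dense_pos[30], 6)
  gs <- make_grid(sparse_pos[1], sparse_pos[30], 6)
  budget <- 40 * 16 * 8
  kd <- plan_iteration(gd, dense, p, budget, 1, G = 4)$k
  ks <- plan_iteration(gs, sparse, p, budget, 1, G = 4)$k
  expect_gte(ks, kd)
})

test_that("omega queues balance by SNP count under the LPT rule", {
  q <- balance_omega_queues(c(5, 3, 2, 2), 2)
  loads <- sapply(q, function(i) sum(c(5, 3, 2, 2)[i]))
  expect_equal(sort(loads), c(5, 7))
  expect_equal(sort(unlist(q)), 1:4)
  expect_equal(balance_omega_queues(c(4, 4), 1), list(1:2))
  q3 <- balance_omega_queues(rep(7, 10), 3)
  expect_lte(diff(range(lengths(q3))), 1)
})

test_that("executing a plan reproduces the plain scan bit for bit", {
  set.seed(19)
  s <- random_bin_snps(10, 32, positions = sort(runif(32, 0, 3200)))
  p <- scan_params(grid_size = 6, minwin = 60, maxwin = 600, minsnps = 4)
  grid <- make_grid(s$positions[1], s$positions[32], 6)
  sc <- omega_scan(s, p)
  start <- 1L
  got <- list()
  while (start <= length(grid)) {
    plan <- plan_iteration(grid, s, p, mem_limit = 60 * 16 * 8,
                           start = start, G = 4)
    got <- c(got, execute_plan(plan, s, p, grid))
    start <- start + plan$k
  }
  expect_length(got, 6)
  for (i in 1:6) {
    expect_identical(got[[i]]$omega_max, sc$report$omega[i])
    expect_identical(got[[i]]$left_border, sc$report$left_border[i])
    expect_identical(got[[i]]$right_border, sc$report$right_border[i])
  }
  # worker count must not change anything
  plan1 <- plan_iteration(grid, s, p, mem_limit = Inf, start = 1, G = 4)
  seq1 <- execute_plan(plan1, s, p, grid, workers = 1)
  seq2 <- execute_plan(plan1, s, p, grid, workers = 2)
  seq8 <- execute_plan(plan1, s, p, grid, workers = 8)
  for (i in 1:6) {
    expect_identical(seq1[[i]]$omega_max, seq2[[i]]$omega_max)
    expect_identical(seq1[[i]]$omega_max, seq8[[i]]$omega_max)
    expect_identical(seq1[[i]]$omega_max, sc$report$omega[i])
  }
})
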