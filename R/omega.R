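#' Cumulative LD-sum matrix
#'
#' Builds the lower-triangular dynamic-programming table M for SNPs
#' `f..t`: `M[i, j]` is the sum of r2 over all SNP pairs (a, b) with
#' `j <= a < b <= i` (window-local indices). The table satisfies the
#' recurrence `M[i,j] = M[i,j+1] + M[i-1,j] - M[i-1,j+1] + r2[i,j]` with
#' `M[i,i] = 0` and `M[i,i-1] = r2[i,i-1]`; rows are filled in one pass
#' using the equivalent unrolled form
#' `M[i,j] = M[i-1,j] + sum_{t=j}^{i-1} r2[i,t]`.
#'
#' Because each entry only sums pairs inside `j..i`, the table for any
#' sub-window is the corresponding sub-block of the table of a larger
#' window: overlapping scan windows can share one table (the data-reuse
#' optimization).
#'
#' @param snps a [snp_matrix]
#' @param f,t first and last SNP index of the window (t - f + 1 = W >= 2)
#' @param kernel `"binary"` or `"dna"`
#' @param r2 optional precomputed r2 matrix for SNPs `f..t` (window-local
#'   indexing); computed with [ld_r2_matrix()] when missing
#' @return An object of class `ld_sum_matrix`: `first_snp`, `W`, and the
#'   W x W matrix `M` (upper triangle zero).
#' @export
build_ld_sums <- function(snps, f = 1L, t = n_snps(snps),
                          kernel = snps$alphabet, r2 = NULL) {
  W <- t - f + 1L
  stopifnot(W >= 2L)
  if (is.null(r2)) {
    r2 <- ld_r2_matrix(snp_subset(snps, f:t), kernel = kernel)
  }
  stopifnot(nrow(r2) == W, ncol(r2) == W)
  structure(list(first_snp = f, W = W, M = ld_cumsum(r2)),
            class = "ld_sum_matrix")
}

#' DP fill of the cumulative LD-sum table from an r2 matrix
#' @noRd
ld_cumsum <- function(r2) {
  W <- nrow(r2)
  M <- matrix(0, W, W)
  if (W < 2L) return(M)
  for (i in 2:W) {
    js <- 1:(i - 1L)
    # sum_{t=j}^{i-1} r2[i,t], computed right-to-left within the row
    rowsum_tail <- rev(cumsum(rev(r2[i, js])))
    M[i, js] <- M[i - 1L, js] + rowsum_tail
  }
  M
}

#' Left / right / cross LD sums at a split
#'
#' Retrieves from an `ld_sum_matrix` the three sums the omega statistic
#' needs when the window of W SNPs is split after SNP `s` (window-local
#' index): `sumL` over pairs within SNPs `1..s`, `sumR` over pairs within
#' `s+1..W`, and `sumX` over pairs straddling the split.
#'
#' @param M an `ld_sum_matrix` from [build_ld_sums()]
#' @param s split index, `1 <= s < W`
#' @return Named numeric vector `c(sumL, sumR, sumX)`.
#' @export
region_sums <- function(M, s) {
  stopifnot(inherits(M, "ld_sum_matrix"), s >= 1L, s < M$W)
  W <- M$W
  sumL <- if (s >= 2L) M$M[s, 1L] else 0
  sumR <- if (s + 1L <= W - 1L) M$M[W, s + 1L] else 0
  sumX <- M$M[W, 1L] - sumL - sumR
  c(sumL = sumL, sumR = sumR, sumX = sumX)
}

#' The omega statistic from region sums
#'
#' omega = \[ (C(l,2) + C(W-l,2))^-1 (sumL + sumR) \] /
#'         \[ (l (W-l))^-1 sumX \].
#' A zero cross-sum is the ideal sweep signature but makes the ratio
#' undefined; `sumX` is floored at `eps` so a perfect split yields a
#' large finite omega while the ranking of candidate splits is
#' preserved.
#'
#' @param sumL,sumR,sumX region LD sums (see [region_sums()])
#' @param l SNP count of the left subregion
#' @param W total SNP count; both sides need at least 2 SNPs
#'   (`2 <= l <= W - 2`)
#' @param eps floor for the cross sum (default 1e-9)
#' @return omega >= 0.
#' @export
omega_value <- function(sumL, sumR, sumX, l, W, eps = 1e-9) {
  if (l < 2 || l > W - 2) stop("omega needs 2 <= l <= W - 2")
  num <- (sumL + sumR) / (choose(l, 2) + choose(W - l, 2))
  den <- pmax(sumX, eps) / (l * (W - l))
  num / den
}

#' Equidistant grid of scan locations
#'
#' @param first_pos,last_pos span to cover (bp), `first_pos < last_pos`
#' @param D number of locations; `D = 1` yields the midpoint
#' @return Numeric vector of D positions spanning the range inclusively.
#' @export
make_grid <- function(first_pos, last_pos, D) {
  stopifnot(D >= 1L, first_pos < last_pos)
  if (D == 1L) return((first_pos + last_pos) / 2)
  seq(first_pos, last_pos, length.out = D)
}

#' Scan parameters
#'
#' @param grid_size number of grid locations D
#' @param minwin minimum flank extent in bp: SNPs strictly closer than
#'   `minwin` to the location always contribute (the mandatory core)
#' @param maxwin maximum flank extent in bp (inclusive bound) for
#'   candidate window borders
#' @param minsnps minimum total SNP count W of an admissible window
#'   (each side additionally needs >= 2 SNPs)
#' @param balance maximum allowed |l - (W - l)| between the two sides
#'   (`Inf` disables the constraint)
#' @param no_singletons drop singleton SNPs before scanning
#' @param binary deduce DNA data to binary before scanning
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(grid_size = 1000L, minwin = 1000, maxwin = 20000,
                        minsnps = 5L, balance = Inf,
                        no_singletons = FALSE, binary = FALSE) {
  stopifnot(grid_size >= 1L, minwin > 0, maxwin > minwin, minsnps >= 2L,
            balance >= 0)
  structure(list(grid_size = as.integer(grid_size), minwin = minwin,
                 maxwin = maxwin, minsnps = as.integer(minsnps),
                 balance = balance, no_singletons = isTRUE(no_singletons),
                 binary = isTRUE(binary)),
            class = "scan_params")
}

#' Best omega at one grid location
#'
#' Implements the window semantics of the scan: SNPs strictly within
#' `minwin` of `pos` form the mandatory core; candidate left (right)
#' borders extend the core one SNP at a time out to `pos - maxwin`
#' (`pos + maxwin`, inclusive). Every border pair with at least 2 SNPs
#' per side, total SNPs >= `minsnps`, and (if set) side imbalance within
#' `balance` is evaluated; the maximum omega is reported. Ties prefer
#' the smallest window, then the leftmost left border. With no
#' admissible pair, omega is 0 and the borders are NA.
#'
#' @param snps a [snp_matrix]
#' @param pos grid location (bp)
#' @param p a [scan_params]
#' @param reuse optional precomputed LD sums for the whole dataset, as
#'   returned by [build_ld_sums()] over all SNPs (window tables are
#'   sub-blocks of it); purely an optimization, results are identical
#' @return A list of class `omega_result`: `position`, `omega_max`,
#'   `best_l`, `best_W`, `left_border`, `right_border`.
#' @export
scan_location <- function(snps, pos, p, reuse = NULL) {
  stopifnot(inherits(snps, "snp_matrix"), inherits(p, "scan_params"))
  positions <- snps$positions
  S <- n_snps(snps)
  empty <- function() {
    structure(list(position = pos, omega_max = 0, best_l = NA_integer_,
                   best_W = NA_integer_, left_border = NA_real_,
                   right_border = NA_real_),
              class = "omega_result")
  }
  if (S < 4L) return(empty())
  # SNPs on each side within maxwin (inclusive)
  left_all <- which(positions <= pos & positions >= pos - p$maxwin)
  right_all <- which(positions > pos & positions <= pos + p$maxwin)
  if (length(left_all) < 2L || length(right_all) < 2L) return(empty())
  s <- max(left_all)                 # last SNP on the left of the split
  # innermost border candidates: outermost core SNP (or nearest SNP when
  # the core is empty on that side)
  core_left <- left_all[positions[left_all] > pos - p$minwin]
  core_right <- right_all[positions[right_all] < pos + p$minwin]
  a_in <- if (length(core_left)) min(core_left) else max(left_all)
  b_in <- if (length(core_right)) max(core_right) else min(right_all)
  a_cand <- seq.int(min(left_all), a_in)      # left borders, leftmost first
  b_cand <- seq.int(b_in, max(right_all))
  l_cnt <- s - a_cand + 1L                    # SNPs on the left per border
  r_cnt <- b_cand - s
  keep_a <- l_cnt >= 2L
  keep_b <- r_cnt >= 2L
  if (!any(keep_a) || !any(keep_b)) return(empty())
  a_cand <- a_cand[keep_a]; l_cnt <- l_cnt[keep_a]
  b_cand <- b_cand[keep_b]; r_cnt <- r_cnt[keep_b]

  M <- if (!is.null(reuse)) {
    stopifnot(inherits(reuse, "ld_sum_matrix"), reuse$first_snp == 1L,
              reuse$W == S)
    reuse$M
  } else {
    f <- min(a_cand); t <- max(b_cand)
    # sub-window table; entries equal the global table's block
    build_ld_sums(snps, f, t, kernel = snps$alphabet)$M
  }
  off <- if (!is.null(reuse)) 0L else min(a_cand) - 1L
  ai <- a_cand - off; bi <- b_cand - off; si <- s - off

  sumL <- M[si, ai]                  # l_cnt >= 2 guarantees ai < si
  sumR <- M[cbind(bi, si + 1L)]      # r_cnt >= 2 guarantees si + 1 < bi
  tot <- M[cbind(rep(bi, each = length(ai)), rep(ai, times = length(bi)))]
  tot <- matrix(tot, length(ai), length(bi))
  sumX <- tot - sumL - rep(sumR, each = length(ai))

  lmat <- matrix(l_cnt, length(ai), length(bi))
  rmat <- matrix(r_cnt, length(ai), length(bi), byrow = TRUE)
  Wmat <- lmat + rmat
  adm <- Wmat >= p$minsnps
  if (is.finite(p$balance)) adm <- adm & abs(lmat - rmat) <= p$balance
  if (!any(adm)) return(empty())

  num <- (sumL + rep(sumR, each = length(ai))) /
    (choose(lmat, 2) + choose(rmat, 2))
  den <- pmax(sumX, 1e-9) / (lmat * rmat)
  om <- num / den
  om[!adm] <- -Inf
  best <- which(om == max(om))
  if (length(best) > 1L) {          # smallest window, then leftmost border
    bw <- Wmat[best]
    best <- best[bw == min(bw)]
    if (length(best) > 1L) {
      arow <- (best - 1L) %% length(ai) + 1L   # smaller row = more left
      best <- best[order(arow)][1L]
    }
  }
  best <- best[1L]
  arow <- (best - 1L) %% length(ai) + 1L
  bcol <- (best - 1L) %/% length(ai) + 1L
  structure(list(position = pos,
                 omega_max = om[best],
                 best_l = l_cnt[arow],
                 best_W = Wmat[best],
                 left_border = positions[a_cand[arow]],
                 right_border = positions[b_cand[bcol]]),
            class = "omega_result")
}

#' @export
print.omega_result <- function(x, ...) {
  cat(sprintf("omega_result @ %.2f: omega = %.4f (l = %s, W = %s, borders %.2f..%.2f)\n",
              x$position, x$omega_max,
              as.character(x$best_l), as.character(x$best_W),
              if (is.na(x$left_border)) NA else x$left_border,
              if (is.na(x$right_border)) NA else x$right_border))
  invisible(x)
}

#' Scan a dataset for selective sweeps with the omega statistic
#'
#' Evaluates the omega statistic at `grid_size` equidistant locations
#' spanning the polymorphic region (first to last SNP position). The
#' squared correlations and the cumulative LD-sum table are computed
#' once and shared by all overlapping windows (the data-reuse
#' optimization), so the result is identical to calling
#' [scan_location()] independently per location.
#'
#' @param snps a [snp_matrix]
#' @param p a [scan_params]; `no_singletons` and `binary` are applied
#'   here before scanning
#' @return An object of class `omega_scan`: `report` (data.frame with
#'   position, omega, left_border, right_border, l, W), `params`,
#'   `n_snps`, `n_samples`.
#' @export
omega_scan <- function(snps, p = scan_params()) {
  stopifnot(inherits(snps, "snp_matrix"), inherits(p, "scan_params"))
  if (p$binary && snps$alphabet == "dna") snps <- deduce_binary(snps)
  if (p$no_singletons) snps <- filter_singletons(snps)
  S <- n_snps(snps)
  if (S == 0L) {
    warning("empty snp_matrix: empty omega report")
    rep0 <- data.frame(position = numeric(0), omega = numeric(0),
                       left_border = numeric(0), right_border = numeric(0),
                       l = integer(0), W = integer(0))
    return(structure(list(report = rep0, params = p, n_snps = 0L,
                          n_samples = n_samples(snps)),
                     class = "omega_scan"))
  }
  if (S < p$minsnps) stop("fewer SNPs (", S, ") than minsnps (", p$minsnps, ")")
  grid <- make_grid(snps$positions[1L], snps$positions[S], p$grid_size)
  if (snps$alphabet == "binary" && !anyNA(snps$geno)) {
    # packed popcount kernel + banded table; agrees bitwise with the
    # plain-R path below
    eng <- .ld_scan_engine(snps$geno, snps$positions, grid, p$minwin,
                           p$maxwin, p$minsnps, p$balance, 1e-9)
    report <- data.frame(
      position = grid, omega = eng[, 1L], left_border = eng[, 4L],
      right_border = eng[, 5L], l = as.integer(eng[, 2L]),
      W = as.integer(eng[, 3L])
    )
  } else {
    shared <- build_ld_sums(snps, 1L, S, kernel = snps$alphabet)
    res <- lapply(grid, function(g) scan_location(snps, g, p, reuse = shared))
    report <- data.frame(
      position = vapply(res, `[[`, numeric(1), "position"),
      omega = vapply(res, `[[`, numeric(1), "omega_max"),
      left_border = vapply(res, `[[`, numeric(1), "left_border"),
      right_border = vapply(res, `[[`, numeric(1), "right_border"),
      l = vapply(res, `[[`, integer(1), "best_l"),
      W = vapply(res, `[[`, integer(1), "best_W")
    )
  }
  structure(list(report = report, params = p, n_snps = S,
                 n_samples = n_samples(snps)),
            class = "omega_scan")
}

#' @export
print.omega_scan <- function(x, ...) {
  cat(sprintf("omega_scan: %d grid locations, %d SNPs x %d samples\n",
              nrow(x$report), x$n_snps, x$n_samples))
  if (nrow(x$report)) {
    i <- which.max(x$report$omega)
    cat(sprintf("  max omega %.4f at position %.2f\n",
                x$report$omega[i], x$report$position[i]))
  }
  invisible(x)
}

#' @export
summary.omega_scan <- function(object, quantile = 0.95, ...) {
  rep <- object$report
  thr <- if (nrow(rep)) empirical_threshold(object, quantile) else NA_real_
  out <- list(n_locations = nrow(rep), n_snps = object$n_snps,
              n_samples = object$n_samples,
              omega_summary = summary(rep$omega),
              threshold = thr, threshold_quantile = quantile,
              candidates = rep[rep$omega > thr, , drop = FALSE])
  class(out) <- "summary.omega_scan"
  out
}

#' @export
print.summary.omega_scan <- function(x, ...) {
  cat(sprintf("omega scan over %d locations (%d SNPs x %d samples)\n",
              x$n_locations, x$n_snps, x$n_samples))
  print(x$omega_summary)
  cat(sprintf("empirical %.0fth-percentile threshold: %.4f\n",
              100 * x$threshold_quantile, x$threshold))
  cat(sprintf("%d location(s) above threshold\n", nrow(x$candidates)))
  invisible(x)
}

#' @export
plot.omega_scan <- function(x, ...) {
  rep <- x$report
  plot(rep$position, rep$omega, type = "l", xlab = "position (bp)",
       ylab = expression(omega), ...)
  i <- which.max(rep$omega)
  points(rep$position[i], rep$omega[i], pch = 19, col = "red")
  invisible(x)
}

#' Write an omega scan report to TSV
#'
#' @param x an `omega_scan`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "omega_scan"))
  utils::write.table(x$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
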