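#' Partition SNPs into contiguous groups of size G
#'
#' @param n_snps total SNP count
#' @param G group size (granularity factor; 128 in production, small
#'   values are useful to exercise the tiling on tiny data)
#' @return data.frame with one row per group: `index`, `first`, `last`,
#'   `size`. Groups partition the SNP sequence in order; all but the
#'   last have exactly G SNPs.
#' @export
build_snp_groups <- function(n_snps, G = 128L) {
  stopifnot(G >= 1L, n_snps >= 0L)
  if (n_snps == 0L) {
    return(data.frame(index = integer(0), first = integer(0),
                      last = integer(0), size = integer(0)))
  }
  ng <- ceiling(n_snps / G)
  first <- (seq_len(ng) - 1L) * G + 1L
  last <- pmin(seq_len(ng) * G, n_snps)
  data.frame(index = seq_len(ng), first = first, last = last,
             size = last - first + 1L)
}

#' Deduplicated compute list over genomic regions
#'
#' A compute group is a pair of SNP groups (x, y), y <= x, whose
#' pairwise LD contributions form one tile of the cumulative-sum table.
#' Each region (a contiguous SNP-group range) needs all its in-range
#' tiles up to `max_diag` off the diagonal (tiles further apart than
#' the maximum window are never read); overlapping regions share tiles,
#' which are listed once.
#'
#' @param regions list of `c(first_group, last_group)` pairs (or a
#'   2-column matrix), sorted
#' @param max_diag maximum allowed `x - y` (default `Inf`)
#' @return data.frame `x`, `y`, `diagonal = x - y`, ordered by diagonal
#'   then x.
#' @export
build_compute_list <- function(regions, max_diag = Inf) {
  if (is.matrix(regions)) regions <- asplit(regions, 1L)
  pairs <- lapply(regions, function(r) {
    stopifnot(length(r) == 2L, r[1] <= r[2])
    g <- seq.int(r[1], r[2])
    expand.grid(y = g, x = g)
  })
  cg <- do.call(rbind, pairs)
  cg <- cg[cg$y <= cg$x & (cg$x - cg$y) <= max_diag, c("x", "y")]
  cg <- unique(cg)
  cg$diagonal <- cg$x - cg$y
  cg <- cg[order(cg$diagonal, cg$x), ]
  rownames(cg) <- NULL
  cg
}

#' Plan one offload-compute iteration under a memory budget
#'
#' Chooses the number of SNP groups T held this iteration as the
#' largest count whose projected tile storage (G^2 cumulative-sum
#' entries of 8 bytes per compute group) fits `mem_limit`, then counts
#' how many consecutive grid locations (from `start`) have their
#' maxwin windows entirely inside those T groups. Because SNP density
#' varies along the data, k varies across iterations at fixed T.
#'
#' @param grid numeric vector of grid positions (bp)
#' @param snps a [snp_matrix]
#' @param p a [scan_params]
#' @param mem_limit tile-storage budget in bytes
#' @param start index of the first grid location of this iteration
#' @param G SNP-group size
#' @return list of class `compute_plan`: `T`, `k`, `first_group`,
#'   `groups`, `compute_list`, `batches` (compute list split by
#'   diagonal, ascending), `locations` (grid indices planned),
#'   `regions` (per-location SNP-group ranges).
#' @export
plan_iteration <- function(grid, snps, p, mem_limit, start = 1L, G = 128L) {
  stopifnot(inherits(snps, "snp_matrix"), inherits(p, "scan_params"),
            start >= 1L, start <= length(grid))
  groups <- build_snp_groups(n_snps(snps), G)
  pos <- snps$positions
  win_range <- function(g) {
    idx <- which(pos >= g - p$maxwin & pos <= g + p$maxwin)
    if (!length(idx)) return(NULL)
    c(min(idx), max(idx))
  }
  group_of <- function(i) ((i - 1L) %/% G) + 1L
  tile_bytes <- function(regions) {
    if (!length(regions)) return(0)
    cl <- build_compute_list(regions, max_diag = max_diag(regions))
    nrow(cl) * G^2 * 8
  }
  max_diag <- function(regions) {
    max(vapply(regions, function(r) r[2] - r[1], numeric(1)))
  }
  # the first location's window must fit by itself
  w1 <- win_range(grid[start])
  if (is.null(w1)) {
    # no SNPs in range: the location is trivially computable alone
    reg1 <- list()
  } else {
    reg1 <- list(c(group_of(w1[1]), group_of(w1[2])))
  }
  need1 <- tile_bytes(reg1)
  if (need1 > mem_limit) {
    stop("mem_limit too small: a single window needs ", need1,
         " bytes of tile storage")
  }
  first_group <- if (length(reg1)) reg1[[1]][1] else 1L
  k <- 1L
  regions <- reg1
  repeat {
    nxt <- start + k
    if (nxt > length(grid)) break
    w <- win_range(grid[nxt])
    cand <- regions
    if (!is.null(w)) cand <- c(cand, list(c(group_of(w[1]), group_of(w[2]))))
    Tcand <- if (length(cand)) {
      max(vapply(cand, `[`, numeric(1), 2)) - first_group + 1L
    } else 1L
    if (tile_bytes(cand) > mem_limit) break
    regions <- cand
    k <- k + 1L
  }
  Tn <- if (length(regions)) {
    max(vapply(regions, `[`, numeric(1), 2)) - first_group + 1L
  } else 1L
  cl <- if (length(regions)) {
    build_compute_list(regions, max_diag = max_diag(regions))
  } else {
    data.frame(x = integer(0), y = integer(0), diagonal = integer(0))
  }
  batches <- if (nrow(cl)) split(cl, cl$diagonal) else list()
  structure(list(T = as.integer(Tn), k = k, first_group = first_group,
                 groups = groups, compute_list = cl, batches = batches,
                 locations = seq.int(start, start + k - 1L),
                 regions = regions, G = as.integer(G)),
            class = "compute_plan")
}

#' @export
print.compute_plan <- function(x, ...) {
  cat(sprintf("compute_plan: T = %d SNP groups (G = %d), k = %d locations, %d compute groups in %d diagonal batches\n",
              x$T, x$G, x$k, nrow(x$compute_list), length(x$batches)))
  invisible(x)
}

#' Balance grid locations into omega queues
#'
#' Longest-processing-time greedy assignment: locations sorted by SNP
#' count descending, each placed into the currently lightest queue, so
#' all queues end up with approximately the same number of SNPs.
#'
#' @param snp_counts per-location SNP counts
#' @param n_queues number of queues (workers)
#' @return list of integer vectors of location indices, one per queue.
#' @export
balance_omega_queues <- function(snp_counts, n_queues = 1L) {
  stopifnot(n_queues >= 1L)
  queues <- rep(list(integer(0)), n_queues)
  loads <- numeric(n_queues)
  for (i in order(snp_counts, decreasing = TRUE)) {
    q <- which.min(loads)
    queues[[q]] <- c(queues[[q]], i)
    loads[q] <- loads[q] + snp_counts[i]
  }
  queues
}

#' Execute a compute plan
#'
#' Computes the r2 tiles of the compute list diagonal by diagonal
#' (optionally in parallel within a diagonal), assembles each planned
#' location's window table from the shared tile store, and evaluates
#' omega with the same window semantics as [scan_location()]. Results
#' are identical to the plain scan on the same locations regardless of
#' worker count or batch schedule.
#'
#' @param plan a `compute_plan` from [plan_iteration()]
#' @param snps the [snp_matrix] the plan was built for
#' @param p the [scan_params]
#' @param grid the grid positions the plan was built for
#' @param workers worker count for within-diagonal tile computation
#'   (uses `parallel::mclapply` when > 1)
#' @return list of `omega_result`, one per planned location.
#' @export
execute_plan <- function(plan, snps, p, grid, workers = 1L) {
  stopifnot(inherits(plan, "compute_plan"))
  G <- plan$G
  groups <- plan$groups
  S <- n_snps(snps)
  tiles <- new.env(parent = emptyenv())
  tile_key <- function(x, y) paste0(x, ".", y)
  compute_tile <- function(x, y) {
    xi <- seq.int(groups$first[x], groups$last[x])
    yi <- seq.int(groups$first[y], groups$last[y])
    idx <- sort(unique(c(xi, yi)))
    sub <- ld_r2_matrix(snp_subset(snps, idx), kernel = snps$alphabet)
    list(xi = xi, yi = yi,
         r2 = sub[match(xi, idx), match(yi, idx), drop = FALSE])
  }
  for (batch in plan$batches) {
    keys <- mapply(tile_key, batch$x, batch$y)
    vals <- if (workers > 1L &&
                requireNamespace("parallel", quietly = TRUE)) {
      parallel::mclapply(seq_len(nrow(batch)), function(i) {
        compute_tile(batch$x[i], batch$y[i])
      }, mc.cores = workers)
    } else {
      lapply(seq_len(nrow(batch)), function(i) {
        compute_tile(batch$x[i], batch$y[i])
      })
    }
    for (i in seq_along(keys)) assign(keys[i], vals[[i]], envir = tiles)
  }
  lapply(seq_along(plan$locations), function(li) {
    gi <- plan$locations[li]
    pos <- grid[gi]
    idx <- which(snps$positions >= pos - p$maxwin &
                   snps$positions <= pos + p$maxwin)
    if (length(idx) < 4L) return(scan_location(snps, pos, p))
    f <- min(idx); t <- max(idx)
    W <- t - f + 1L
    r2 <- matrix(0, W, W)
    gset <- seq.int(((f - 1L) %/% G) + 1L, ((t - 1L) %/% G) + 1L)
    for (x in gset) for (y in gset[gset <= x]) {
      key <- tile_key(x, y)
      if (!exists(key, envir = tiles, inherits = FALSE)) next
      tl <- get(key, envir = tiles, inherits = FALSE)
      ri <- tl$xi[tl$xi >= f & tl$xi <= t]
      ci <- tl$yi[tl$yi >= f & tl$yi <= t]
      if (!length(ri) || !length(ci)) next
      blk <- tl$r2[match(ri, tl$xi), match(ci, tl$yi), drop = FALSE]
      r2[ri - f + 1L, ci - f + 1L] <- blk
      r2[ci - f + 1L, ri - f + 1L] <- t(blk)
    }
    win <- snp_subset(snps, f:t)
    M <- build_ld_sums(win, 1L, W, kernel = snps$alphabet, r2 = r2)
    # the window table is bitwise the corresponding block of the global
    # table, so this reproduces the plain scan exactly
    scan_location(win, pos, p, reuse = M)
  })
}
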