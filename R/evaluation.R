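#' Sliding window grid
#'
#' Overlapping windows of fixed length at a fixed offset: starts at 0,
#' `offset`, `2*offset`, ... while `start + window <= region_length`
#' (only full windows are used).
#'
#' @param region_length region length in bp
#' @param window window length in bp (default 10,000)
#' @param offset distance between consecutive window starts (default 1,000)
#' @return list of class `window_grid`: `region_length`, `window`,
#'   `offset`, `starts`, `ends` (half-open intervals), `centers`.
#' @export
sliding_windows <- function(region_length, window = 10000, offset = 1000) {
  stopifnot(offset >= 1, window > 0)
  if (window > region_length) stop("window longer than the region")
  starts <- seq(0, region_length - window, by = offset)
  structure(list(region_length = region_length, window = window,
                 offset = offset, starts = starts, ends = starts + window,
                 centers = starts + window / 2),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of %g bp at %g bp offset over %g bp\n",
              length(x$starts), x$window, x$offset, x$region_length))
  invisible(x)
}

#' Registered window statistics
#' @noRd
window_stat_registry <- function() {
  c("theta_pi", "theta_w", "theta_h", "tajimas_d", "fu_li_dstar",
    "fu_li_fstar", "fay_wu_h_norm", "dv_k", "dv_h", "hudsons_c", "omega")
}

#' Per-window scores of a statistic
#'
#' Evaluates one registered statistic in every window of the grid.
#' Windows with too few complete SNP columns for the statistic yield
#' `NaN`. SFS-based statistics are vectorized over windows through
#' cumulative sums; `"omega"` delegates to [scan_location()] at each
#' window center.
#'
#' @param snps a binary [snp_matrix]
#' @param grid a [sliding_windows] grid
#' @param statistic one of `r paste(window_stat_registry(), collapse=", ")`
#' @param p a [scan_params], used only by `"omega"`
#' @return numeric vector, one score per window.
#' @export
window_scores <- function(snps, grid, statistic,
                          p = scan_params(minwin = 2500, maxwin = 25000)) {
  stopifnot(inherits(snps, "snp_matrix"), inherits(grid, "window_grid"))
  if (!statistic %in% window_stat_registry()) {
    stop("unknown statistic: ", statistic)
  }
  nw <- length(grid$starts)
  if (statistic == "omega") {
    shared <- if (n_snps(snps) >= 2L) {
      build_ld_sums(snps, 1L, n_snps(snps), kernel = snps$alphabet)
    } else NULL
    return(vapply(grid$centers, function(g) {
      scan_location(snps, g, p, reuse = shared)$omega_max
    }, numeric(1)))
  }
  n <- n_samples(snps)
  pos <- snps$positions
  complete <- colSums(is.na(snps$geno)) == 0L
  cols <- which(complete)
  dpos <- pos[cols]
  # window membership: half-open [start, end)
  lo <- findInterval(grid$starts, dpos, left.open = TRUE) + 1L
  hi <- findInterval(grid$ends - 1e-9, dpos)
  if (statistic %in% c("dv_k", "dv_h")) {
    return(vapply(seq_len(nw), function(w) {
      if (hi[w] < lo[w]) return(if (statistic == "dv_k") 1 else 0)
      kh <- dv_k_h(snps, cols[lo[w]:hi[w]])
      if (statistic == "dv_k") kh$K else kh$H
    }, numeric(1)))
  }
  if (statistic == "hudsons_c") {
    return(vapply(seq_len(nw), function(w) {
      if (hi[w] - lo[w] + 1L < 2L) return(NaN)
      suppressWarnings(hudsons_c(snps, cols[lo[w]:hi[w]]))
    }, numeric(1)))
  }
  dc <- colSums(snps$geno[, cols, drop = FALSE])
  sfs_fun <- switch(statistic,
    theta_pi = theta_pi, theta_w = theta_w, theta_h = theta_h,
    tajimas_d = tajimas_d, fu_li_dstar = fu_li_dstar,
    fu_li_fstar = fu_li_fstar, fay_wu_h_norm = fay_wu_h_norm)
  needs_s <- statistic %in% c("tajimas_d", "fu_li_dstar", "fu_li_fstar",
                              "fay_wu_h_norm")
  vapply(seq_len(nw), function(w) {
    if (hi[w] < lo[w]) {
      return(if (needs_s) NaN else 0)
    }
    counts <- tabulate(dc[lo[w]:hi[w]], nbins = n - 1L)
    spec <- sfs_from_counts(n, counts)
    if (needs_s && spec$S < 1) return(NaN)
    suppressWarnings(sfs_fun(spec))
  }, numeric(1))
}

#' Detection threshold from per-replicate extrema
#'
#' The parametric-bootstrap threshold logic: for each neutral replicate
#' take the extreme window score (minimum for statistics depressed by a
#' sweep, maximum for omega), then take a nearest-rank percentile of
#' those extrema — the 5th percentile of minima, or the 95th percentile
#' of maxima. Only one extremum per replicate enters, so the number of
#' windows poses no multiple-testing problem.
#'
#' @param neutral_scores list of per-replicate score vectors
#' @param tail `"low"` (threshold under minima) or `"high"` (maxima)
#' @param quantile percentile as a fraction (default 0.05 for `"low"`,
#'   0.95 for `"high"`)
#' @return the threshold (scalar).
#' @export
detection_threshold <- function(neutral_scores, tail = c("low", "high"),
                                quantile = NULL) {
  tail <- match.arg(tail)
  if (is.null(quantile)) quantile <- if (tail == "low") 0.05 else 0.95
  ext <- vapply(neutral_scores, function(s) {
    s <- s[is.finite(s)]
    if (!length(s)) return(NA_real_)
    if (tail == "low") min(s) else max(s)
  }, numeric(1))
  if (anyNA(ext)) {
    warning(sum(is.na(ext)), " all-NaN replicate(s) excluded")
    ext <- ext[!is.na(ext)]
  }
  if (length(ext) < 20L) warning("fewer than 20 replicates for threshold")
  nearest_rank(if (tail == "low") ext else ext, quantile)
}

#' Nearest-rank percentile: the ceil(q n)-th order statistic
#' @noRd
nearest_rank <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q * length(x)))]
}

#' Empirical whole-scan threshold
#'
#' When neutral simulations are impractical, the threshold can be taken
#' from the scan itself under the assumption that the vast majority of
#' the data is neutral: the nearest-rank `quantile` of all grid omega
#' values.
#'
#' @param report an `omega_scan`
#' @param quantile fraction (default 0.95)
#' @return the threshold.
#' @export
empirical_threshold <- function(report, quantile = 0.95) {
  stopifnot(inherits(report, "omega_scan"))
  if (!nrow(report$report)) stop("empty omega report")
  nearest_rank(report$report$omega, quantile)
}

#' Sensitivity and detection distance for one statistic
#'
#' Sensitivity is the fraction of selection replicates whose extreme
#' window score is beyond the threshold (strictly below for
#' `tail = "low"`, strictly above for `"high"`); the distance is the
#' absolute distance between the most extreme window's center and the
#' true target, averaged over the detected replicates only.
#'
#' @param selection_scores list of per-replicate score vectors from
#'   simulations with selection
#' @param threshold threshold from [detection_threshold()]
#' @param tail `"low"` or `"high"` (must match the statistic's sweep
#'   direction)
#' @param true_target true sweep position (bp)
#' @param centers window centers (bp) aligned with the score vectors
#' @param statistic label carried through to the output
#' @return list of class `detection_outcome`: `statistic`, `threshold`,
#'   `sensitivity`, `mean_distance` (NaN when nothing is detected),
#'   `n_detected`, `n_replicates`.
#' @export
sensitivity_specificity <- function(selection_scores, threshold,
                                    tail = c("low", "high"), true_target,
                                    centers, statistic = "statistic") {
  tail <- match.arg(tail)
  per_rep <- vapply(selection_scores, function(s) {
    ok <- is.finite(s)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    i <- if (tail == "low") which.min(replace(s, !ok, Inf))
         else which.max(replace(s, !ok, -Inf))
    c(s[i], centers[i])
  }, numeric(2))
  ext <- per_rep[1L, ]
  where <- per_rep[2L, ]
  detected <- if (tail == "low") ext < threshold else ext > threshold
  detected[is.na(detected)] <- FALSE
  sens <- mean(detected)
  dist <- if (any(detected)) mean(abs(where[detected] - true_target)) else NaN
  structure(list(statistic = statistic, threshold = threshold,
                 sensitivity = sens, mean_distance = dist,
                 n_detected = sum(detected),
                 n_replicates = length(selection_scores)),
            class = "detection_outcome")
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf("%s: sensitivity %.1f%% (%d/%d), mean distance %s\n",
              x$statistic, 100 * x$sensitivity, x$n_detected,
              x$n_replicates,
              if (is.nan(x$mean_distance)) "NA"
              else sprintf("%.1f bp", x$mean_distance)))
  invisible(x)
}

#' Whole-scan omega extrema and argmax positions for replicates
#'
#' Convenience driver for the power study: scans each replicate and
#' returns its maximum omega and the grid position attaining it.
#'
#' @param reps list of [snp_matrix] replicates
#' @param p a [scan_params]
#' @return data.frame with columns `max_omega`, `argmax_pos`.
#' @export
scan_maxima <- function(reps, p) {
  rows <- lapply(reps, function(r) {
    sc <- omega_scan(r, p)
    if (!nrow(sc$report)) return(c(NA_real_, NA_real_))
    i <- which.max(sc$report$omega)
    c(sc$report$omega[i], sc$report$position[i])
  })
  out <- do.call(rbind, rows)
  data.frame(max_omega = out[, 1L], argmax_pos = out[, 2L])
}

#' Scaled-down sensitivity/specificity study
#'
#' Reproduces the evaluation methodology end to end for one demographic
#' model: neutral and sweep replicates are simulated under identical
#' conditions, the omega threshold is the 95th percentile of neutral
#' per-replicate maxima, summary-statistic thresholds are 5th
#' percentiles of neutral per-replicate window minima, and sensitivity
#' and mean detection distance are measured against the true sweep
#' target at the region center.
#'
#' @param demography preset name (e.g. `"bottleneck2"`)
#' @param n_neutral,n_sweep replicate counts
#' @param sim a [sim_params] template (its demography/sweep are set here)
#' @param p a [scan_params] for the omega scan
#' @param statistics summary statistics to evaluate over sliding windows
#'   (in addition to omega), or `character(0)`
#' @param window,offset sliding-window geometry in bp
#' @param seed integer seed
#' @param progress print progress to stderr
#' @return list with `omega` (a `detection_outcome` with distances) and
#'   one `detection_outcome` per summary statistic.
#' @export
power_study <- function(demography, n_neutral = 200L, n_sweep = 200L,
                        sim = sim_params(), p = scan_params(
                          grid_size = 250L, minwin = 10000,
                          maxwin = 100000, minsnps = 5L),
                        statistics = c("theta_pi", "dv_h"),
                        window = 10000, offset = 1000, seed = 1L,
                        progress = FALSE) {
  base <- sim
  base$demography <- if (is.character(demography)) {
    demography_preset(demography)
  } else demography
  neutral_par <- base
  neutral_par$sweep <- NULL
  sweep_par <- base
  if (is.null(sweep_par$sweep)) {
    sweep_par$sweep <- list(position_fraction = 0.5, alpha = 1000,
                            fixation_time_backwards = 0)
  }
  true_target <- sweep_par$sweep$position_fraction * base$region_length

  set.seed(seed)
  note <- function(...) if (progress) message(...)
  note("simulating ", n_neutral, " neutral replicates")
  neutral <- simulate_neutral(neutral_par, n_neutral)
  note("simulating ", n_sweep, " sweep replicates")
  swept <- simulate_sweep(sweep_par, n_sweep)

  note("omega scans")
  mx_neutral <- scan_maxima(neutral, p)
  mx_sweep <- scan_maxima(swept, p)
  thr_omega <- nearest_rank(mx_neutral$max_omega[!is.na(mx_neutral$max_omega)],
                            0.95)
  det <- !is.na(mx_sweep$max_omega) & mx_sweep$max_omega > thr_omega
  omega_out <- structure(list(
    statistic = "omega", threshold = thr_omega,
    sensitivity = mean(det),
    mean_distance = if (any(det)) {
      mean(abs(mx_sweep$argmax_pos[det] - true_target))
    } else NaN,
    n_detected = sum(det), n_replicates = n_sweep),
    class = "detection_outcome")

  out <- list(omega = omega_out)
  if (length(statistics)) {
    grid <- sliding_windows(base$region_length, window, offset)
    for (st in statistics) {
      note("windowed ", st)
      ns <- lapply(neutral, window_scores, grid = grid, statistic = st)
      ss <- lapply(swept, window_scores, grid = grid, statistic = st)
      thr <- detection_threshold(ns, tail = "low")
      out[[st]] <- sensitivity_specificity(ss, thr, tail = "low",
                                           true_target, grid$centers,
                                           statistic = st)
    }
  }
  out
}
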