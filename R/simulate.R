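#' Demography presets
#'
#' Piecewise-constant population-size histories used throughout:
#' `constant`, and seven bottleneck scenarios. Each bottleneck is given
#' by its beginning (most recent change) and end, in units of 4N
#' generations measured backwards from sampling, the relative size
#' during the bottleneck, and the relative size before it (further in
#' the past).
#'
#' @param name one of `"constant"`, `"bottleneck1"` .. `"bottleneck7"`
#' @return data.frame with columns `start` (backwards time, 4N units at
#'   which the epoch begins) and `size` (relative size in that epoch).
#' @export
demography_preset <- function(name) {
  presets <- list(
    constant    = c(NA, NA, NA, NA),
    bottleneck1 = c(0.100, 0.1004, 0.5, 1.0),
    bottleneck2 = c(0.015, 0.0160, 0.5, 1.0),
    bottleneck3 = c(0.015, 0.0170, 0.01, 1.0),
    bottleneck4 = c(0.015, 0.0160, 0.005, 1.0),
    bottleneck5 = c(0.015, 0.0170, 0.1, 1.0),
    bottleneck6 = c(0.010, 0.0104, 0.5, 1.0),
    bottleneck7 = c(0.010, 0.0104, 0.1, 1.0)
  )
  if (!name %in% names(presets)) {
    stop("unknown demography: ", name, " (use constant or bottleneck1..7)")
  }
  p <- presets[[name]]
  if (name == "constant") {
    return(data.frame(start = 0, size = 1))
  }
  data.frame(start = c(0, p[1], p[2]), size = c(1, p[3], p[4]))
}

#' Simulation parameters
#'
#' Conditions for the rescaled Wright-Fisher simulator. Rates follow
#' the coalescent convention: `theta_total = 4 N mu` and
#' `rho_total = 4 N c` for the whole region, so per chromosome per
#' generation the mutation rate is `theta_total / (4 pop_size)` and the
#' crossover rate `rho_total / (4 pop_size)`.
#'
#' @param n_samples haplotypes drawn at the end (default 50)
#' @param pop_size diploid population size N of the rescaled forward
#'   model (default 500, i.e. 1000 chromosomes)
#' @param region_length region length in bp (default 1e6)
#' @param theta_total region-wide scaled mutation rate 4 N mu L
#' @param rho_total region-wide scaled recombination rate 4 N c L
#' @param demography preset name (see [demography_preset()]) or a
#'   data.frame of epochs `(start, size)` with `start` in 4N units
#'   backwards, increasing, `size > 0`
#' @param sweep `NULL`, or a list with `position_fraction` (location of
#'   the beneficial allele on \[0,1\]), `alpha` (2 N s > 0), and
#'   optionally `fixation_time_backwards` (4N units; default 0 =
#'   sampling at fixation)
#' @param burn_factor burn-in length in units of `pop_size` generations
#'   before the oldest epoch boundary (default 10)
#' @return list of class `sim_params`
#' @export
sim_params <- function(n_samples = 50L, pop_size = 500L,
                       region_length = 1e6, theta_total = 1000,
                       rho_total = 1000, demography = "constant",
                       sweep = NULL, burn_factor = 10) {
  if (is.character(demography)) demography <- demography_preset(demography)
  stopifnot(is.data.frame(demography), all(c("start", "size") %in% names(demography)),
            all(demography$size > 0), !is.unsorted(demography$start),
            demography$start[1] == 0,
            n_samples >= 2L, pop_size >= 2L, region_length > 0,
            theta_total >= 0, rho_total >= 0, burn_factor > 0)
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), !is.null(sweep$position_fraction),
              !is.null(sweep$alpha), sweep$alpha > 0,
              sweep$position_fraction >= 0, sweep$position_fraction <= 1)
    if (is.null(sweep$fixation_time_backwards)) sweep$fixation_time_backwards <- 0
    stopifnot(sweep$fixation_time_backwards >= 0)
  }
  structure(list(n_samples = as.integer(n_samples),
                 pop_size = as.integer(pop_size),
                 region_length = region_length, theta_total = theta_total,
                 rho_total = rho_total, demography = demography,
                 sweep = sweep, burn_factor = burn_factor),
            class = "sim_params")
}

#' Per-generation chromosome counts, backwards from sampling
#' @noRd
backward_sizes <- function(p) {
  four_n <- 4 * p$pop_size
  oldest <- ceiling(max(p$demography$start) * four_n)
  total <- oldest + ceiling(p$burn_factor * p$pop_size)
  b <- seq_len(total)                      # backwards generation index
  epoch <- findInterval((b - 0.5) / four_n, p$demography$start)
  as.integer(pmax(2, round(2 * p$pop_size * p$demography$size[epoch])))
}

#' Sample a conditioned sweep trajectory
#'
#' Simulates the carrier count of a beneficial allele forward in time
#' under Wright-Fisher binomial sampling with selection coefficient
#' `s = alpha / (2 pop_size)` per generation and the epoch-dependent
#' population size, starting from a single copy and conditioned on
#' fixation (paths that lose the allele are rejected and resampled).
#' The epoch clock is anchored so that fixation coincides with the
#' sweep's `fixation_time_backwards` (default: the sampling
#' generation); the anchor is refined iteratively since the sojourn
#' time is itself random.
#'
#' @param p a [sim_params] with a sweep
#' @param max_tries resampling cap (error beyond it)
#' @return list of class `sweep_trajectory`: `freq` (forward-in-time
#'   frequencies from 1/(2N) to 1), `counts` (carrier counts), `L`
#'   (sojourn in generations).
#' @export
sample_trajectory <- function(p, max_tries = 10000L) {
  stopifnot(inherits(p, "sim_params"), !is.null(p$sweep))
  sizes <- backward_sizes(p)               # chromosomes, index = gens back
  s <- p$sweep$alpha / (2 * p$pop_size)
  ftb <- if (is.null(p$sweep$fixation_time_backwards)) 0 else
    p$sweep$fixation_time_backwards
  fix_back <- round(ftb * 4 * p$pop_size)
  draw <- function(anchor) {
    # forward step g lives at backwards generation anchor - g
    k <- 1L
    counts <- k
    M_at <- function(bk) {
      if (bk < 1) sizes[1L] else if (bk > length(sizes)) sizes[length(sizes)]
      else sizes[bk]
    }
    for (g in seq_len(length(sizes))) {
      M_now <- M_at(anchor - g + 1L)
      M_next <- M_at(anchor - g)
      x <- k / M_now
      xp <- x * (1 + s) / (1 + x * s)
      k <- stats::rbinom(1L, M_next, xp)
      counts <- c(counts, k)
      if (k == 0L) return(NULL)
      if (k == M_next) return(counts)
    }
    NULL
  }
  anchor <- min(length(sizes), fix_back + ceiling(4 * log(2 * p$pop_size) /
                                                   max(s, 1e-3)))
  tries <- 0L
  repeat {
    tries <- tries + 1L
    if (tries > max_tries) stop("trajectory conditioning failed after ",
                                max_tries, " attempts")
    counts <- draw(anchor)
    if (is.null(counts)) next
    L <- length(counts) - 1L
    if (abs(L + fix_back - anchor) <= 2L || tries > max_tries / 2L) {
      structure(list(freq = counts / vapply(seq_along(counts) - 1L,
                       function(g) {
                         bk <- anchor - g
                         if (bk < 1) sizes[1L]
                         else if (bk > length(sizes)) sizes[length(sizes)]
                         else sizes[bk]
                       }, numeric(1)),
                     counts = counts, L = L),
                class = "sweep_trajectory") -> out
      return(out)
    }
    anchor <- min(length(sizes), L + fix_back)   # refine and retry
  }
}

#' One replicate from the lineage-wise WF engine
#' @noRd
wf_replicate <- function(p, carriers) {
  sizes <- backward_sizes(p)
  u <- p$theta_total / (4 * p$pop_size)
  r <- p$rho_total / (4 * p$pop_size)
  sel_pos <- if (is.null(p$sweep)) 0.5 else p$sweep$position_fraction
  out <- .wf_ancestry_sim(p$n_samples, sizes, u, r, sel_pos, carriers)
  pos <- out$positions * p$region_length
  geno <- out$geno
  if (length(pos) == 0L) {
    return(snp_matrix(matrix(integer(0), p$n_samples, 0), numeric(0), "binary"))
  }
  while (any(dup <- duplicated(pos))) {    # measure-zero, but be safe
    pos[dup] <- pos[dup] + 1e-6 * p$region_length
    o <- order(pos)
    pos <- pos[o]
    geno <- geno[, o, drop = FALSE]
  }
  snp_matrix(geno, pos, "binary")
}

#' Simulate neutral replicates
#'
#' Draws samples of `p$n_samples` haplotypes from the rescaled
#' Wright-Fisher model at mutation-drift equilibrium (clonal founding
#' `burn_factor * pop_size` generations before the oldest epoch, then
#' the demography of `p`). Positions are infinite-sites uniform,
#' scaled to `region_length`.
#'
#' @param p a [sim_params]
#' @param reps number of replicates
#' @param seed integer seed (controls all randomness)
#' @return list of binary [snp_matrix] objects.
#' @export
simulate_neutral <- function(p, reps = 1L, seed = NULL) {
  stopifnot(inherits(p, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  sizes <- backward_sizes(p)
  zero <- integer(length(sizes))
  lapply(seq_len(reps), function(i) wf_replicate(p, zero))
}

#' Simulate replicates with a conditioned selective sweep
#'
#' Each replicate draws its own fixation-conditioned trajectory
#' ([sample_trajectory()]) and evolves the linked neutral variation
#' under the same Wright-Fisher dynamics with the per-generation
#' carrier counts forced to the trajectory, i.e. parents are drawn
#' within allelic classes. Sampling occurs at fixation (or
#' `fixation_time_backwards` after it); the beneficial site itself is
#' fixed and therefore absent from the output SNPs.
#'
#' @inheritParams simulate_neutral
#' @return list of binary [snp_matrix] objects.
#' @export
simulate_sweep <- function(p, reps = 1L, seed = NULL) {
  stopifnot(inherits(p, "sim_params"), !is.null(p$sweep))
  if (!is.null(seed)) set.seed(seed)
  sizes <- backward_sizes(p)
  ftb <- if (is.null(p$sweep$fixation_time_backwards)) 0 else
    p$sweep$fixation_time_backwards
  fix_back <- round(ftb * 4 * p$pop_size)
  lapply(seq_len(reps), function(i) {
    traj <- sample_trajectory(p)
    carriers <- integer(length(sizes))
    # backwards step b: parental generation b generations before sampling
    if (fix_back > 0) carriers[seq_len(min(fix_back, length(carriers)))] <-
      sizes[seq_len(min(fix_back, length(carriers)))]
    for (b in seq_len(traj$L)) {
      idx <- fix_back + b
      if (idx <= length(carriers)) {
        carriers[idx] <- min(traj$counts[traj$L - b + 1L], sizes[idx])
      }
    }
    wf_replicate(p, carriers)
  })
}
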