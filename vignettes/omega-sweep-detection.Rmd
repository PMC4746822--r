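---
title: "Detecting selective sweeps from linkage-disequilibrium patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps from linkage-disequilibrium patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegascan)
```

## The signal and the statistic

When a beneficial mutation fixes in a population it drags linked neutral
variants with it (genetic hitchhiking). Recombination lets the two
flanks of the swept site escape on partly independent haplotype
backgrounds, which leaves a characteristic footprint in linkage
disequilibrium: allelic association (measured here by the squared
correlation coefficient $r^2$) is *elevated among SNPs on the same side*
of the fixed site and *depressed between SNPs on opposite sides*.

For a window of $W$ SNPs split into a left part $L$ of $l$ SNPs and a
right part $R$ of $W-l$ SNPs, the omega statistic contrasts the average
within-flank LD with the average cross-flank LD:

$$
\omega \;=\;
\frac{\left[\binom{l}{2} + \binom{W-l}{2}\right]^{-1}
      \left(\sum_{i,j \in L} r^2_{ij} + \sum_{i,j \in R} r^2_{ij}\right)}
     {\left[l\,(W-l)\right]^{-1} \sum_{i \in L,\, j \in R} r^2_{ij}} .
$$

Under homogeneous LD the two averages cancel and $\omega \approx 1$; at
the centre of a completed sweep $\omega$ becomes large. Neutral data
under equilibrium rarely produce large $\omega$, while bottlenecked
demographies can, which is why detection thresholds are calibrated by
simulation under an explicit demographic null (below).

### $r^2$ for binary and DNA data

For binary (infinite-sites, 0 = ancestral / 1 = derived) data, $r^2$ is
the squared correlation of the derived-state indicators,
$r^2 = (p_{11} - p_1 p_2)^2 / [p_1(1-p_1)\,p_2(1-p_2)]$, always in
$[0,1]$. For DNA data each SNP can carry up to four states; the kernel
sums the per-state-pair terms over state pairs segregating at both
members and scales by $(v_i-1)(v_j-1)v_{ij}/(v_i v_j)$, where $v_i$,
$v_j$ count the states present at each SNP. The weight $v_{ij}$ — "the
number of valid pairs of states" — is ambiguous in the literature; we
define it as the *fraction* of samples valid (non-gap, non-N) at both
SNPs. Two properties motivated this choice: the weight is 1 on gap-free
data, and the DNA kernel then collapses *exactly* to the binary kernel
for gap-free biallelic sites (the four state-pair terms contribute
$4r^2$, cancelled by the $1/4$ prefactor). Any reading of $v_{ij}$ as an
absolute count makes $r^2$ unbounded in the sample size. Frequencies
always use the jointly-valid sample count as denominator; a SNP
monomorphic over that intersection contributes $r^2 = 0$ rather than an
error, so scans proceed over masked data.

### The cumulative LD-sum table

Evaluating $\omega$ for every candidate split and border would repeat
the same pair sums many times. The package instead fills a triangular
dynamic-programming table $M$ with
$M_{i,j} = \sum_{j \le a < b \le i} r^2_{ab}$ via the recurrence
$M_{i,j} = M_{i,j+1} + M_{i-1,j} - M_{i-1,j+1} + r^2_{ij}$ (implemented
row-wise in its algebraically identical unrolled form
$M_{i,j} = M_{i-1,j} + \sum_{t=j}^{i-1} r^2_{it}$). All three sums in
$\omega$ are then table lookups. Because an entry only involves pairs
inside $j..i$, the table of any sub-window is literally a sub-block of
the table of a larger window — that single observation supplies the
data-reuse optimization: one table serves every overlapping window of a
scan, and the workplan executor's per-window tables are bitwise equal to
blocks of the scan's table.

## Window semantics of a scan

`omega_scan()` lays a grid of `grid_size` equidistant locations over the
polymorphic span (first to last SNP position; outside that span $\omega$
is undefined, a documented divergence from tools that may grid the full
region). At each location:

* every SNP strictly closer than `minwin` is always included (the
  mandatory core; the bound is open, matching "distance < minwin");
* candidate borders extend the core one SNP at a time out to `maxwin`
  (inclusive) on each side;
* a border pair is admissible when both sides hold at least 2 SNPs
  (the binomial coefficients in $\omega$ require it), the total is at
  least `minsnps`, and — when the balance parameter is set — the side
  difference $|l - (W-l)|$ does not exceed it;
* the maximum $\omega$ over all admissible pairs is reported, with ties
  broken toward the smallest window and then the leftmost left border,
  so results are deterministic across platforms.

A perfect sweep pattern has a cross-flank sum of exactly zero, where the
ratio is undefined; the cross sum is floored at $\varepsilon = 10^{-9}$,
which keeps $\omega$ finite and leaves the ranking of candidate splits
unchanged. `minwin`/`minsnps` matter most in practice: very small values
let stochastically high LD in tiny windows dominate even under
neutrality. The defaults used in the study below (10 kb, 5) are typical
choices for human-scale data; `maxwin` hardly matters once it is large
(we use 100 kb).

Complete binary data take a compiled fast path (SNPs packed into 64-bit
words, joint counts by population counts, banded table). The plain-R
path and the compiled path are verified bitwise-identical in the test
suite; DNA or masked data always use the reference path.

## Work partitioning (offload–compute planning)

For memory-bounded runs the scan can be organised into *SNP groups* of
`G` SNPs (128 in production; tests use 2–4 to exercise the logic) and
*compute groups* — tiles formed by a pair of SNP groups, deduplicated
across overlapping windows and capped at the diagonal distance implied
by `maxwin`. `plan_iteration()` chooses the largest number of groups
`T` whose projected tile storage ($G^2$ eight-byte entries per tile,
summed over the deduplicated compute list) fits a user budget, and
counts how many consecutive grid locations `k` are fully covered; `k`
varies with local SNP density at fixed `T`. The exact budget formula of
the original C implementation is unpublished, so the tile-entry
accounting above is this package's documented convention. Tiles are
processed by ascending diagonal — a tile depends only on the previous
diagonal, mirroring the table recurrence — optionally in parallel within
a diagonal; the contract, enforced by tests, is that the executed plan
equals the plain sequential scan bit for bit at any worker count.
`balance_omega_queues()` distributes locations to per-worker queues by
total SNP count with the longest-processing-time greedy rule.

## The synthetic-data generator

The generator is a *rescaled discrete Wright–Fisher model*: a
population of $2N$ chromosomes (default $N = 500$ diploids) with
per-generation random mating, Poisson crossovers at rate
$\rho/(4N)$ per meiosis (uniform breakpoints), infinite-sites Poisson
mutation at rate $\theta/(4N)$ per chromosome per generation (fresh
uniform positions on $[0,1]$, scaled to `region_length`), and
piecewise-constant population size. Epoch times are given backwards
from sampling in units of $4N$ generations; the bottleneck presets
(`bottleneck1` … `bottleneck7`) place a short size reduction (relative
sizes 0.5 down to 0.005) at 0.010–0.100 before the present. Populations
are founded clonally `burn_factor * N` generations (default 10N) before
the oldest epoch boundary, long enough that residual non-coalesced
ancestry is negligible (below 1% per lineage pair at the defaults).

Rather than storing every genome in every generation, the sampled
haplotypes are produced by tracing the sample's ancestral material
backwards through the same per-generation parent, crossover, and
mutation draws. This is an exact, generation-by-generation evaluation
of the identical discrete process — no diffusion or continuous-time
approximation enters — and it makes the cost proportional to the
ancestral recombination structure rather than to population size times
generations times mutations per genome. Only crossovers inside the span
of a lineage's ancestral material (plus the selected site while a sweep
is ongoing) can affect the sample, so the crossover Poisson is thinned
accordingly; material carried by all samples is pruned as fully
coalesced.

Selective sweeps are simulated by first drawing a *fixation-conditioned
trajectory* of carrier counts: Wright–Fisher binomial sampling with
selection coefficient $s = \alpha/(2N)$ per generation under the
epoch-dependent sizes, restarted until fixation occurs, with the epoch
clock anchored so that fixation lands at the sampling generation (the
anchor is refined iteratively because the sojourn is random; residual
misalignment is a couple of generations). The linked neutral variation
then evolves with per-generation carrier counts *forced to the
trajectory*: each chromosome inherits the selected site from a parent of
its own allelic class, while crossovers let flanking material escape to
the other class. Sampling happens at fixation by default (a complete
sweep, the regime the omega statistic targets); the beneficial site
itself is fixed and therefore absent from the output SNPs.

What the generator does *not* emulate: gene conversion, variable
mutation/recombination maps, population structure and migration, and
finite-sites homoplasy. Passing tests on these simulations therefore
demonstrate correctness of the method under the idealised infinite-sites
WF model, not robustness to every feature of real data.

### Parameter defaults

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 50 | haplotypes drawn |
| `pop_size` | 500 | rescaled diploid N (1000 chromosomes) |
| `region_length` | 1 Mb | only scales positions |
| `theta_total` | 1000 | $4N\mu L$; ≈ 4500 segregating sites per Mb at n = 50 |
| `rho_total` | 1000 | $4NcL$ |
| `alpha` | 1000 | $2Ns$; a strong sweep, fixing in a few dozen rescaled generations |
| `burn_factor` | 10 | founding age in units of N generations |

The default $\theta$ targets the 3000–5000 SNPs/Mb regime typical of
the simulation studies this design follows; $\rho \approx \theta$ is a
standard humanlike choice. The rescaling ($N = 500$) preserves the
coalescent-scale quantities that drive the statistics ($\theta$,
$\rho$, $\alpha$, epoch times in $4N$ units).

## Threshold calibration and the power study

Detection follows the parametric-bootstrap logic: simulate neutral
replicates under the assumed demography, record for each replicate a
single extreme score — the maximum $\omega$ over the scan, or the
minimum of a summary statistic over sliding windows — and set the
threshold at a nearest-rank percentile of those extrema (95th of maxima
for $\omega$, 5th of minima otherwise). Because only one extremum per
replicate enters the null, the number of windows creates no
multiple-testing problem. Nearest-rank (the $\lceil qn \rceil$-th order
statistic) was chosen over interpolated quantiles for determinism. When
neutral simulation is impractical, `empirical_threshold()` instead takes
the 95th percentile of the scan's own grid values, assuming the dataset
is mostly neutral.

Sensitivity is the fraction of sweep replicates whose extreme score
passes the threshold (strictly); the localisation error is the distance
from the most extreme window's centre (for $\omega$: the argmax grid
location) to the true target, averaged over detected replicates only —
undetected replicates report no sweep region, so they contribute no
distance. Sliding windows are full windows only: 10 kb windows at 1 kb
offset over 1 Mb give 991 windows (a truncated 1000th window would
change the minimum statistics' support, so it is not used).

`power_study()` packages the whole design for one demographic model.
The study sizes used by the acceptance script are 200 neutral + 200
sweep replicates per model at $\theta = \rho = 500$, scan grid 250,
`minwin` 10 kb, `maxwin` 100 kb, `minsnps` 5; the test suite runs the
same design at 100 + 100. These sizes were chosen once as the package's
desk-scale study conditions. Under the mild `bottleneck2` the omega
scan detects essentially every sweep within a few tens of kb; under the
severe `bottleneck4` the neutral null itself produces sweep-like LD
(the 95th percentile of neutral maximum $\omega$ rises by more than an
order of magnitude), and sensitivity drops — the qualitative ordering
the method's literature reports. The absolute sensitivities under
severe bottlenecks depend on simulation details (sample size, $\theta$,
sweep age) that published studies do not always state; our generator's
committed conditions give higher severe-bottleneck sensitivity than
some published figures, and we report what the package computes.

## Numerical and edge-case conventions

* Positions are 1-based base pairs stored as reals; ms-style fractional
  positions are scaled by `region_length` and duplicate positions are
  perturbed by $10^{-6} \times$ `region_length` to keep coordinates
  strictly increasing.
* Binary deduction of DNA data maps the majority state to 0 with
  alphabetical tie-break — deterministic where the original tool's
  mapping is unspecified.
* `-` and `N` are both invalid observations; unphased heterozygotes are
  split (0,1) in sample order when reading VCF.
* Singleton removal drops sites whose minor class is exactly one
  sample; DNA sites where several minor states jointly exceed one
  sample are kept (flagged as an interpretation choice).
* S = 0 windows yield `NaN` for the normalized SFS statistics, with a
  warning; Hudson's C clamps to $[0, 10^7]$ and is a simplified moment
  inversion built on the two-locus coalescence-time correlation
  $(\rho+18)/(\rho^2+13\rho+18)$ — adequate for the ordering the
  comparisons need, not a replication of any specific historical
  implementation.

## A small worked example

```{r example, fig.width = 6, fig.height = 3.5, eval = requireNamespace("graphics", quietly = TRUE)}
sim <- sim_params(n_samples = 20, pop_size = 200, theta_total = 200,
                  rho_total = 100,
                  sweep = list(position_fraction = 0.5, alpha = 800))
rep1 <- simulate_sweep(sim, 1, seed = 7)[[1]]
rep1
p <- scan_params(grid_size = 100, minwin = 10000, maxwin = 100000,
                 minsnps = 5)
sc <- omega_scan(rep1, p)
summary(sc)
plot(sc)
```

## Known limitations

* The severe-bottleneck sensitivities are tied to this generator's
  committed conditions; they reproduce the qualitative demographic
  confounding but not every published percentage.
* The DNA kernel's $v_{ij}$ weight and the binary-deduction rule are
  documented conventions where the source material is ambiguous.
* Parallel plan execution uses forked workers where available and is
  purely an optimisation; scheduling never changes results.
* The VCF reader covers the biallelic-SNP/GT subset only.
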