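# Canonical-ensemble reweighting of aMD snapshot ensembles.
#
# Each aMD snapshot carries the boost dV it experienced; multiplying its
# statistical weight by exp(dV/kBT) recovers the unbiased (canonical)
# ensemble.  All estimators here take per-snapshot weights; uniform weights
# reproduce the conventional-MD (cMD) limit.

#' Normalized snapshot weights from a Delta-V series
#'
#' w_i proportional to exp(dV_i / kBT), computed with a max-shift (largest
#' exponent brought to 0 before exponentiation) so large boosts cannot
#' overflow; consequently the weights are invariant under adding any
#' constant to the whole series.
#'
#' @param delta_v per-snapshot boost energies, kcal/mol (finite, >= 0).
#' @param temperature K.
#' @return Numeric weights summing to 1.
#' @export
snapshot_weights <- function(delta_v, temperature = 310) {
  if (length(delta_v) == 0) stop("empty Delta-V series")
  if (any(!is.finite(delta_v))) stop("non-finite Delta-V")
  e <- delta_v / kBT(temperature)
  w <- exp(e - max(e))
  w / sum(w)
}

#' Effective sample size of a weighted ensemble
#'
#' ESS = (sum w)^2 / sum(w^2): the number of equally-weighted snapshots the
#' ensemble is statistically worth.  Reported with every reweighted
#' estimate as a reliability diagnostic.
#'
#' @param weights snapshot weights (any positive scale).
#' @return Scalar in (0, length(weights)].
#' @export
effective_sample_size <- function(weights) {
  sum(weights)^2 / sum(weights^2)
}

#' Weighted histogram over fixed bin edges
#'
#' Values outside the edge range are dropped and counted; bin masses are
#' renormalized to sum to 1 over the retained values.  Binning convention
#' is half-open [lo, hi) with the last bin closed.
#'
#' @param values observable values.
#' @param weights optional snapshot weights (default uniform).
#' @param edges strictly increasing bin boundaries.
#' @return List of class `weighted_histogram`: `masses` (sums to 1),
#'   `edges`, `mids`, `n_dropped`.
#' @export
weighted_histogram <- function(values, weights = NULL, edges) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(values) == length(weights), all(weights >= 0))
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(edges) - 1
  keep <- values >= edges[1] & values <= edges[nb + 1]
  if (sum(weights[keep]) <= 0)
    stop("no weighted mass falls inside the histogram range")
  bin <- findInterval(values[keep], edges, rightmost.closed = TRUE)
  masses <- vapply(seq_len(nb), function(b) sum(weights[keep][bin == b]),
                   numeric(1))
  masses <- masses / sum(masses)
  structure(list(masses = masses, edges = edges,
                 mids = (edges[-1] + edges[-(nb + 1)]) / 2,
                 n_dropped = sum(!keep)),
            class = "weighted_histogram")
}

#' Default bin edges from the weighted value range
#'
#' Spans the weighted 0.5-99.5 percentile range with `nbins` equal bins;
#' both the count and the percentile span are configurable and are recorded
#' in analysis metadata.
#'
#' @param values observable values.
#' @param weights optional weights.
#' @param nbins number of bins.
#' @param probs lower/upper weighted-quantile bounds.
#' @export
default_edges <- function(values, weights = NULL, nbins = 50,
                          probs = c(0.005, 0.995)) {
  if (is.null(weights)) weights <- rep(1, length(values))
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  lo <- values[o][which(cw >= probs[1])[1]]
  hi <- values[o][which(cw >= probs[2])[1]]
  if (hi <= lo) { lo <- min(values); hi <- max(values) + 1e-9 }
  seq(lo, hi, length.out = nbins + 1)
}

#' Two-dimensional free-energy surface from a weighted ensemble
#'
#' Bins (x, y) jointly, converts bin probability densities P to free
#' energies f = -kBT ln P, and shifts so the minimum over occupied bins is
#' exactly zero.  Empty bins are masked (NA in `f`, FALSE in `occupied`),
#' never given a numeric free energy.
#'
#' @param x,y observable values (Angstrom in the distance analyses).
#' @param weights optional snapshot weights.
#' @param x_edges,y_edges bin boundaries.
#' @param temperature K.
#' @return Object of class `free_energy_surface`: `f` (matrix, kcal/mol,
#'   NA where empty), `occupied` mask, edges, `temperature`, `ess`.
#' @export
free_energy_2d <- function(x, y, weights = NULL, x_edges, y_edges,
                           temperature = 310) {
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(x) == length(weights))
  if (any(diff(x_edges) <= 0) || any(diff(y_edges) <= 0))
    stop("bin edges must be strictly increasing")
  nx <- length(x_edges) - 1; ny <- length(y_edges) - 1
  keep <- x >= x_edges[1] & x <= x_edges[nx + 1] &
          y >= y_edges[1] & y <= y_edges[ny + 1]
  if (sum(weights[keep]) <= 0) stop("no weighted mass inside the grid")
  bx <- findInterval(x[keep], x_edges, rightmost.closed = TRUE)
  by <- findInterval(y[keep], y_edges, rightmost.closed = TRUE)
  mass <- matrix(0, nx, ny)
  ww <- weights[keep] / sum(weights[keep])
  for (i in seq_along(ww)) mass[bx[i], by[i]] <- mass[bx[i], by[i]] + ww[i]
  occupied <- mass > 0
  if (sum(occupied) < 2)
    warning("fewer than 2 occupied bins in free-energy surface")
  area <- outer(diff(x_edges), diff(y_edges))
  kT <- kBT(temperature)
  f <- matrix(NA_real_, nx, ny)
  f[occupied] <- -kT * log(mass[occupied] / area[occupied])
  f <- f - min(f[occupied])
  structure(list(f = f, occupied = occupied, mass = mass,
                 x_edges = x_edges, y_edges = y_edges,
                 temperature = temperature,
                 ess = effective_sample_size(weights[keep])),
            class = "free_energy_surface")
}

#' Weighted Pearson correlation
#'
#' Weighted covariance over the product of weighted standard deviations;
#' uniform weights reduce it to the ordinary Pearson coefficient.
#'
#' @param x,y paired observable values.
#' @param weights optional snapshot weights (>= 0, at least two positive).
#' @return Correlation in [-1, 1].
#' @export
weighted_pearson <- function(x, y, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(x) == length(weights),
            all(weights >= 0))
  if (sum(weights > 0) < 2) stop("need >= 2 points with positive weight")
  w <- weights / sum(weights)
  mx <- sum(w * x); my <- sum(w * y)
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx <= 0 || cyy <= 0)
    stop("zero weighted variance: correlation undefined")
  cxy <- sum(w * (x - mx) * (y - my))
  max(-1, min(1, cxy / sqrt(cxx * cyy)))
}

#' Select a half-open time window of a series
#'
#' Keeps entries with t_start <= t < t_end.  The half-open convention makes
#' consecutive windows compose without double counting.  Typical use is
#' restricting the analysis to the equilibrated tail of each run (e.g. the
#' last 0.5 of a 1.2 span).
#'
#' @param times frame time stamps.
#' @param t_start,t_end window bounds, t_start < t_end.
#' @return Integer indices of the retained frames (error if none).
#' @export
select_window <- function(times, t_start, t_end) {
  stopifnot(t_start < t_end)
  idx <- which(times >= t_start & times < t_end)
  if (length(idx) == 0)
    stop("empty window [", t_start, ", ", t_end, ") for times in [",
         min(times), ", ", max(times), "]")
  idx
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' sum p log(p/q) over bins with p > 0; used to compare reweighted
#' histograms with the quadrature Boltzmann oracle.
#'
#' @param p,q probability masses on the same bins (each summing to 1).
#' @return Non-negative divergence in nats (Inf if q = 0 where p > 0).
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  s <- p > 0
  if (any(q[s] == 0)) return(Inf)
  sum(p[s] * log(p[s] / q[s]))
}

#' Marginal of a free-energy surface along x
#'
#' Converts the surface back to bin probabilities and sums over y; used to
#' check consistency with directly computed 1D histograms.
#'
#' @param fes a [free_energy_2d()] surface.
#' @return Numeric vector of x-bin masses summing to 1.
#' @export
fel_marginal_x <- function(fes) {
  stopifnot(inherits(fes, "free_energy_surface"))
  kT <- kBT(fes$temperature)
  area <- outer(diff(fes$x_edges), diff(fes$y_edges))
  p <- matrix(0, nrow(fes$f), ncol(fes$f))
  p[fes$occupied] <- exp(-fes$f[fes$occupied] / kT) * area[fes$occupied]
  rowSums(p) / sum(p)
}
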