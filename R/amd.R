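# Accelerated-MD boost potential and a toy Langevin simulator.
#
# The boost lifts the potential below a threshold E_B:
#
#   V*(r) = V(r) + dV(r),   dV = (E_B - V)^2 / (alpha + E_B - V)  for V < E_B
#                           dV = 0                                 for V >= E_B
#
# so barriers are flattened while the surface above E_B is untouched.  The
# boosted force is the unboosted force scaled by alpha^2/(alpha+E_B-V)^2,
# the derivative of V* with respect to V.  Reweighting each snapshot by
# exp(dV/kBT) recovers canonical-ensemble statistics.

#' Boost specification for accelerated MD
#'
#' @param e_b threshold energy E_B in kcal/mol; boosting is active below it.
#' @param alpha boost-depth parameter alpha in kcal/mol (> 0); smaller alpha
#'   flattens the surface more aggressively.
#' @return An object of class `boost_spec`.
#' @export
boost_spec <- function(e_b, alpha) {
  stopifnot(is.finite(e_b), is.finite(alpha), alpha > 0)
  structure(list(e_b = e_b, alpha = alpha), class = "boost_spec")
}

#' Boost energy Delta-V at a potential energy
#'
#' Vectorized in `v`.  Zero at and above the threshold; below it,
#' `(e_b - v)^2 / (alpha + e_b - v)`, which is always >= 0 and keeps the
#' boosted energy `v + dV` below `e_b`.  A list of boost specs (e.g. a
#' dihedral plus a total-potential boost) contributes additively, matching
#' the way dual-boost logs are summed on input.
#'
#' @param v potential energy (kcal/mol), scalar or vector.
#' @param boost a [boost_spec()] or list of them.
#' @return Delta-V in kcal/mol, same length as `v`.
#' @export
boost_delta_v <- function(v, boost) {
  if (inherits(boost, "boost_spec")) boost <- list(boost)
  dv <- numeric(length(v))
  for (b in boost) {
    u <- b$e_b - v
    dv <- dv + ifelse(u > 0, u * u / (b$alpha + u), 0)
  }
  dv
}

#' Force-scaling factor on the boosted surface
#'
#' The boosted force equals the unboosted force times
#' `alpha^2 / (alpha + e_b - v)^2` below the threshold and 1 at or above
#' it; equivalently `1 + d(dV)/dv`.  The factor lies in (0, 1] and tends to
#' 0 as v -> -Inf.  For a list of boosts the factors from each term
#' combine as `1 + sum(f_i - 1)` (additive dV derivatives).
#'
#' @inheritParams boost_delta_v
#' @return Dimensionless factor(s) in (0, 1].
#' @export
force_scale <- function(v, boost) {
  if (inherits(boost, "boost_spec")) boost <- list(boost)
  f <- rep(1, length(v))
  for (b in boost) {
    u <- b$e_b - v
    f <- f + ifelse(u > 0, b$alpha^2 / (b$alpha + u)^2 - 1, 0)
  }
  f
}

#' Analytic toy potentials
#'
#' `harmonic_potential`: V(x) = sum k/2 (x - center)^2 in d dimensions.
#' `double_well_potential`: 1D quartic V(x) = h ((x^2 - a^2) / a^2)^2 with
#' minima at +/- a (Angstrom) and barrier height h (kcal/mol) at x = 0.
#' `toy_potential` wraps arbitrary value/gradient closures.
#'
#' @param k stiffness, kcal/mol/A^2.
#' @param d dimensionality.
#' @param center minimum position (recycled to length d).
#' @return A `toy_potential` object with `$value(x)`, `$grad(x)`, `$d`.
#' @export
harmonic_potential <- function(k, d = 1, center = 0) {
  stopifnot(k > 0, d >= 1)
  center <- rep_len(center, d)
  toy_potential(value = function(x) 0.5 * k * sum((x - center)^2),
                grad = function(x) k * (x - center),
                d = d, name = "harmonic",
                parameters = list(k = k, center = center))
}

#' @rdname harmonic_potential
#' @param height barrier height h, kcal/mol.
#' @param separation half well separation a, Angstrom (minima at +/- a).
#' @export
double_well_potential <- function(height, separation) {
  stopifnot(height > 0, separation > 0)
  h <- height; a <- separation
  toy_potential(value = function(x) h * ((x[1]^2 - a^2) / a^2)^2,
                grad = function(x) 4 * h * x[1] * (x[1]^2 - a^2) / a^4,
                d = 1, name = "double_well",
                parameters = list(height = h, separation = a))
}

#' @rdname harmonic_potential
#' @param value function(x) -> energy kcal/mol; must be bounded below.
#' @param grad function(x) -> gradient vector, kcal/mol/A.
#' @param name label used in metadata.
#' @param parameters named list recorded in metadata.
#' @export
toy_potential <- function(value, grad, d, name = "custom", parameters = list()) {
  stopifnot(is.function(value), is.function(grad), d >= 1)
  structure(list(value = value, grad = grad, d = as.integer(d),
                 name = name, parameters = parameters),
            class = "toy_potential")
}

#' Simulation specification for the toy Langevin integrator
#'
#' Defaults mirror typical solution-MD thermostat settings: 310 K and a
#' collision frequency of 1 ps^-1.
#'
#' @param temperature K.
#' @param friction collision frequency gamma, ps^-1.
#' @param timestep ps.
#' @param n_steps number of integration steps.
#' @param stride save every `stride`-th step.
#' @param seed integer RNG seed; the run is reproducible given the seed.
#' @param mass particle mass, amu.
#' @param x0 initial position (recycled to potential dimension).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(temperature = 310, friction = 1, timestep = 0.002,
                     n_steps = 10000, stride = 10, seed = 1, mass = 12,
                     x0 = 0) {
  stopifnot(temperature >= 0, friction > 0, timestep > 0, n_steps >= 1,
            stride >= 1, mass > 0)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed),
                 mass = mass, x0 = x0),
            class = "sim_spec")
}

#' Run toy Langevin dynamics, optionally on the boosted surface
#'
#' BAOAB splitting with the exact Ornstein-Uhlenbeck solution for the
#' friction substep, so the sampled configurational distribution is
#' accurate at the default timestep.  With a boost, dynamics run on
#' V* = V + dV (forces scaled by [force_scale()]) and the per-frame dV is
#' logged for reweighting.  At zero temperature the integrator is purely
#' deterministic dissipative dynamics.
#'
#' @param potential a `toy_potential`.
#' @param spec a [sim_spec()].
#' @param boost optional [boost_spec()] (or list of them).
#' @return A `toy_trajectory`: list with `positions` (frames x d), `times`
#'   (ps), `v` (unboosted potential energy per frame, kcal/mol), `delta_v`
#'   (kcal/mol, zeros when unboosted), and the specs used.
#' @export
run_langevin <- function(potential, spec, boost = NULL) {
  stopifnot(inherits(potential, "toy_potential"), inherits(spec, "sim_spec"))
  if (!is.null(boost) && inherits(boost, "boost_spec")) boost <- list(boost)
  d <- potential$d
  dt <- spec$timestep
  m <- spec$mass
  kT <- .kB * spec$temperature
  c1 <- exp(-spec$friction * dt)
  c2 <- sqrt((1 - c1^2) * .AKMA * kT / m)
  acc <- .AKMA / m

  set.seed(spec$seed)
  x <- rep_len(spec$x0, d)
  vel <- rnorm(d) * sqrt(.AKMA * kT / m)

  vfun <- potential$value
  gfun <- potential$grad
  forcefun <- if (is.null(boost)) {
    function(x) -gfun(x)
  } else {
    function(x) {
      v <- vfun(x)
      -gfun(x) * force_scale(v, boost)
    }
  }

  n_out <- spec$n_steps %/% spec$stride
  pos <- matrix(NA_real_, n_out, d)
  vser <- numeric(n_out)
  dvser <- numeric(n_out)

  f <- forcefun(x)
  half_dt_acc <- 0.5 * dt * acc
  for (step in seq_len(spec$n_steps)) {
    vel <- vel + half_dt_acc * f
    x <- x + (0.5 * dt) * vel
    vel <- c1 * vel + c2 * rnorm(d)
    x <- x + (0.5 * dt) * vel
    f <- forcefun(x)
    vel <- vel + half_dt_acc * f
    if (step %% spec$stride == 0) {
      v <- vfun(x)
      if (!is.finite(v) || any(!is.finite(x)))
        stop("non-finite energy/position at step ", step)
      j <- step %/% spec$stride
      pos[j, ] <- x
      vser[j] <- v
      dvser[j] <- if (is.null(boost)) 0 else boost_delta_v(v, boost)
    }
  }
  structure(list(positions = pos,
                 times = dt * spec$stride * seq_len(n_out),
                 v = vser, delta_v = dvser,
                 potential = potential$name,
                 parameters = potential$parameters,
                 spec = spec,
                 boost = boost),
            class = "toy_trajectory")
}

#' Write a toy trajectory as columnar text plus a Delta-V log
#'
#' @param traj a `toy_trajectory` from [run_langevin()].
#' @param path output table (step, time_ps, coordinates, V, Delta-V).
#' @param deltav_path optional Delta-V log in the [read_deltav_log()] format.
#' @export
write_toy_trajectory <- function(traj, path, deltav_path = NULL) {
  d <- ncol(traj$positions)
  tab <- data.frame(step = seq_len(nrow(traj$positions)) * traj$spec$stride,
                    time_ps = traj$times)
  for (j in seq_len(d)) tab[[paste0("x", j)]] <- traj$positions[, j]
  tab$v <- traj$v
  tab$delta_v <- traj$delta_v
  con <- file(path, "w")
  writeLines(paste0("# ", paste(names(tab), collapse = "\t")), con)
  utils::write.table(format(tab, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  if (!is.null(deltav_path))
    write_deltav_log(traj$delta_v, deltav_path)
  invisible(path)
}
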