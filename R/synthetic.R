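# Synthetic fixtures with known ground truth.
#
# Three generators cover the pipeline's needs: (i) quadrature Boltzmann
# densities on analytic potentials, the independent oracle for reweighting;
# (ii) bivariate distance ensembles with prescribed means, spreads and
# anticorrelation, emulating the (FAD-FMN, FMN-heme) statistics of the
# oxidized and reduced states; (iii) two-domain bead-model PDB trajectories
# that exercise the full file-based pipeline at desk scale.

#' Redox-state ensemble presets
#'
#' Bivariate-normal presets for the joint (FAD-FMN distance, predicted
#' FMN-heme distance) ensemble.  The anticorrelations (-0.21 oxidized,
#' -0.41 reduced) are the state-defining statistics; the means and SDs are
#' package choices at a physically sensible scale (the reduced state sits
#' 2 A more open in FAD-FMN distance and correspondingly closer in
#' FMN-heme distance).
#'
#' @param name "oxidized" or "reduced".
#' @return Object of class `state_preset` with fields `d_fadfmn_mean`,
#'   `d_fadfmn_sd`, `d_fmnheme_mean`, `d_fmnheme_sd`, `rho`, `open_shift`.
#' @export
state_preset <- function(name = c("oxidized", "reduced")) {
  name <- match.arg(name)
  p <- switch(name,
    oxidized = list(d_fadfmn_mean = 12, d_fadfmn_sd = 2,
                    d_fmnheme_mean = 25, d_fmnheme_sd = 3, rho = -0.21),
    reduced  = list(d_fadfmn_mean = 14, d_fadfmn_sd = 2.5,
                    d_fmnheme_mean = 22, d_fmnheme_sd = 3, rho = -0.41))
  p$name <- name
  p$open_shift <- 2  # reduced minus oxidized FAD-FMN mean, Angstrom
  stopifnot(p$d_fadfmn_sd > 0, p$d_fmnheme_sd > 0, abs(p$rho) < 1)
  structure(p, class = "state_preset")
}

#' Boltzmann density oracle by numerical quadrature
#'
#' exp(-V/kBT) on a 1D grid, normalized by the trapezoidal rule.  Entirely
#' independent of the Langevin sampler and of the reweighting code, so it
#' serves as ground truth for both.
#'
#' @param potential a `toy_potential` (1D).
#' @param temperature K.
#' @param grid strictly increasing evaluation points (Angstrom).
#' @return List: `grid`, `density` (integrates to 1 on the grid).
#' @export
boltzmann_density_oracle <- function(potential, temperature, grid) {
  stopifnot(inherits(potential, "toy_potential"), potential$d == 1,
            all(diff(grid) > 0))
  v <- vapply(grid, function(x) potential$value(x), numeric(1))
  dens <- exp(-(v - min(v)) / kBT(temperature))
  z <- sum(diff(grid) * (dens[-1] + dens[-length(dens)]) / 2)
  list(grid = grid, density = dens / z)
}

#' Boltzmann bin masses on histogram edges
#'
#' Integrates the quadrature density over each bin (fine sub-grid per bin)
#' and normalizes; the comparison target for reweighted histograms.
#'
#' @param potential 1D `toy_potential`.
#' @param temperature K.
#' @param edges histogram bin edges.
#' @param n_sub quadrature points per bin.
#' @return Numeric bin masses summing to 1.
#' @export
boltzmann_bin_masses <- function(potential, temperature, edges, n_sub = 64) {
  nb <- length(edges) - 1
  masses <- vapply(seq_len(nb), function(b) {
    g <- seq(edges[b], edges[b + 1], length.out = n_sub)
    v <- vapply(g, function(x) potential$value(x), numeric(1))
    d <- exp(-v / kBT(temperature))
    sum(diff(g) * (d[-1] + d[-n_sub]) / 2)
  }, numeric(1))
  masses / sum(masses)
}

#' Generate a bivariate distance ensemble for a redox-state preset
#'
#' Draws n samples of (FAD-FMN, FMN-heme) distances.  Untilted
#' (`tilted = FALSE`): samples come from the preset bivariate normal and
#' the pseudo boost series is zero (uniform weights recover the preset
#' directly).  Tilted (`tilted = TRUE`): samples come from a mean-shifted
#' copy of the preset density q, and each sample carries a pseudo boost
#' dV = kBT log(p/q) (shifted to be >= 0 and capped so the max weight
#' ratio stays <= `max_weight_ratio`), so that exp(dV/kBT) reweighting
#' recovers the preset from the deliberately biased draw while the
#' unweighted estimate reproduces the tilted parameters.
#'
#' @param preset a [state_preset()].
#' @param n sample count (>= 2).
#' @param seed integer RNG seed; generation is reproducible.
#' @param tilted draw from the shifted density with pseudo boosts?
#' @param tilt_shift mean shift of the tilted draw, in preset SD units.
#' @param temperature K (enters the pseudo-boost scale only).
#' @param max_weight_ratio cap on max/min snapshot weight.
#' @param mixture draw from a two-component closed/open mixture instead of
#'   a single bivariate normal: the open component is shifted by
#'   `open_shift` outward in FAD-FMN distance and inward in FMN-heme
#'   distance, emulating shifted bimodal distance distributions.
#'   Incompatible with `tilted`.
#' @param p_open open-component probability when `mixture = TRUE`.
#' @return data.frame with columns `d_fad_fmn`, `d_fmn_heme`, `delta_v`
#'   (kcal/mol) and attributes `preset`, `tilted`.
#' @export
generate_two_state_ensemble <- function(preset, n, seed = 1, tilted = FALSE,
                                        tilt_shift = 0.5, temperature = 310,
                                        max_weight_ratio = 1e3,
                                        mixture = FALSE, p_open = 0.3) {
  stopifnot(inherits(preset, "state_preset"), n >= 2)
  if (tilted && mixture)
    stop("the tilted pseudo-boost construction is defined for the single-component draw")
  mu <- c(preset$d_fadfmn_mean, preset$d_fmnheme_mean)
  s1 <- preset$d_fadfmn_sd; s2 <- preset$d_fmnheme_sd
  sigma <- matrix(c(s1^2, preset$rho * s1 * s2,
                    preset$rho * s1 * s2, s2^2), 2, 2)
  ch <- chol(sigma)
  set.seed(seed)
  z <- matrix(rnorm(2 * n), n, 2)
  delta <- if (tilted) tilt_shift * c(s1, s2) else c(0, 0)
  x <- z %*% ch + matrix(mu + delta, n, 2, byrow = TRUE)
  if (mixture) {
    open <- runif(n) < p_open
    x[open, 1] <- x[open, 1] + preset$open_shift
    x[open, 2] <- x[open, 2] - preset$open_shift
  }
  if (tilted) {
    sinv <- solve(sigma)
    qf <- function(center) {
      xc <- sweep(x, 2, center)
      rowSums((xc %*% sinv) * xc)
    }
    log_ratio <- -0.5 * qf(mu) + 0.5 * qf(mu + delta)  # log p - log q
    kT <- kBT(temperature)
    dv <- kT * (log_ratio - min(log_ratio))
    cap <- kT * log(max_weight_ratio)
    dv <- pmin(dv, cap)
  } else {
    dv <- rep(0, n)
  }
  out <- data.frame(d_fad_fmn = x[, 1], d_fmn_heme = x[, 2], delta_v = dv)
  attr(out, "preset") <- preset
  attr(out, "tilted") <- tilted
  out
}

#' Write / read a distance ensemble as on-disk files
#'
#' The ensemble is written the way the pipeline exchanges data: a TSV of
#' per-frame distances plus a Delta-V log in the [read_deltav_log()]
#' format.  `read_two_state_ensemble()` reassembles the data.frame.
#'
#' @param ens ensemble from [generate_two_state_ensemble()].
#' @param dir output directory (created if needed).
#' @return Invisibly, named paths `distances`, `deltav`.
#' @export
write_two_state_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dist_path <- file.path(dir, "distances.tsv")
  dv_path <- file.path(dir, "deltav.log")
  con <- file(dist_path, "w")
  writeLines("# frame\td_fad_fmn\td_fmn_heme", con)
  writeLines(sprintf("%d\t%.10g\t%.10g", seq_len(nrow(ens)) - 1,
                     ens$d_fad_fmn, ens$d_fmn_heme), con)
  close(con)
  write_deltav_log(ens$delta_v, dv_path)
  invisible(c(distances = dist_path, deltav = dv_path))
}

#' @rdname write_two_state_ensemble
#' @param dir directory written by `write_two_state_ensemble()`.
#' @export
read_two_state_ensemble <- function(dir) {
  tab <- utils::read.table(file.path(dir, "distances.tsv"),
                           comment.char = "#")
  dv <- read_deltav_log(file.path(dir, "deltav.log"))
  if (length(dv) != nrow(tab))
    stop("distance table and Delta-V log disagree in frame count")
  data.frame(d_fad_fmn = tab[[2]], d_fmn_heme = tab[[3]], delta_v = dv)
}

#' Bead-model specification
#'
#' Two rigid bead domains stand in for the FAD domain (with its cofactor
#' ring) and the FMN domain (with its ring); a companion complex-reference
#' structure adds a HEM pseudo-residue on a partner chain.  Interdomain
#' separations are sampled per frame from a [state_preset()]; `jitter_sd`
#' adds independent Gaussian noise to every atom, emulating thermal
#' fluctuation.
#'
#' @param beads_per_domain beads per rigid domain (>= 3).
#' @param n_frames frames to generate.
#' @param jitter_sd per-coordinate thermal jitter SD, Angstrom (>= 0).
#' @param seed integer RNG seed.
#' @param separation_closed,separation_open interdomain distances (A) used
#'   for the complex-reference geometry and metadata.
#' @return Object of class `bead_model_spec`.
#' @export
bead_model_spec <- function(beads_per_domain = 8, n_frames = 100,
                            jitter_sd = 0.1, seed = 1,
                            separation_closed = 12, separation_open = 14) {
  stopifnot(beads_per_domain >= 3, n_frames >= 1, jitter_sd >= 0)
  structure(list(beads_per_domain = as.integer(beads_per_domain),
                 n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 seed = as.integer(seed),
                 separation_closed = separation_closed,
                 separation_open = separation_open),
            class = "bead_model_spec")
}

# Ring template: atoms on a circle in the yz-plane, then translated so the
# *mass-weighted* center sits exactly at `center` despite heterogeneous
# element masses.
.ring_atoms <- function(center, names, resname, resid, chain, radius = 1.5) {
  k <- length(names)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  coord <- cbind(0, radius * cos(theta), radius * sin(theta))
  ele <- toupper(substr(names, 1, 1))
  mass <- .atom_masses(ele, names)
  com <- colSums(coord * mass) / sum(mass)
  coord <- sweep(coord, 2, com) +
    matrix(center, k, 3, byrow = TRUE)
  list(atom = data.frame(atom_name = names, residue_name = resname,
                         residue_id = resid, chain_id = chain,
                         element = ele, mass = mass,
                         stringsAsFactors = FALSE),
       coord = coord)
}

# Domain template: beads on a circle of radius 3 A in the yz-plane centered
# (by mass) at `center`; carbon beads named CA so Calpha selections work.
.domain_atoms <- function(center, n, resid_start, chain) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  coord <- cbind(0, 3 * cos(theta), 3 * sin(theta))
  coord <- sweep(coord, 2, colMeans(coord)) + matrix(center, n, 3, byrow = TRUE)
  list(atom = data.frame(atom_name = "CA", residue_name = "ALA",
                         residue_id = resid_start + seq_len(n) - 1,
                         chain_id = chain, element = "C",
                         mass = rep(12.0107, n), stringsAsFactors = FALSE),
       coord = coord)
}

# Assemble one CPR-like bead frame: FAD domain (+ FAD ring) fixed at the
# origin, FMN domain at distance d1 along x, FMN ring placed so its
# mass center lies at distance d2 from the heme position `heme_pos`.
.bead_frame_coords <- function(nb, d1, d2, heme_pos) {
  fad_dom <- .domain_atoms(c(0, 0, 0), nb, 1, "A")
  fmn_dom <- .domain_atoms(c(d1, 0, 0), nb, 101, "A")
  fad_ring <- .ring_atoms(c(0, 0, 0), alloxazine_atoms(), "FAD", 900, "A")
  fmn_ring <- .ring_atoms(heme_pos + c(-d2, 0, 0), alloxazine_atoms(),
                          "FMN", 901, "A")
  # FAD/FMN rings share atom names; distinct residue ids keep keys unique
  atom <- rbind(fad_dom$atom, fmn_dom$atom, fad_ring$atom, fmn_ring$atom)
  coord <- rbind(fad_dom$coord, fmn_dom$coord, fad_ring$coord, fmn_ring$coord)
  list(atom = atom, coord = coord)
}

#' Standard selections for bead-model structures
#'
#' @param spec a [bead_model_spec()].
#' @return Named list of [selection_spec()]s: `fad_domain`, `fmn_domain`,
#'   `fad_ring`, `fmn_ring`, `heme`.
#' @export
bead_model_selections <- function(spec) {
  nb <- spec$beads_per_domain
  list(fad_domain = selection_spec("fad_domain",
                                   residue_ranges = list(c(1, nb)),
                                   atom_names = "CA"),
       fmn_domain = selection_spec("fmn_domain",
                                   residue_ranges = list(c(101, 100 + nb)),
                                   atom_names = "CA"),
       fad_ring = selection_spec("fad_ring", residue_names = "FAD",
                                 atom_names = alloxazine_atoms()),
       fmn_ring = selection_spec("fmn_ring", residue_names = "FMN",
                                 atom_names = alloxazine_atoms()),
       heme = selection_spec("heme", residue_names = "HEM"))
}

#' Generate a bead-model PDB trajectory with companion files
#'
#' Writes a multi-model PDB trajectory whose per-frame interdomain
#' (FAD-FMN) distance and predicted FMN-heme distance are sampled from the
#' preset's bivariate distribution, a Delta-V log (zeros for the untilted
#' draw, pseudo boosts for the tilted one), a complex-reference PDB with a
#' HEM pseudo-residue on chain H, and a JSON manifest of every parameter.
#' The files round-trip through [read_pdb()] and feed the geometry module,
#' which recovers the preset distance statistics.
#'
#' @param spec a [bead_model_spec()].
#' @param preset a [state_preset()].
#' @param dir output directory (created).
#' @param tilted passed to [generate_two_state_ensemble()].
#' @param fixed_distances optional 2-column matrix overriding the sampled
#'   (d1, d2) per frame - used for exactly constructed fixtures.
#' @return List: `paths` (trajectory, deltav, complex_ref, manifest),
#'   `selections`, `samples` (the generating distance table).
#' @export
generate_bead_trajectory <- function(spec, preset, dir, tilted = FALSE,
                                     fixed_distances = NULL) {
  stopifnot(inherits(spec, "bead_model_spec"), inherits(preset, "state_preset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nb <- spec$beads_per_domain
  heme_pos <- c(30, 2, 0)

  if (is.null(fixed_distances)) {
    ens <- generate_two_state_ensemble(preset, spec$n_frames,
                                       seed = spec$seed, tilted = tilted)
  } else {
    stopifnot(nrow(fixed_distances) == spec$n_frames)
    ens <- data.frame(d_fad_fmn = fixed_distances[, 1],
                      d_fmn_heme = fixed_distances[, 2],
                      delta_v = 0)
  }

  template <- .bead_frame_coords(nb, preset$d_fadfmn_mean,
                                 preset$d_fmnheme_mean, heme_pos)
  set.seed(spec$seed + 1L)
  xyz <- matrix(NA_real_, spec$n_frames, 3 * nrow(template$atom))
  for (i in seq_len(spec$n_frames)) {
    fr <- .bead_frame_coords(nb, ens$d_fad_fmn[i], ens$d_fmn_heme[i], heme_pos)
    coord <- fr$coord
    if (spec$jitter_sd > 0)
      coord <- coord + matrix(rnorm(length(coord), sd = spec$jitter_sd),
                              nrow(coord), 3)
    xyz[i, ] <- as.vector(t(coord))
  }
  traj <- md_trajectory(template$atom, xyz, delta_v = ens$delta_v)

  # complex reference: unjittered CPR part in the closed arrangement plus a
  # heme pseudo-residue (Fe + 4 pyrrole-like N) on partner chain H
  ref_cpr <- .bead_frame_coords(nb, spec$separation_closed,
                                spec$separation_open, heme_pos)
  hem <- .ring_atoms(heme_pos, c("FE", "N1", "N2", "N3", "N4"),
                     "HEM", 950, "H", radius = 2)
  hem$atom$element <- c("FE", "N", "N", "N", "N")
  hem$atom$mass <- .atom_masses(hem$atom$element, hem$atom$atom_name)
  # re-center by the corrected masses so the heme COM is exactly heme_pos
  com <- colSums(hem$coord * hem$atom$mass) / sum(hem$atom$mass)
  hem$coord <- sweep(hem$coord, 2, com - heme_pos)
  ref <- md_structure(rbind(ref_cpr$atom, hem$atom),
                      rbind(ref_cpr$coord, hem$coord))

  paths <- c(trajectory = file.path(dir, "trajectory.pdb"),
             deltav = file.path(dir, "deltav.log"),
             complex_ref = file.path(dir, "complex_ref.pdb"),
             manifest = file.path(dir, "manifest.json"))
  write_pdb(traj, paths[["trajectory"]])
  write_deltav_log(ens$delta_v, paths[["deltav"]])
  write_pdb(ref, paths[["complex_ref"]])
  manifest <- list(generator = "generate_bead_trajectory",
                   spec = unclass(spec), preset = unclass(preset),
                   tilted = tilted, heme_position = heme_pos,
                   com_convention = "mass-weighted over all selected atoms (hydrogen-free structures use heavy atoms)")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths[["manifest"]])
  list(paths = paths, selections = bead_model_selections(spec),
       samples = ens)
}
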