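# Shared fixtures: tiny PDB writers, random rigid transforms, and the
# brute-force rotation-grid RMSD oracle used to check Kabsch superposition.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resno, x, y, z, element)
}

# a 5-atom single-model structure on disk; returns the path
write_tiny_pdb <- function(path, shift = 0, models = 1, drop_atom_in = NULL) {
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1) lines <- c(lines, sprintf("MODEL %8d", m))
    atoms <- c(
      pdb_line(1, "CA", "ALA", "A", 1, 0 + shift, 0, 0 + m - 1),
      pdb_line(2, "CA", "ALA", "A", 2, 2 + shift, 0, 0 + m - 1),
      pdb_line(3, "CB", "ALA", "A", 2, 2 + shift, 1, 0 + m - 1),
      pdb_line(4, "N1", "FMN", "A", 9, 4 + shift, 1, 0 + m - 1,
               record = "HETATM", element = "N"),
      pdb_line(5, "C2", "FMN", "A", 9, 4 + shift, 2, 0 + m - 1,
               record = "HETATM", element = "C"))
    if (!is.null(drop_atom_in) && m == drop_atom_in) atoms <- atoms[-3]
    lines <- c(lines, atoms)
    if (models > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# uniform-ish random rotation from three Euler angles + random translation
random_rigid_transform <- function() {
  ang <- stats::runif(3, 0, 2 * pi)
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  list(rotation = rz %*% ry %*% rx, translation = stats::runif(3, -10, 10))
}

apply_rigid <- function(coords, tr) {
  coords %*% t(tr$rotation) +
    matrix(tr$translation, nrow(coords), 3, byrow = TRUE)
}

transform_structure <- function(s, tr) {
  md_structure(s$atom, apply_rigid(s$coord, tr))
}

# first frame of either container type
first_frame <- function(x) {
  if (inherits(x, "md_structure")) x else get_frame(x, 1)
}

# Brute-force minimum RMSD over a ZYZ Euler-angle rotation grid (degrees).
# Independent of kabsch_superpose: optimal translation is handled by
# centering, and the rotation is exhaustively enumerated.
grid_min_rmsd <- function(mobile, reference, step_deg = 5) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  n <- nrow(a)
  const <- sum(a^2) / n + sum(b^2) / n
  h <- t(a) %*% b
  rotz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
  roty <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  full <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  half <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a1 in full) {
    r1 <- rotz(a1)
    for (b1 in half) {
      r12 <- r1 %*% roty(b1)
      for (c1 in full) {
        r <- r12 %*% rotz(c1)
        msd <- const - 2 * sum(r * t(h)) / n
        if (msd < best) best <- msd
      }
    }
  }
  sqrt(max(best, 0))
}
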