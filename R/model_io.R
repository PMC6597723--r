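# Structure / trajectory containers and PDB + boost-log I/O.
#
# PDB parsing and writing are delegated to bio3d; this file adds the
# containers the analysis works on (per-atom masses, per-frame times and
# boost energies), strict topology validation across MODEL blocks, and the
# named-selection machinery for domains and cofactor rings.

#' Construct a structure object
#'
#' A structure is an atom table plus an N x 3 coordinate matrix (Angstrom).
#' Masses are in amu and must be positive; coordinates must be finite.
#'
#' @param atom data.frame with columns `atom_name`, `residue_name`,
#'   `residue_id`, `chain_id`, `element`, `mass`.
#' @param coord numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atom, coord) {
  coord <- as.matrix(coord)
  required <- c("atom_name", "residue_name", "residue_id", "chain_id",
                "element", "mass")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols) > 0)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atom) != nrow(coord))
    stop("atom table (", nrow(atom), ") and coordinates (", nrow(coord),
         ") disagree in atom count")
  if (!all(is.finite(coord)))
    stop("non-finite coordinates in structure")
  if (any(!is.finite(atom$mass)) || any(atom$mass <= 0))
    stop("every atom must have a finite positive mass")
  key <- paste(atom$chain_id, atom$residue_id, atom$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_id, atom_name) in structure: ",
         key[duplicated(key)][1])
  structure(list(atom = atom, coord = coord), class = "md_structure")
}

#' Construct a trajectory object
#'
#' Frames share one topology (the atom table); coordinates are stored as an
#' F x 3N matrix in bio3d xyz layout (x1, y1, z1, x2, ...).
#'
#' @param atom shared atom table (see [md_structure()]).
#' @param xyz numeric matrix, one row per frame, 3N columns.
#' @param times frame time stamps in ns, strictly increasing.  Defaults to
#'   0, 1, 2, ... frame indices.
#' @param delta_v optional per-frame boost energy Delta-V in kcal/mol
#'   (all values >= 0), used for aMD reweighting.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(atom, xyz, times = NULL, delta_v = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(atom))
    stop("xyz has ", ncol(xyz), " columns; expected ", 3 * nrow(atom))
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in trajectory")
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz))
    stop("times length differs from frame count")
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(delta_v)) {
    if (length(delta_v) != nrow(xyz))
      stop("delta_v length (", length(delta_v), ") differs from frame count (",
           nrow(xyz), ")")
    if (any(!is.finite(delta_v)) || any(delta_v < 0))
      stop("delta_v values must be finite and >= 0")
  }
  if (any(!is.finite(atom$mass)) || any(atom$mass <= 0))
    stop("every atom must have a finite positive mass")
  structure(list(atom = atom, xyz = xyz, times = as.numeric(times),
                 delta_v = delta_v),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return An `md_structure`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  md_structure(traj$atom, matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE))
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atom), "atoms,",
      length(unique(paste(x$atom$chain_id, x$atom$residue_id))), "residues\n")
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames x", nrow(x$atom), "atoms; t = [",
      x$times[1], ",", x$times[length(x$times)], "] ns;",
      if (is.null(x$delta_v)) "no" else "with", "boost log\n")
  invisible(x)
}

# Pre-scan of a PDB file: validates ATOM/HETATM records and per-MODEL atom
# counts so malformed or topology-inconsistent files fail with a precise
# message before bio3d sees them.
.scan_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad) == 0) {
    coords <- lapply(which(is_atom), function(i) {
      suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                    substr(lines[i], 39, 46),
                                    substr(lines[i], 47, 54))))
    })
    bad <- which(is_atom)[vapply(coords, function(z) any(is.na(z)), logical(1))]
  }
  if (length(bad) > 0)
    stop("malformed ATOM/HETATM record at line ", bad[1], " of ", path,
         ": ", trimws(lines[bad[1]]))
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) <= 1) return(invisible(length(model_starts)))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL blocks in ", path)
  counts <- mapply(function(a, b) sum(is_atom[a:b]), model_starts, model_ends)
  if (length(unique(counts)) != 1)
    stop("inconsistent topology in ", path, ": model atom counts ",
         paste(counts, collapse = ", "))
  invisible(length(model_starts))
}

# Standard atomic masses (amu) for the elements that occur in protein /
# cofactor structures.
.element_mass_table <- c(
  "H" = 1.00794, "D" = 2.0141, "C" = 12.0107, "N" = 14.0067, "O" = 15.9994,
  "F" = 18.9984, "NA" = 22.98977, "MG" = 24.305, "P" = 30.97376,
  "S" = 32.065, "CL" = 35.453, "K" = 39.0983, "CA" = 40.078,
  "MN" = 54.93805, "FE" = 55.845, "CO" = 58.9332, "NI" = 58.6934,
  "CU" = 63.546, "ZN" = 65.38, "SE" = 78.96, "BR" = 79.904, "I" = 126.9045)

# element -> mass, with a fallback guess from the first letter of the atom
# name for records lacking an element column.
.atom_masses <- function(elesy, elety) {
  ele <- toupper(trimws(elesy))
  guess <- toupper(substr(trimws(elety), 1, 1))
  bad <- is.na(ele) | ele == "" | !(ele %in% names(.element_mass_table))
  ele[bad] <- guess[bad]
  m <- unname(.element_mass_table[ele])
  if (any(is.na(m)))
    stop("cannot assign a mass to element(s): ",
         paste(unique(ele[is.na(m)]), collapse = ", "))
  m
}

.atom_table_from_bio3d <- function(pdb_atom) {
  # altloc: keep blank or 'A'; insertion codes: keep the first occurrence.
  keep <- is.na(pdb_atom$alt) | pdb_atom$alt %in% c("", "A")
  if (!all(keep))
    warning("dropping ", sum(!keep), " alternate-location atoms (altloc != 'A')")
  pdb_atom <- pdb_atom[keep, , drop = FALSE]
  ins <- ifelse(is.na(pdb_atom$insert), "", pdb_atom$insert)
  if (any(ins != "")) {
    key <- paste(pdb_atom$chain, pdb_atom$resno, pdb_atom$elety)
    first <- !duplicated(key)
    if (!all(first | ins == "")) warning("keeping first insertion code only")
    pdb_atom <- pdb_atom[first | ins == "", , drop = FALSE]
  }
  chain <- ifelse(is.na(pdb_atom$chain), "", pdb_atom$chain)
  data.frame(atom_name = pdb_atom$elety,
             residue_name = pdb_atom$resid,
             residue_id = pdb_atom$resno,
             chain_id = chain,
             element = toupper(trimws(ifelse(is.na(pdb_atom$elesy), "",
                                             pdb_atom$elesy))),
             mass = .atom_masses(pdb_atom$elesy, pdb_atom$elety),
             keep = pdb_atom$eleno,
             stringsAsFactors = FALSE)
}

#' Read a PDB file
#'
#' Single-MODEL files give an [md_structure()]; multi-MODEL files give an
#' [md_trajectory()] whose frames share one topology.  Hetero residues
#' (FAD, FMN, NAP, HEM, ...) are retained.  Masses are assigned from the
#' element symbol (or guessed from the atom name when the element column is
#' absent); structures without hydrogens are fine - centers of mass are then
#' heavy-atom centers.  Alternate locations other than 'A' and repeated
#' insertion codes are dropped with a warning.
#'
#' @param path PDB file.
#' @param times optional frame times (ns) for multi-model files.
#' @return `md_structure` or `md_trajectory`.
#' @export
read_pdb <- function(path, times = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_models <- .scan_pdb(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- .atom_table_from_bio3d(pdb$atom)
  # map kept atoms back into xyz columns
  idx <- match(atom$keep, pdb$atom$eleno)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  atom$keep <- NULL
  xyz <- pdb$xyz[, cols, drop = FALSE]
  if (nrow(xyz) > 1) {
    md_trajectory(atom, xyz, times = times)
  } else {
    md_structure(atom, matrix(xyz[1, ], ncol = 3, byrow = TRUE))
  }
}

#' Write a structure or trajectory to a PDB file
#'
#' Multi-frame input is written as MODEL/ENDMDL blocks.  Coordinates are
#' fixed-width PDB (3 decimals).
#'
#' @param x `md_structure` or `md_trajectory`.
#' @param path output file.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "md_structure")) {
    xyz <- matrix(as.vector(t(x$coord)), nrow = 1)
  } else if (inherits(x, "md_trajectory")) {
    xyz <- x$xyz
  } else stop("x must be md_structure or md_trajectory")
  at <- x$atom
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$residue_id, resid = at$residue_name,
                   elety = at$atom_name, chain = at$chain_id,
                   elesy = at$element)
  invisible(path)
}

#' Define a named atom selection
#'
#' Selections name the structural parts the analysis speaks about: the FAD
#' domain (customarily including the connecting domain), the FMN domain, the
#' alloxazine rings of the flavin cofactors, and the heme of a redox
#' partner.  All criteria present are combined with AND.  Residue ranges
#' (inclusive, PDB author numbering) must not overlap.
#'
#' @param name selection label, used in error messages and metadata.
#' @param residue_ranges list of `c(first, last)` inclusive residue-id ranges.
#' @param residue_names optional character vector of residue names (e.g. "FMN").
#' @param atom_names optional character vector of atom names (e.g. "CA").
#' @param chain_id optional chain restriction.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(name, residue_ranges = NULL, residue_names = NULL,
                           atom_names = NULL, chain_id = NULL) {
  if (!is.null(residue_ranges)) {
    if (!is.list(residue_ranges)) residue_ranges <- list(residue_ranges)
    for (r in residue_ranges)
      if (length(r) != 2 || r[1] > r[2])
        stop("residue range must be c(first, last) with first <= last")
    if (length(residue_ranges) > 1) {
      o <- order(vapply(residue_ranges, `[`, numeric(1), 1))
      rr <- residue_ranges[o]
      for (i in seq_len(length(rr) - 1))
        if (rr[[i + 1]][1] <= rr[[i]][2])
          stop("overlapping residue ranges in selection '", name, "'")
    }
  }
  structure(list(name = name, residue_ranges = residue_ranges,
                 residue_names = residue_names, atom_names = atom_names,
                 chain_id = chain_id),
            class = "selection_spec")
}

# The 15 fused-ring (iso)alloxazine atoms of a flavin, PDB chemical
# component names; methyls and the ribityl chain are excluded.
#' Alloxazine ring atom names
#'
#' Default atom set defining the redox-active fused tricyclic ring of FAD
#' and FMN: N1, C2, O2, N3, C4, O4, C4A, N5, C5A, C6, C7, C8, C9, C9A, N10.
#' @export
alloxazine_atoms <- function() {
  c("N1", "C2", "O2", "N3", "C4", "O4", "C4A", "N5", "C5A",
    "C6", "C7", "C8", "C9", "C9A", "N10")
}

#' Resolve a selection on a structure or trajectory topology
#'
#' @param x `md_structure` or `md_trajectory`.
#' @param spec a [selection_spec()] (or an integer index vector, returned
#'   unchanged after range checking).
#' @return Integer atom indices in topology order; an empty result is an
#'   error naming the selection.
#' @export
resolve_selection <- function(x, spec) {
  at <- x$atom
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
    if (length(idx) == 0 || any(idx < 1) || any(idx > nrow(at)))
      stop("index selection out of range")
    return(idx)
  }
  stopifnot(inherits(spec, "selection_spec"))
  keep <- rep(TRUE, nrow(at))
  if (!is.null(spec$chain_id))
    keep <- keep & at$chain_id %in% spec$chain_id
  if (!is.null(spec$residue_ranges)) {
    in_range <- rep(FALSE, nrow(at))
    for (r in spec$residue_ranges)
      in_range <- in_range | (at$residue_id >= r[1] & at$residue_id <= r[2])
    keep <- keep & in_range
  }
  if (!is.null(spec$residue_names))
    keep <- keep & at$residue_name %in% spec$residue_names
  if (!is.null(spec$atom_names))
    keep <- keep & at$atom_name %in% spec$atom_names
  idx <- which(keep)
  if (length(idx) == 0)
    stop("selection '", spec$name, "' matches no atoms")
  idx
}

#' Mass-weighted center of a selection
#'
#' @param x `md_structure`.
#' @param selection a [selection_spec()] or integer indices.
#' @return Numeric length-3 vector (Angstrom).
#' @export
center_of_mass <- function(x, selection) {
  stopifnot(inherits(x, "md_structure"))
  idx <- resolve_selection(x, selection)
  m <- x$atom$mass[idx]
  if (sum(m) <= 0) stop("zero total mass in selection")
  colSums(x$coord[idx, , drop = FALSE] * m) / sum(m)
}

#' Read a per-frame boost-energy (Delta-V) log
#'
#' Whitespace-separated columns: frame index then one or more boost-energy
#' columns in kcal/mol; `#` starts a comment.  When several boost columns
#' are present (e.g. a dihedral and a total-potential boost), the series
#' used downstream is their elementwise sum, matching the additive dual
#' boost.  The 6-column AMBER-style amd.log dialect is accepted via
#' `columns`, naming which columns hold the boosts.
#'
#' @param path log file.
#' @param columns integer columns holding boost energies; default all
#'   columns after the first.
#' @return Numeric Delta-V series (kcal/mol) ordered by frame index.
#' @export
read_deltav_log <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           colClasses = "numeric")
  if (ncol(tab) < 2)
    stop("Delta-V log needs a frame-index column plus >= 1 boost column")
  if (is.null(columns)) columns <- 2:ncol(tab)
  if (any(columns < 2) || any(columns > ncol(tab)))
    stop("boost column indices out of range")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate frame index in Delta-V log: ",
         tab[[1]][duplicated(tab[[1]])][1])
  dv <- rowSums(tab[, columns, drop = FALSE])
  if (any(!is.finite(dv)) || any(dv < 0))
    stop("Delta-V values must be finite and >= 0 (line ",
         which(!is.finite(dv) | dv < 0)[1], ")")
  dv[order(tab[[1]])]
}

#' Write a Delta-V log in the columnar format read by [read_deltav_log()]
#'
#' @param delta_v numeric boost energies, kcal/mol.
#' @param path output file.
#' @param frame_index frame indices; default 0-based.
#' @export
write_deltav_log <- function(delta_v, path, frame_index = NULL) {
  if (is.null(frame_index)) frame_index <- seq_along(delta_v) - 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame_index deltav_total", con)
  writeLines(sprintf("%d %.10g", frame_index, delta_v), con)
  invisible(path)
}
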