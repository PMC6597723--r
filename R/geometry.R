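# Structural observables: interdomain / inter-cofactor distances, Kabsch
# superposition, and the complex-reference FMN-to-heme distance prediction.
#
# The open-close coordinate is the distance between the mass centers of the
# FAD domain (with the connecting domain) and the FMN domain; the
# electron-transfer coordinate is the distance between the alloxazine-ring
# mass centers of the two flavins.  Because the downstream acceptor is not
# part of the simulated system, the FMN-to-heme distance is *predicted*:
# each snapshot's FAD domain is superposed onto the FAD domain of a
# CPR-acceptor complex structure, and the distance is measured from the
# superposed snapshot's FMN ring to the complex's heme.

#' Distance between the mass centers of two selections
#'
#' @param frame an `md_structure`.
#' @param sel_a,sel_b selections ([selection_spec()] or indices).
#' @return Distance in Angstrom.
#' @export
interdomain_distance <- function(frame, sel_a, sel_b) {
  sqrt(sum((center_of_mass(frame, sel_a) - center_of_mass(frame, sel_b))^2))
}

#' @rdname interdomain_distance
#' @details `intercofactor_distance` is the same center-of-mass distance
#'   evaluated on cofactor-ring selections (see [alloxazine_atoms()]).
#' @export
intercofactor_distance <- function(frame, sel_a, sel_b) {
  interdomain_distance(frame, sel_a, sel_b)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation taking `mobile` onto `reference`,
#' via SVD of the weighted covariance of the centered coordinate sets, with
#' the reflection corrected so the rotation is proper (det = +1).
#'
#' @param mobile,reference N x 3 coordinate matrices, paired row-by-row,
#'   N >= 3 and not collinear.
#' @param weights optional per-point fitting weights (e.g. masses); default
#'   uniform.
#' @return List of class `rigid_transform`: `rotation` (3 x 3, proper
#'   orthogonal), `translation` (length 3), `rmsd` (the minimized weighted
#'   RMSD, Angstrom).  Apply as `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("degenerate geometry: need >= 3 paired points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  ma <- colSums(mobile * w); mb <- colSums(reference * w)
  a <- sweep(mobile, 2, ma); b <- sweep(reference, 2, mb)
  # collinearity check: rank of the centered mobile set
  if (sum(svd(a)$d > 1e-8 * max(1, max(abs(a)))) < 2)
    stop("degenerate geometry: points are collinear")
  h <- t(a * w) %*% b
  s <- svd(h)
  dsign <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  translation <- as.numeric(mb - r %*% ma)
  fitted <- a %*% t(r)
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  structure(list(rotation = r, translation = translation, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 matrix (or length-3 vector).
#' @param transform a `rigid_transform`.
#' @return Transformed coordinates, same shape.
#' @export
apply_transform <- function(coords, transform) {
  vec <- is.null(dim(coords))
  coords <- matrix(coords, ncol = 3, byrow = FALSE)
  out <- coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Reference complex structure for the FMN-to-heme prediction
#'
#' Bundles the CPR-acceptor complex structure with the three selections the
#' prediction needs: the FAD domain (fit region), the FMN alloxazine ring,
#' and the heme of the partner protein.
#'
#' @param structure `md_structure` of the complex.
#' @param fad_domain,fmn_ring,heme selections on `structure`.
#' @return Object of class `complex_reference`.
#' @export
complex_reference <- function(structure, fad_domain, fmn_ring, heme) {
  stopifnot(inherits(structure, "md_structure"))
  for (s in list(fad_domain, fmn_ring, heme)) resolve_selection(structure, s)
  structure(list(structure = structure, fad_domain = fad_domain,
                 fmn_ring = fmn_ring, heme = heme),
            class = "complex_reference")
}

# Pair atoms between a frame and a reference by (residue_id, atom_name)
# within the given selections; Calpha-only by default.
.pair_atoms <- function(frame, frame_sel, ref, ref_sel, fit_atoms = "CA") {
  fi <- resolve_selection(frame, frame_sel)
  ri <- resolve_selection(ref, ref_sel)
  if (!is.null(fit_atoms)) {
    fi <- fi[frame$atom$atom_name[fi] %in% fit_atoms]
    ri <- ri[ref$atom$atom_name[ri] %in% fit_atoms]
  }
  fkey <- paste(frame$atom$residue_id[fi], frame$atom$atom_name[fi])
  rkey <- paste(ref$atom$residue_id[ri], ref$atom$atom_name[ri])
  common <- intersect(fkey, rkey)
  if (length(common) < 3) {
    missing <- setdiff(rkey, fkey)
    stop("cannot pair fit atoms between frame and reference; unmatched: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  }
  list(frame = fi[match(common, fkey)], ref = ri[match(common, rkey)])
}

#' Predict the FMN-ring-to-heme distance of a snapshot
#'
#' Superposes the snapshot's FAD domain onto the reference complex's FAD
#' domain (Kabsch on atoms paired by residue id and atom name, Calpha-only
#' by default, unweighted), applies the fit to the whole snapshot, and
#' returns the center-of-mass distance between the transformed snapshot's
#' FMN alloxazine ring and the reference heme.  The result is invariant
#' under any rigid transform of the input frame.
#'
#' @param frame `md_structure` snapshot.
#' @param frame_selections list with elements `fad_domain` and `fmn_ring`,
#'   selections on `frame`.
#' @param ref a [complex_reference()].
#' @param fit_atoms atom names used in the superposition (default "CA";
#'   NULL fits every paired atom).
#' @param fit_weights optional per-atom weights for the fit (e.g. masses).
#' @return Predicted distance in Angstrom.
#' @export
predict_fmn_heme_distance <- function(frame, frame_selections, ref,
                                      fit_atoms = "CA", fit_weights = NULL) {
  stopifnot(inherits(ref, "complex_reference"))
  pair <- .pair_atoms(frame, frame_selections$fad_domain,
                      ref$structure, ref$fad_domain, fit_atoms)
  tr <- kabsch_superpose(frame$coord[pair$frame, , drop = FALSE],
                         ref$structure$coord[pair$ref, , drop = FALSE],
                         weights = fit_weights)
  ring_idx <- resolve_selection(frame, frame_selections$fmn_ring)
  m <- frame$atom$mass[ring_idx]
  ring_com <- colSums(apply_transform(frame$coord[ring_idx, , drop = FALSE],
                                      tr) * m) / sum(m)
  heme_com <- center_of_mass(ref$structure, ref$heme)
  sqrt(sum((ring_com - heme_com)^2))
}

#' Distance observables along a trajectory
#'
#' Per frame: the FAD-FMN interdomain distance, the inter-cofactor
#' (alloxazine ring) distance, and, when a complex reference is supplied,
#' the predicted FMN-to-heme distance.
#'
#' @param traj `md_trajectory`.
#' @param selections list with `fad_domain`, `fmn_domain`, `fad_ring`,
#'   `fmn_ring` selections.
#' @param ref optional [complex_reference()].
#' @param fit_atoms see [predict_fmn_heme_distance()].
#' @return data.frame: frame, time, d_interdomain, d_intercofactor
#'   (+ d_fmn_heme).
#' @export
trajectory_distances <- function(traj, selections, ref = NULL,
                                 fit_atoms = "CA") {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  d_dom <- numeric(nf); d_cof <- numeric(nf)
  d_fh <- if (is.null(ref)) NULL else numeric(nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    d_dom[i] <- interdomain_distance(fr, selections$fad_domain,
                                     selections$fmn_domain)
    d_cof[i] <- intercofactor_distance(fr, selections$fad_ring,
                                       selections$fmn_ring)
    if (!is.null(ref))
      d_fh[i] <- predict_fmn_heme_distance(fr, selections, ref, fit_atoms)
  }
  out <- data.frame(frame = seq_len(nf), time = traj$times,
                    d_interdomain = d_dom, d_intercofactor = d_cof)
  if (!is.null(ref)) out$d_fmn_heme <- d_fh
  out
}
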