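# Distances, Kabsch superposition, and the FMN-heme distance prediction.

make_two_domain_structure <- function() {
  at <- data.frame(atom_name = rep("CA", 8), residue_name = "ALA",
                   residue_id = 1:8, chain_id = "A", element = "C",
                   mass = 12)
  # domain A: square around origin; domain B: square around (3, 4, 0)
  sq <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  md_structure(at, rbind(sq, sweep(sq, 2, -c(3, 4, 0))))
}

test_that("interdomain distance is a COM distance with rigid invariance", {
  s <- make_two_domain_structure()
  expect_equal(interdomain_distance(s, 1:4, 5:8), 5)  # 3-4-5 triangle
  expect_equal(interdomain_distance(s, 1:4, 1:4), 0)
  expect_equal(interdomain_distance(s, 5:8, 1:4), 5)  # symmetric

  set.seed(23)
  for (i in 1:5) {
    tr <- random_rigid_transform()
    expect_equal(interdomain_distance(transform_structure(s, tr), 1:4, 5:8),
                 5, tolerance = 1e-10)
  }
  # permuting atom order within a selection changes nothing
  expect_equal(intercofactor_distance(s, c(3, 1, 4, 2), 5:8), 5)

  # triangle inequality for COM points
  expect_lte(abs(interdomain_distance(s, 1:4, 5:8) -
                 interdomain_distance(s, 1:2, 5:8)) - 1e-12,
             interdomain_distance(s, 1:4, 1:2))
})

test_that("Kabsch superposition recovers exact transforms and proper rotations", {
  set.seed(29)
  a <- matrix(rnorm(15), 5, 3)
  id <- kabsch_superpose(a, a)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_lt(id$rmsd, 1e-10)

  for (i in 1:5) {
    tr <- random_rigid_transform()
    b <- apply_rigid(a, tr)
    fit <- kabsch_superpose(a, b)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(fit$rotation, tr$rotation, tolerance = 1e-8)
    expect_equal(apply_transform(a, fit), b, tolerance = 1e-8)
    # proper orthogonality
    expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-10)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }

  # mirror image: reflection must be rejected, so the fit is imperfect
  m4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 0.9))
  mir <- m4 %*% diag(c(1, 1, -1))
  fm <- kabsch_superpose(m4, mir)
  expect_equal(det(fm$rotation), 1, tolerance = 1e-10)
  expect_gt(fm$rmsd, 0.1)
  expect_lte(fm$rmsd, grid_min_rmsd(m4, mir, step_deg = 10) + 1e-9)

  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), "3 paired points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches brute-force rotation search and bio3d", {
  set.seed(37)
  for (i in 1:3) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    fit <- kabsch_superpose(a, b)
    gmin <- grid_min_rmsd(a, b, step_deg = 5)
    expect_lte(fit$rmsd, gmin + 1e-9)           # true optimum can't be worse
    ac <- sweep(a, 2, colMeans(a))
    expect_lte(gmin - fit$rmsd, 0.2 * max(sqrt(rowSums(ac^2))))
    # independent route: bio3d's least-squares fit (printed to 3 decimals)
    b3 <- bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
    expect_equal(fit$rmsd, b3, tolerance = 1e-3)
  }
})

test_that("the FMN-heme prediction is self-consistent and rigid-invariant", {
  spec <- bead_model_spec(n_frames = 1, jitter_sd = 0, seed = 5)
  preset <- state_preset("oxidized")
  dir <- withr::local_tempdir()
  res <- generate_bead_trajectory(spec, preset, dir,
                                  fixed_distances = cbind(12, 20))
  ref_s <- read_pdb(res$paths[["complex_ref"]])
  sels <- res$selections
  ref <- complex_reference(ref_s, sels$fad_domain, sels$fmn_ring, sels$heme)

  # reference CPR as its own frame: prediction equals the reference's own
  # FMN-ring-to-heme COM distance
  cpr_idx <- which(ref_s$atom$residue_name != "HEM")
  frame_ref <- md_structure(ref_s$atom[cpr_idx, ], ref_s$coord[cpr_idx, ])
  own <- sqrt(sum((center_of_mass(ref_s, sels$fmn_ring) -
                   center_of_mass(ref_s, sels$heme))^2))
  expect_equal(predict_fmn_heme_distance(frame_ref, sels, ref), own,
               tolerance = 1e-8)

  # a constructed frame with the ring exactly d2 = 20 A from the heme
  frame <- read_pdb(res$paths[["trajectory"]])
  fr <- first_frame(frame)
  expect_equal(predict_fmn_heme_distance(fr, sels, ref), 20, tolerance = 1e-6)

  # invariance under arbitrary rigid transforms of the input frame
  set.seed(41)
  for (i in 1:5) {
    tr <- random_rigid_transform()
    expect_equal(predict_fmn_heme_distance(transform_structure(fr, tr),
                                           sels, ref),
                 20, tolerance = 1e-8)
  }

  # displacing the FMN ring 2 A toward the heme shortens the prediction by 2
  ring_idx <- resolve_selection(fr, sels$fmn_ring)
  heme_com <- center_of_mass(ref_s, sels$heme)
  ring_com <- center_of_mass(fr, sels$fmn_ring)
  u <- (heme_com - ring_com) / sqrt(sum((heme_com - ring_com)^2))
  shifted <- fr
  shifted$coord[ring_idx, ] <- sweep(shifted$coord[ring_idx, ], 2, -2 * u)
  expect_equal(predict_fmn_heme_distance(shifted, sels, ref), 18,
               tolerance = 1e-6)

  # unmatched pairing errors name the problem
  broken <- fr
  broken$atom$residue_id[broken$atom$atom_name == "CA"] <- 500 +
    seq_len(sum(broken$atom$atom_name == "CA"))
  expect_error(predict_fmn_heme_distance(broken, sels, ref), "unmatched|no atoms")
})

test_that("trajectory_distances tabulates all observables per frame", {
  spec <- bead_model_spec(n_frames = 25, jitter_sd = 0, seed = 8)
  preset <- state_preset("reduced")
  dir <- withr::local_tempdir()
  res <- generate_bead_trajectory(spec, preset, dir)
  traj <- read_pdb(res$paths[["trajectory"]])
  ref_s <- read_pdb(res$paths[["complex_ref"]])
  sels <- res$selections
  ref <- complex_reference(ref_s, sels$fad_domain, sels$fmn_ring, sels$heme)
  dt <- trajectory_distances(traj, sels, ref = ref)
  expect_equal(nrow(dt), 25)
  expect_equal(dt$d_interdomain, res$samples$d_fad_fmn, tolerance = 1e-3)
  expect_equal(dt$d_fmn_heme, res$samples$d_fmn_heme, tolerance = 1e-3)
})
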