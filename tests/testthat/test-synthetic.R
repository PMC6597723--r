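# Quadrature oracle, two-state ensembles, bead-model generators.

test_that("the quadrature Boltzmann oracle matches closed forms", {
  k <- 2; temp <- 310
  pot <- harmonic_potential(k = k)
  grid <- seq(-4, 4, length.out = 2001)
  o <- boltzmann_density_oracle(pot, temp, grid)
  expect_equal(o$density, dnorm(grid, 0, sqrt(kBT(temp) / k)),
               tolerance = 1e-5)

  # symmetric double well: equal mass in both wells
  dw <- double_well_potential(height = 3, separation = 1.5)
  g2 <- seq(-4, 4, length.out = 4001)
  o2 <- boltzmann_density_oracle(dw, temp, g2)
  left <- sum(o2$density[g2 < 0]); right <- sum(o2$density[g2 > 0])
  expect_equal(left / right, 1, tolerance = 1e-6)

  # grid refinement stability of bin masses
  edges <- seq(-3, 3, length.out = 31)
  m1 <- boltzmann_bin_masses(dw, temp, edges, n_sub = 128)
  m2 <- boltzmann_bin_masses(dw, temp, edges, n_sub = 256)
  expect_lt(max(abs(m1 - m2)), 1e-6)
})

test_that("a tilted double well yields the Boltzmann well-mass ratio", {
  # V = quartic double well + small linear tilt; at low T the well-mass
  # ratio approaches exp(-dE/kBT) with dE the minima energy difference
  h <- 3; a <- 1.5; c <- 0.2; temp <- 80
  pot <- toy_potential(value = function(x) h * ((x^2 - a^2) / a^2)^2 + c * x,
                       grad = function(x) 4 * h * x * (x^2 - a^2) / a^4 + c,
                       d = 1)
  xl <- optimize(pot$value, c(-3, 0))$minimum
  xr <- optimize(pot$value, c(0, 3))$minimum
  de <- pot$value(xr) - pot$value(xl)
  g <- seq(-4, 4, length.out = 8001)
  o <- boltzmann_density_oracle(pot, temp, g)
  ratio <- sum(o$density[g > 0]) / sum(o$density[g < 0])
  expect_equal(log(ratio), -de / kBT(temp), tolerance = 0.05)
})

test_that("two-state ensembles realize their presets reproducibly", {
  preset <- state_preset("reduced")
  expect_gt(preset$d_fadfmn_mean, state_preset("oxidized")$d_fadfmn_mean)

  # bit-reproducible generation
  e1 <- generate_two_state_ensemble(preset, 1000, seed = 5)
  e2 <- generate_two_state_ensemble(preset, 1000, seed = 5)
  expect_identical(e1, e2)

  # zero-correlation preset: sample correlation ~ 0
  p0 <- preset; p0$rho <- 0
  e0 <- generate_two_state_ensemble(p0, 1e5, seed = 6)
  expect_lt(abs(cor(e0$d_fad_fmn, e0$d_fmn_heme)), 0.01)

  # reduced preset, untilted draw, uniform weights: r = -0.41 +/- 0.02
  er <- generate_two_state_ensemble(preset, 1e5, seed = 7)
  expect_equal(weighted_pearson(er$d_fad_fmn, er$d_fmn_heme), -0.41,
               tolerance = 0.02)
  expect_true(all(er$delta_v == 0))

  # closed/open mixture option shifts the open component by open_shift
  em <- generate_two_state_ensemble(preset, 4e4, seed = 10, mixture = TRUE,
                                    p_open = 0.5)
  expect_equal(mean(em$d_fad_fmn),
               preset$d_fadfmn_mean + 0.5 * preset$open_shift,
               tolerance = 0.05)
  expect_error(generate_two_state_ensemble(preset, 10, tilted = TRUE,
                                           mixture = TRUE),
               "single-component")

  # tilted draw: pseudo boosts bounded by the weight-ratio cap
  et <- generate_two_state_ensemble(preset, 1e4, seed = 8, tilted = TRUE)
  expect_true(all(et$delta_v >= 0))
  expect_lte(max(et$delta_v), kBT(310) * log(1e3) + 1e-12)
})

test_that("ensemble files round-trip through the on-disk format", {
  ens <- generate_two_state_ensemble(state_preset("oxidized"), 500,
                                     seed = 9, tilted = TRUE)
  dir <- withr::local_tempdir()
  write_two_state_ensemble(ens, dir)
  back <- read_two_state_ensemble(dir)
  expect_equal(back$d_fad_fmn, ens$d_fad_fmn, tolerance = 1e-8)
  expect_equal(back$d_fmn_heme, ens$d_fmn_heme, tolerance = 1e-8)
  expect_equal(back$delta_v, ens$delta_v, tolerance = 1e-8)
})

test_that("bead trajectories encode the requested distances exactly at zero jitter", {
  preset <- state_preset("oxidized")
  spec <- bead_model_spec(n_frames = 4, jitter_sd = 0, seed = 2)
  dir <- withr::local_tempdir()
  res <- generate_bead_trajectory(spec, preset, dir,
                                  fixed_distances = cbind(rep(11, 4),
                                                          rep(24, 4)))
  traj <- read_pdb(res$paths[["trajectory"]])
  sels <- res$selections
  for (i in 1:4) {
    fr <- get_frame(traj, i)
    expect_equal(interdomain_distance(fr, sels$fad_domain, sels$fmn_domain),
                 11, tolerance = 1e-3)
  }
})

test_that("bead ensembles separate redox states by the configured open shift", {
  n <- 400
  measure <- function(state, dir) {
    preset <- state_preset(state)
    spec <- bead_model_spec(n_frames = n, jitter_sd = 0.1, seed = 14)
    res <- generate_bead_trajectory(spec, preset, dir)
    traj <- read_pdb(res$paths[["trajectory"]])
    sels <- res$selections
    vapply(seq_len(n), function(i)
      interdomain_distance(get_frame(traj, i), sels$fad_domain,
                           sels$fmn_domain), numeric(1))
  }
  d <- list(ox = measure("oxidized", withr::local_tempdir()),
            red = measure("reduced", withr::local_tempdir()))
  shift <- mean(d$red) - mean(d$ox)
  se <- sqrt(var(d$red) / n + var(d$ox) / n)
  expect_lt(abs(shift - state_preset("reduced")$open_shift), 3 * se)
})

test_that("generated bundles round-trip losslessly through model_io", {
  preset <- state_preset("reduced")
  spec <- bead_model_spec(n_frames = 10, jitter_sd = 0.05, seed = 3)
  dir <- withr::local_tempdir()
  res <- generate_bead_trajectory(spec, preset, dir, tilted = TRUE)
  traj <- read_pdb(res$paths[["trajectory"]])
  expect_equal(n_frames(traj), 10)
  dv <- read_deltav_log(res$paths[["deltav"]])
  expect_equal(dv, res$samples$delta_v, tolerance = 1e-8)
  out <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, out)
  again <- read_pdb(out)
  expect_equal(again$xyz, traj$xyz, tolerance = 1e-9)
  expect_identical(again$atom$atom_name, traj$atom$atom_name)
  manifest <- jsonlite::read_json(res$paths[["manifest"]])
  expect_equal(manifest$preset$rho, -0.41)
})
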