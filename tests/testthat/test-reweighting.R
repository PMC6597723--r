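# Snapshot weights, weighted estimators, free-energy surfaces, windows.

test_that("snapshot weights follow exp(dV/kBT) with overflow-safe shifting", {
  expect_equal(snapshot_weights(c(0, 0, 0), 310), rep(1 / 3, 3))

  kT <- kBT(310)
  expect_equal(snapshot_weights(c(0, kT * log(2)), 310), c(1 / 3, 2 / 3))

  set.seed(7)
  dv <- runif(100, 0, 5)
  expect_equal(snapshot_weights(dv + 3.7, 310), snapshot_weights(dv, 310))
  # huge boosts do not overflow
  expect_equal(sum(snapshot_weights(dv + 1e6, 310)), 1)
  expect_error(snapshot_weights(numeric(0)), "empty")
})

test_that("weighted histograms bin mass correctly and match binomial error", {
  h <- weighted_histogram(c(0.5, 0.6), weights = c(1, 1), edges = c(0, 1, 2))
  expect_equal(h$masses, c(1, 0))

  h2 <- weighted_histogram(c(0.5, 1.5), weights = c(0.25, 0.75),
                           edges = c(0, 1, 2))
  expect_equal(h2$masses, c(0.25, 0.75))

  # out-of-range values dropped and counted, mass renormalized
  h3 <- weighted_histogram(c(0.5, 1.5, 9), weights = c(1, 1, 2),
                           edges = c(0, 1, 2))
  expect_equal(h3$n_dropped, 1)
  expect_equal(sum(h3$masses), 1)

  # large normal sample vs analytic masses, binomial 3 SE per bin
  set.seed(31)
  n <- 2e4
  x <- rnorm(n)
  edges <- seq(-3, 3, by = 0.5)
  h4 <- weighted_histogram(x, edges = edges)
  p <- diff(pnorm(edges)) / diff(pnorm(c(-3, 3)))
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(h4$masses - p) < 3 * se + 1e-12))
})

test_that("free-energy surfaces obey the min-shift, ratio and masking contract", {
  # two equally occupied bins -> both exactly zero
  f <- free_energy_2d(c(0.5, 1.5), c(0.5, 0.5), weights = c(1, 1),
                      x_edges = c(0, 1, 2), y_edges = c(0, 1),
                      temperature = 310)
  expect_equal(f$f[, 1], c(0, 0))

  # occupancy ratio e:1 -> free-energy gap of exactly kBT (~0.616 kcal/mol)
  f2 <- free_energy_2d(c(0.5, 1.5), c(0.5, 0.5),
                       weights = c(exp(1), 1),
                       x_edges = c(0, 1, 2), y_edges = c(0, 1),
                       temperature = 310)
  expect_equal(min(f2$f[f2$occupied]), 0)
  expect_equal(f2$f[2, 1] - f2$f[1, 1], kBT(310), tolerance = 1e-12)
  expect_equal(kBT(310), 0.61603324, tolerance = 1e-7)

  # empty bins are masked, not numeric
  f3 <- free_energy_2d(c(0.5, 2.5), c(0.5, 0.5), weights = c(1, 1),
                       x_edges = c(0, 1, 2, 3), y_edges = c(0, 1))
  expect_true(is.na(f3$f[2, 1]))
  expect_false(f3$occupied[2, 1])

  expect_warning(free_energy_2d(rep(0.5, 4), rep(0.5, 4), NULL,
                                c(0, 1), c(0, 1)), "fewer than 2")
})

test_that("the 2D surface is marginally consistent with 1D histograms", {
  set.seed(13)
  n <- 5000
  x <- rnorm(n, 12, 2); y <- rnorm(n, 25, 3)
  w <- runif(n)
  xe <- seq(4, 20, length.out = 21); ye <- seq(15, 35, length.out = 16)
  keep <- x >= min(xe) & x <= max(xe) & y >= min(ye) & y <= max(ye)
  fes <- free_energy_2d(x, y, w, xe, ye, 310)
  h1 <- weighted_histogram(x[keep], w[keep], xe)
  expect_lt(max(abs(fel_marginal_x(fes) - h1$masses)), 1e-10)
})

test_that("weighted Pearson correlation matches its invariances and cov.wt", {
  set.seed(17)
  x <- rnorm(30)
  w <- runif(30)
  expect_equal(weighted_pearson(x, 2 * x + 1, w), 1)
  expect_equal(weighted_pearson(x, -x), -1)

  y <- rnorm(30) + 0.5 * x
  r <- weighted_pearson(x, y, w)
  expect_equal(weighted_pearson(y, x, w), r)                  # symmetry
  expect_equal(weighted_pearson(3 * x + 2, 0.5 * y - 1, w), r) # affine
  expect_equal(weighted_pearson(-x, y, w), -r)                 # sign flip
  expect_equal(weighted_pearson(x, y), cor(x, y))              # uniform limit
  # independent route: stats::cov.wt with the same weights
  expect_equal(r, cov.wt(cbind(x, y), wt = w, cor = TRUE, method = "ML")$cor[1, 2],
               tolerance = 1e-12)

  expect_error(weighted_pearson(rep(1, 5), rnorm(5)), "zero weighted variance")
  expect_error(weighted_pearson(1, 2, 1), "2 points")
})

test_that("time windows are half-open and validated", {
  times <- seq(0, 1.19, by = 0.01)
  expect_identical(select_window(times, 0, 2), seq_along(times))
  idx <- select_window(times, 0.7, 1.2)  # last 0.5 of a 1.2 span
  expect_equal(min(times[idx]), 0.7)
  expect_equal(length(idx), 50)
  # half-open: t = t_end excluded
  expect_false(31 %in% select_window(times, 0.0, 0.3))
  expect_error(select_window(times, 5, 6), "empty window")
})

test_that("effective sample size diagnoses weight concentration", {
  expect_equal(effective_sample_size(rep(0.1, 10)), 10)
  expect_equal(effective_sample_size(c(1, 0, 0)), 1)
  w <- snapshot_weights(c(0, 10, 0), 310)
  expect_lt(effective_sample_size(w), 1.01)
})

test_that("tilted draws are corrected by their pseudo boosts", {
  preset <- state_preset("reduced")
  ens <- generate_two_state_ensemble(preset, 4e4, seed = 12, tilted = TRUE)
  w <- snapshot_weights(ens$delta_v, 310)
  ess <- effective_sample_size(w)
  for (col in c("d_fad_fmn", "d_fmn_heme")) {
    mu <- if (col == "d_fad_fmn") preset$d_fadfmn_mean else preset$d_fmnheme_mean
    sd0 <- if (col == "d_fad_fmn") preset$d_fadfmn_sd else preset$d_fmnheme_sd
    se <- sd0 / sqrt(ess)
    # weighted estimates recover the preset ...
    expect_lt(abs(sum(w * ens[[col]]) - mu), 3 * se)
    wsd <- sqrt(sum(w * (ens[[col]] - sum(w * ens[[col]]))^2))
    expect_lt(abs(wsd - sd0), 3 * sd0 * sqrt(2 / ess))
    # ... while the unweighted (biased-draw) estimates do not
    expect_gt(abs(mean(ens[[col]]) - mu), 10 * se)
  }
})
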