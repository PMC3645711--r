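test_that("a frozen trajectory gives RAF = 1, MSD = 0 and zero-variance series", {
  spec <- small_spec(n_frames = 20, D_lateral = 0, D_r = 0, box_fluct_sd = 0)
  tr <- generate_bilayer(spec)
  lf <- assign_leaflets(tr)
  raf <- head_vector_raf(tr, lf, window = c(0, 1))
  expect_equal(raf$raf, rep(1, nrow(raf)))
  msd <- msd_lateral(tr, lf, window = c(0, 1))
  expect_equal(msd$msd, rep(0, nrow(msd)))
  expect_equal(attr(area_per_lipid(tr, lf, c(0, 1)), "sd"), 0)
})

test_that("rigid rotation about x gives RAF(t) = cos(wt) at exact lags", {
  n <- 5
  F <- 41
  dt <- 0.005
  w_ang <- 2 * pi / (200 * dt) # one revolution per 200 frames
  P <- array(cbind(1:n * 8, 10, rep(c(15, -15), length.out = n)), c(n, 3, F))
  u <- array(NA_real_, c(n, 3, F))
  for (f in seq_len(F)) {
    ang <- w_ang * (f - 1) * dt
    u[, , f] <- matrix(rep(c(0, sin(ang), cos(ang)), each = n), ncol = 3)
  }
  tr <- micro_traj(P, u = u, dt = dt)
  raf <- head_vector_raf(tr, assign_leaflets(tr), window = c(0, 10))
  expect_equal(raf$raf, cos(w_ang * raf$lag), tolerance = 1e-10)
  expect_equal(raf$raf[1], 1) # RAF(0) exactly 1
})

test_that("RAF with origin stride 1 equals the brute-force all-origin average", {
  spec <- small_spec(n_lipids_per_leaflet = 5, bridge_count = 0, n_frames = 50,
                     n_waters = 0, hydration_count = 0, n_na = 0, n_cl = 0)
  tr <- generate_bilayer(spec)
  lf <- assign_leaflets(tr)
  raf <- head_vector_raf(tr, lf, window = c(0, 10))

  # brute force: unit P->N vectors, all origins, all lipids
  lip <- tr$topology$lipids
  nfr <- dim(tr$coords)[3]
  U <- array(NA_real_, c(nrow(lip), 3, nfr))
  for (f in seq_len(nfr)) {
    v <- tr$coords[lip$choline_n, , f] - tr$coords[lip$head, , f]
    U[, , f] <- v / sqrt(rowSums(v^2))
  }
  max_lag <- floor(nfr / 2)
  n_orig <- nfr - max_lag
  brute <- sapply(0:max_lag, function(l) {
    acc <- 0
    for (o in seq_len(n_orig)) {
      acc <- acc + mean(rowSums(U[, , o] * U[, , o + l]))
    }
    acc / n_orig
  })
  expect_equal(raf$raf, brute, tolerance = 1e-12)
  expect_true(all(raf$n_origins == n_orig))
})

test_that("free rotational diffusion decays as exp(-2 D_r t)", {
  spec <- small_spec(
    n_lipids_per_leaflet = 48, bridge_count = 0, n_frames = 400,
    n_waters = 0, hydration_count = 0, n_na = 0, n_cl = 0,
    tilt_mean_deg = NULL, D_r = 1, seed = 7
  )
  tr <- generate_bilayer(spec)
  raf <- head_vector_raf(tr, assign_leaflets(tr), window = c(0, 10))
  expect_lt(max(abs(raf$raf - exp(-2 * raf$lag))), 0.08)
  fit <- kww_fit(raf)
  expect_equal(fit$tau, 0.5, tolerance = 0.15)
  expect_equal(fit$beta, 1, tolerance = 0.15)
})

test_that("KWW linearized fitting recovers noiseless (tau, beta) within 1 percent", {
  lags <- seq(0, 300, by = 0.05)
  for (tau in c(1, 10, 100)) {
    for (beta in c(0.5, 0.7, 1.0)) {
      curve <- generate_kww_curve(tau, beta, lags)
      fit <- kww_fit(curve)
      expect_equal(fit$tau, tau, tolerance = 0.01)
      expect_equal(fit$beta, beta, tolerance = 0.01)
      expect_true(fit$converged)
    }
  }
  # beta = 1 linearization is exact
  fit1 <- kww_fit(generate_kww_curve(10, 1, seq(0, 60, by = 0.1)))
  expect_equal(fit1$tau, 10, tolerance = 1e-8)
  expect_equal(fit1$beta, 1, tolerance = 1e-8)
})

test_that("KWW fit reports non-convergence when the RAF never decays into the fit window", {
  raf <- tibble::tibble(lag = seq(0, 1, by = 0.01), raf = rep(1, 101))
  fit <- kww_fit(raf)
  expect_false(fit$converged)
  expect_true(is.na(fit$tau))
})

test_that("tilt angles against the outward normal: analytic limits and recovery", {
  # all vectors along the outward normal -> 0 deg
  tr0 <- flat_bilayer(n_per_leaflet = 4)
  lf0 <- assign_leaflets(tr0)
  t0 <- tilt_statistics(tr0, lf0, window = c(0, 1))
  expect_equal(attr(t0, "mean"), 0)
  expect_equal(attr(t0, "sd"), 0)

  # all vectors in-plane -> 90 deg
  n <- 6
  P <- array(cbind(1:n * 6, 6, rep(c(18, -18), each = 3)), c(n, 3, 1))
  u_flat <- array(rep(c(1, 0, 0), each = n), c(n, 3, 1))
  tr90 <- micro_traj(P, u = u_flat)
  t90 <- tilt_statistics(tr90, assign_leaflets(tr90), window = c(0, 1))
  expect_equal(attr(t90, "mean"), 90)
  expect_equal(attr(t90, "sd"), 0)

  # generator tilt distribution is recovered: the analysis reproduces the
  # realized truth essentially exactly, and the realized truth sits near the
  # requested (75, 25) distribution
  spec <- small_spec(n_frames = 150, tilt_mean_deg = 75, tilt_sd_deg = 25, seed = 11)
  tr <- generate_bilayer(spec)
  gt <- ground_truth_report(spec, tr, frames = 1)
  tl <- tilt_statistics(tr, assign_leaflets(tr), window = c(0, 10))
  expect_equal(attr(tl, "mean"), gt$tilt$tilt_mean_deg, tolerance = 1e-9)
  expect_equal(attr(tl, "sd"), gt$tilt$tilt_sd_deg, tolerance = 1e-6)
  expect_equal(attr(tl, "mean"), 75, tolerance = 3)
  expect_equal(attr(tl, "sd"), 25, tolerance = 3)
})

test_that("MSD: static, ballistic and Brownian limits", {
  # static lipids -> MSD identically zero (covered in frozen test); drift:
  n <- 8
  F <- 60
  dt <- 0.005
  v <- 20 # A/ns drift along x
  P <- array(NA_real_, c(n, 3, F))
  base <- cbind(1:n * 6, 10, rep(c(15, -15), each = 4))
  for (f in seq_len(F)) {
    P[, , f] <- base + cbind(rep(v * (f - 1) * dt, n), 0, 0)
  }
  tr <- micro_traj(P, dt = dt, box = c(400, 60, 90))
  msd <- msd_lateral(tr, assign_leaflets(tr), window = c(0, 10))
  expect_equal(msd$msd, (v * msd$lag)^2, tolerance = 1e-6)
  fit <- diffusion_fit(msd)
  expect_true(fit$nonlinear) # ballistic flagged

  # Brownian motion: D recovered within 10 percent
  spec <- small_spec(
    n_lipids_per_leaflet = 48, bridge_count = 0, n_frames = 400,
    n_waters = 0, hydration_count = 0, n_na = 0, n_cl = 0,
    scd_sn1 = 0.2, scd_sn2 = c(0.2, 0.2, 0.2),
    D_lateral = 0.675, seed = 3
  )
  tr2 <- generate_bilayer(spec)
  msd2 <- msd_lateral(tr2, assign_leaflets(tr2), window = c(0, 10))
  fit2 <- diffusion_fit(msd2)
  expect_equal(fit2$D_A2_ns, 0.675, tolerance = 0.10)
  expect_false(fit2$negative_slope)
})

test_that("multi-origin MSD equals a brute-force double loop and survives re-wrapping", {
  spec <- small_spec(
    n_lipids_per_leaflet = 4, bridge_count = 0, n_frames = 40,
    n_waters = 0, hydration_count = 0, n_na = 0, n_cl = 0,
    scd_sn1 = 0.2, scd_sn2 = c(0.2, 0.2, 0.2), D_lateral = 2, seed = 9,
    box_fluct_sd = 0
  )
  tr <- generate_bilayer(spec)
  lf <- assign_leaflets(tr)
  msd <- msd_lateral(tr, lf, window = c(0, 10))

  com <- bilayr:::lipid_com_xy_unwrapped(tr, seq_len(40))
  nfr <- 40
  max_lag <- nrow(msd) - 1
  brute <- sapply(seq_len(max_lag), function(l) {
    acc <- c()
    for (o in seq_len(nfr - l)) {
      acc <- c(acc, (com$x[o + l, ] - com$x[o, ])^2 + (com$y[o + l, ] - com$y[o, ])^2)
    }
    mean(acc)
  })
  expect_equal(msd$msd[-1], brute, tolerance = 1e-12)

  # globally re-wrapping all coordinates must not change the MSD
  tr_wrap <- tr
  for (ax in 1:2) {
    L <- tr$box[1, ax] # constant box in this spec
    shifted <- tr$coords[, ax, ] + 0.37 * L
    tr_wrap$coords[, ax, ] <- shifted - L * floor(shifted / L)
  }
  msd_wrap <- msd_lateral(tr_wrap, lf, window = c(0, 10))
  expect_equal(msd_wrap$msd, msd$msd, tolerance = 1e-9)
})

test_that("diffusion fitting converts units correctly and flags pathologies", {
  lags <- seq(0, 2, by = 0.01)
  msd_lin <- tibble::tibble(lag = lags, msd = 4 * 0.9 * lags)
  class(msd_lin) <- c("bl_msd", class(msd_lin))
  fit <- diffusion_fit(msd_lin)
  expect_equal(fit$D_A2_ns, 0.9, tolerance = 1e-12)
  expect_equal(fit$D_cm2_s, 9.00e-8, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$nonlinear)

  msd_neg <- tibble::tibble(lag = lags, msd = 10 - 2 * lags)
  expect_warning(fit_neg <- diffusion_fit(msd_neg), "negative")
  expect_lt(fit_neg$D_A2_ns, 0)
  expect_true(fit_neg$negative_slope)

  expect_error(diffusion_fit(msd_lin[1:2, ]), "fewer than 3 lags")
})

test_that("D recovery is unbiased (<3%) with seed scatter <10% across 20 seeds", {
  ds <- vapply(1:20, function(seed) {
    spec <- small_spec(
      n_lipids_per_leaflet = 48, bridge_count = 0, n_frames = 500,
      n_waters = 0, hydration_count = 0, n_na = 0, n_cl = 0,
      scd_sn1 = 0.2, scd_sn2 = c(0.2, 0.2, 0.2),
      D_lateral = 0.9, seed = seed
    )
    tr <- generate_bilayer(spec)
    msd <- msd_lateral(tr, assign_leaflets(tr))
    diffusion_fit(msd)$D_A2_ns
  }, numeric(1))
  expect_lt(abs(mean(ds) / 0.9 - 1), 0.03)
  expect_lt(sd(ds) / 0.9, 0.10)
})

test_that("coincident headgroup and choline atoms are rejected", {
  n <- 4
  P <- array(cbind(1:n * 6, 5, c(20, 20, -20, -20)), c(n, 3, 2))
  u0 <- array(0, c(n, 3, 2)) # zero-length P->N vectors
  tr <- micro_traj(P, u = u0)
  lf <- structure(list(upper = 1:2, lower = 3:4, reference_frame = 1L),
    class = "bl_leaflets"
  )
  expect_error(head_vector_raf(tr, lf, window = c(0, 1)), "zero-length")
  expect_error(tilt_statistics(tr, lf, window = c(0, 1)), "zero-length")
})
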