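test_that("unwrapping restores continuous coordinates and flags jumps", {
  # a trajectory that never crosses a face is unchanged
  L <- 10
  pos <- lapply(0:4, function(k) matrix(c(2 + 0.1 * k, 5, 5), 1, 3))
  traj <- traj_from_frames(pos, "O", L, dt = 0.01)
  expect_equal(unwrap_trajectory(traj)$coords, traj$coords)

  # a face crossing is reconnected; the Brownian generator's stored
  # unwrapped record is the oracle
  tb <- brownian_com_trajectory(16, 8, D_true = 0.5, dt = 0.05,
                                n_frames = 300, seed = 51)
  unw <- unwrap_trajectory(tb)
  truth <- tb$meta$unwrapped
  # unwrapping reconstructs displacements, not absolute offsets: compare
  # displacement fields
  expect_equal(unw$coords[300, , ] - unw$coords[1, , ],
               truth[300, , ] - truth[1, , ], tolerance = 1e-9)
  expect_gt(max(abs(truth[300, , ] - truth[1, , ])), 8 / 2) # walks far

  # a synthetic jump of 0.6 L raises an error naming frame and atom
  pos_jump <- list(matrix(c(1, 1, 1), 1, 3), matrix(c(1 + 0.6 * L, 1, 1), 1, 3))
  tj <- traj_from_frames(pos_jump, "O", L)
  expect_error(unwrap_trajectory(tj, max_jump = 0.3 * L), "atom 1")
})

test_that("MSD reproduces stationary, ballistic, and Brownian motion", {
  # stationary -> identically zero
  still <- traj_from_frames(rep(list(matrix(c(1, 2, 3), 1, 3)), 6), "O", 20,
                            dt = 0.1)
  expect_equal(compute_msd(still)$data$msd, rep(0, 4))

  # linear motion r = v t -> MSD = |v|^2 t^2 exactly
  v <- c(0.3, -0.2, 0.1)
  pos <- lapply(0:19, function(k) matrix(c(5, 5, 5) + v * k * 0.1, 1, 3))
  lin <- traj_from_frames(pos, "O", 1e6, dt = 0.1)
  msd <- compute_msd(lin)
  expect_equal(msd$data$msd, sum(v^2) * msd$data$time^2, tolerance = 1e-9)

  expect_error(compute_msd(traj_from_frames(pos[1], "O", 20)), "2 frames")

  # Brownian ensemble: slope/6 recovers D (quick check; the full-size
  # recovery lives in the acceptance suite). The fit window sits at small
  # lags, where time origins are dense and the MSD estimator is tight.
  tb <- brownian_com_trajectory(64, 12.445, 0.23, 0.01, 800, seed = 53)
  fit <- fit_diffusion(compute_msd(unwrap_trajectory(tb), max_lag = 250),
                       fit_window = c(0.5, 2.0))
  expect_lt(abs(fit$D_L - 0.23) / 0.23, 0.1)
})

test_that("multi-origin MSD equals the naive double-loop oracle", {
  tb <- brownian_com_trajectory(3, 10, 0.4, 0.05, 10, seed = 55)
  unw <- unwrap_trajectory(tb)
  fft_msd <- compute_msd(unw, max_lag = 9)$data$msd
  dir_msd <- compute_msd(unw, max_lag = 9, method = "direct")$data$msd

  # oracle: explicit loops over origins, lags, atoms (oxygen entities)
  o_idx <- which(unw$elements == "O")
  X <- unw$coords[, o_idx, , drop = FALSE]
  oracle <- numeric(10)
  for (k in 0:9) {
    tot <- 0; cnt <- 0
    for (t0 in seq_len(10 - k)) {
      for (i in seq_along(o_idx)) {
        tot <- tot + sum((X[t0 + k, i, ] - X[t0, i, ])^2)
        cnt <- cnt + 1
      }
    }
    oracle[k + 1] <- tot / cnt
  }
  expect_equal(fft_msd, oracle, tolerance = 1e-10)
  expect_equal(dir_msd, oracle, tolerance = 1e-10)

  # origin strides subsample origins
  st <- compute_msd(unw, max_lag = 4, origin_stride = 3, method = "direct")
  expect_equal(st$data$n_origins[2], length(seq(1, 9, by = 3)))
})

test_that("diffusion fits recover exact slopes and validate windows", {
  lags <- 0:100
  msd <- structure(
    list(data = tibble::tibble(lag = lags, time = lags * 0.1,
                               msd = 6 * 0.2 * lags * 0.1,
                               n_origins = 101 - lags),
         dt = 0.1, atoms = "oxygen", n_entities = 1L),
    class = "aq_msd")
  fit <- fit_diffusion(msd)
  expect_equal(fit$D_L, 0.2, tolerance = 1e-12)
  expect_equal(fit$D_L_1e9m2s, 2.0, tolerance = 1e-12)
  expect_lt(fit$D_L_se, 1e-12)
  expect_error(fit_diffusion(msd, fit_window = c(4.99, 5.01)), "fewer than 3")
})

test_that("the finite-size correction is exact, monotone, and invertible", {
  # arithmetic oracle: independent unit conversion of xi kB T/(6 pi eta L)
  T_ <- 300; L <- 12.445; eta <- 0.896e-3
  term_oracle_m2s <- 2.837297 * 1.380649e-23 * T_ /
    (6 * pi * eta * L * 1e-10)                    # m^2/s
  term_oracle_A2ps <- term_oracle_m2s / 1e-8      # 1 A^2/ps = 1e-8 m^2/s
  expect_equal(diffusion_correction_term(T_, L, eta), term_oracle_A2ps,
               tolerance = 1e-6)

  D <- 0.2
  expect_equal(finite_size_correct(D, T_, L, eta), D + term_oracle_A2ps,
               tolerance = 1e-6)
  # round trip is the identity
  expect_equal(rescale_exp_to_box(finite_size_correct(D, T_, L, eta),
                                  T_, L, eta), D, tolerance = 1e-12)
  # eta -> infinity kills the correction
  expect_lt(finite_size_correct(D, T_, L, 1e9) - D, 1e-10)
  # monotone: increasing in T, decreasing in L and eta
  expect_gt(finite_size_correct(D, 320, L, eta),
            finite_size_correct(D, 300, L, eta))
  expect_lt(finite_size_correct(D, T_, 2 * L, eta),
            finite_size_correct(D, T_, L, eta))
  expect_lt(finite_size_correct(D, T_, L, 2 * eta),
            finite_size_correct(D, T_, L, eta))
  expect_error(finite_size_correct(D, T_, L, -1), "viscosity")
})

test_that("Ewald summation reproduces the cubic-lattice constant", {
  xi <- ewald_self_constant()
  expect_equal(xi, 2.837297, tolerance = 1e-6)
  # converged result is independent of the splitting parameter
  expect_equal(ewald_self_constant(alpha = 1.5, n_real = 8, n_recip = 8),
               ewald_self_constant(alpha = 2.5, n_real = 8, n_recip = 8),
               tolerance = 1e-9)
})

test_that("orientational ACFs start at 1 and decay as rotational diffusion", {
  tr <- rotor_trajectory(32, D_r = 0.08, dt = 0.02, n_frames = 800, seed = 57)
  top <- assign_water_topology(get_frame(tr, 1))
  for (ax in c("OH", "HH", "dipole")) {
    acf <- orientational_acf(tr, top, ax, order = 2, max_lag = 10)
    expect_equal(acf$data$C[1], 1, tolerance = 1e-12)
    expect_true(all(abs(acf$data$C) <= 1 + 1e-12))
  }
  expect_error(orientational_acf(tr, top, "OH", order = 3), "order")

  # C_2(t) tracks exp(-6 D_r t) for isotropic rotational diffusion
  acf2 <- orientational_acf(tr, top, "OH", 2, max_lag = 150)
  theo <- exp(-6 * 0.08 * acf2$data$time)
  expect_lt(max(abs(acf2$data$C - theo)[theo > 0.2]), 0.08)

  # direct loop and FFT implementations agree to round-off
  for (n in 1:2) {
    a_f <- orientational_acf(tr, top, "dipole", n, max_lag = 40,
                             method = "fft")
    a_d <- orientational_acf(tr, top, "dipole", n, max_lag = 40,
                             method = "direct")
    expect_equal(a_f$data$C, a_d$data$C, tolerance = 1e-10)
  }
})

test_that("ACFs and MSDs respect rigid-motion invariances", {
  tr <- rotor_trajectory(8, 0.1, 0.02, 60, seed = 59)
  top <- assign_water_topology(get_frame(tr, 1))
  ref <- orientational_acf(tr, top, "OH", 2, max_lag = 20)

  # rigid translation of every frame
  shifted <- tr
  shifted$coords <- tr$coords + 0.777
  expect_equal(orientational_acf(shifted, top, "OH", 2, max_lag = 20)$data$C,
               ref$data$C, tolerance = 1e-12)

  # one global rotation applied to all frames
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- tr
  for (k in seq_len(n_frames(tr))) rot$coords[k, , ] <- tr$coords[k, , ] %*% t(R)
  expect_equal(orientational_acf(rot, top, "OH", 2, max_lag = 20)$data$C,
               ref$data$C, tolerance = 1e-10)

  # MSD under rigid translation
  tb <- brownian_com_trajectory(4, 10, 0.2, 0.05, 40, seed = 61)
  unw <- unwrap_trajectory(tb)
  sh <- unw; sh$coords <- unw$coords + 3.21
  expect_equal(compute_msd(sh)$data$msd, compute_msd(unw)$data$msd,
               tolerance = 1e-10)
})

test_that("exponential relaxation times are recovered from clean ACFs", {
  a1 <- synthetic_acf(function(t) exp(-t / 2), dt = 0.05, t_max = 8)
  f1 <- fit_relaxation_time(a1, fit_start = 0)
  expect_equal(f1$tau, 2, tolerance = 1e-9)
  expect_equal(f1$A, 1, tolerance = 1e-9)

  a2 <- synthetic_acf(function(t) 0.9 * exp(-t / 3), dt = 0.05, t_max = 10)
  f2 <- suppressWarnings(fit_relaxation_time(a2, fit_start = 0))
  expect_equal(f2$tau, 3, tolerance = 1e-9)
  expect_equal(f2$A, 0.9, tolerance = 1e-9)
  # 10 ps for tau = 3: close to the 3-tau guideline; nonlinear refinement
  # agrees on clean data
  f2n <- suppressWarnings(fit_relaxation_time(a2, fit_start = 0,
                                              nonlinear = TRUE))
  expect_equal(f2n$tau, 3, tolerance = 1e-6)

  # non-positive C throughout the window
  a3 <- synthetic_acf(function(t) -0.1 + 0 * t, dt = 0.05, t_max = 5)
  expect_error(fit_relaxation_time(a3, fit_start = 0, fit_end = 5),
               "non-positive")

  # trajectories shorter than ~3 tau are flagged
  a4 <- synthetic_acf(function(t) exp(-t / 10), dt = 0.05, t_max = 6)
  expect_warning(f4 <- fit_relaxation_time(a4, fit_start = 0), "unreliable")
  expect_true(f4$short_trajectory)
})

test_that("rotor relaxation times and their ratio obey the n(n+1) law", {
  # the log-space fit stops at C = 0.2, before the statistical noise floor
  # that log-scaling would otherwise amplify
  D_r <- 0.05
  tr <- rotor_trajectory(64, D_r, dt = 0.02, n_frames = 2000, seed = 63)
  top <- assign_water_topology(get_frame(tr, 1))
  acf2 <- orientational_acf(tr, top, "OH", 2)
  f2 <- fit_relaxation_time(acf2, fit_start = 0.2, floor_C = 0.2)
  expect_lt(abs(f2$tau - 1 / (6 * D_r)) / (1 / (6 * D_r)), 0.10)

  acf1 <- orientational_acf(tr, top, "OH", 1, max_lag = 1800)
  f1 <- fit_relaxation_time(acf1, fit_start = 0.2, floor_C = 0.2)
  expect_lt(abs(f1$tau / f2$tau - 3), 0.5)
})
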