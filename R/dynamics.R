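# Translational and rotational dynamics: Einstein-relation self-diffusion
# from multi-origin mean-squared displacements, the hydrodynamic finite-size
# correction for cubic boxes, and orientational relaxation times from
# Legendre autocorrelation functions.

#' Unwrap a trajectory across periodic boundaries
#'
#' Reconstructs continuous per-atom coordinates by accumulating minimum-image
#' displacements between consecutive frames. Valid as long as no atom moves
#' half a box edge or more between saved frames. Displacements whose
#' components exceed `max_jump` are treated as errors (a genuinely wrapped
#' crossing produces a small minimum-image displacement; a large one signals
#' corrupt or undersampled data).
#'
#' @param traj an [aq_trajectory()] with wrapped coordinates.
#' @param max_jump maximal plausible per-component displacement between
#'   consecutive frames (Angstrom); defaults to L/4.
#' @return an [aq_trajectory()] with continuous coordinates
#'   (`meta$unwrapped_from` records the provenance).
#' @export
unwrap_trajectory <- function(traj, max_jump = NULL) {
  stopifnot(inherits(traj, "aq_traj"))
  L <- traj$box
  if (is.null(max_jump)) max_jump <- L / 4
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  out <- traj$coords
  if (nf >= 2L) {
    for (k in 2:nf) {
      disp <- minimum_image(matrix(traj$coords[k, , ], na, 3) -
                              matrix(traj$coords[k - 1L, , ], na, 3), L)
      bad <- which(abs(disp) > max_jump, arr.ind = TRUE)
      if (nrow(bad) > 0L)
        stop("jump of ", format(max(abs(disp)), digits = 4),
             " A (> max_jump = ", format(max_jump, digits = 4),
             " A) between frames ", k - 1L, " and ", k, " for atom ",
             bad[1, 1])
      out[k, , ] <- out[k - 1L, , ] + disp
    }
  }
  res <- traj
  res$coords <- out
  res$meta$unwrapped_from <- "minimum-image continuity"
  res
}

# sum over columns of the autocorrelation S[k] = sum_t X[t, ] * X[t + k, ],
# k = 0..max_lag, computed with FFTs.
autocorr_colsum <- function(X, max_lag) {
  T_ <- nrow(X)
  nfft <- stats::nextn(2L * T_, 2)
  Xp <- rbind(X, matrix(0, nfft - T_, ncol(X)))
  F_ <- mvfft(Xp)
  S <- Re(mvfft(F_ * Conj(F_), inverse = TRUE))[seq_len(max_lag + 1L), ,
                                                drop = FALSE] / nfft
  rowSums(S)
}

#' Mean-squared displacement with multiple time origins
#'
#' Computes `MSD(t) = (1/N) sum_i < |r_i(t0 + t) - r_i(t0)|^2 >` over time
#' origins t0, by default using the oxygen positions of an unwrapped
#' trajectory. With `origin_stride = 1` every origin is used and the average
#' is evaluated exactly with an FFT-based algorithm; larger strides fall back
#' to the direct sum.
#'
#' @param traj an unwrapped [aq_trajectory()] (see [unwrap_trajectory()]).
#' @param topology an [aq_topology()]; required for `atoms = "com"`.
#' @param atoms `"oxygen"` (default), `"com"` (molecular centres of mass), or
#'   `"all"`.
#' @param max_lag maximal lag in frames; defaults to half the trajectory.
#' @param origin_stride spacing between time origins in frames (default 1).
#' @param method `"auto"` (FFT when the stride is 1), `"fft"`, or `"direct"`.
#' @return an object of class `aq_msd`: a `data` tibble with `lag` (frames),
#'   `time` (ps), `msd` (Angstrom^2) and `n_origins`.
#' @export
compute_msd <- function(traj, topology = NULL, atoms = c("oxygen", "com", "all"),
                        max_lag = NULL, origin_stride = 1L,
                        method = c("auto", "fft", "direct")) {
  stopifnot(inherits(traj, "aq_traj"))
  atoms <- match.arg(atoms)
  method <- match.arg(method)
  T_ <- n_frames(traj)
  if (T_ < 2L) stop("trajectory must have at least 2 frames")
  if (is.null(max_lag)) max_lag <- floor(T_ / 2)
  max_lag <- min(max_lag, T_ - 1L)
  if (method == "auto") method <- if (origin_stride == 1L) "fft" else "direct"
  if (method == "fft" && origin_stride != 1L)
    stop("the FFT path requires origin_stride = 1")

  if (atoms == "oxygen") {
    sel <- which(traj$elements == "O")
    X <- matrix(traj$coords[, sel, ], T_, length(sel) * 3L)
    n_entities <- length(sel)
  } else if (atoms == "all") {
    X <- matrix(traj$coords, T_, n_atoms(traj) * 3L)
    n_entities <- n_atoms(traj)
  } else {
    if (is.null(topology)) stop("`topology` is required for atoms = 'com'")
    mol <- topology$molecules
    m <- c(aq_constants$mass_O, topology$mass_h, topology$mass_h)
    nm <- nrow(mol)
    X <- matrix(0, T_, nm * 3L)
    for (i in seq_len(nm)) {
      at <- mol[i, ]
      com <- (m[1] * traj$coords[, at[1], ] + m[2] * traj$coords[, at[2], ] +
                m[3] * traj$coords[, at[3], ]) / sum(m)
      X[, (i - 1L) * 3L + 1:3] <- com
    }
    n_entities <- nm
  }

  lags <- 0:max_lag
  if (method == "fft") {
    S2 <- autocorr_colsum(X, max_lag)
    D <- rowSums(X * X)
    Q <- numeric(max_lag + 1L)
    Q[1] <- 2 * sum(D)
    for (k in seq_len(max_lag)) Q[k + 1L] <- Q[k] - D[k] - D[T_ + 1L - k]
    msd <- (Q - 2 * S2) / (T_ - lags) / n_entities
    msd[1] <- 0
    n_origins <- T_ - lags
  } else {
    msd <- numeric(max_lag + 1L)
    n_origins <- integer(max_lag + 1L)
    n_origins[1] <- length(seq.int(1L, T_, by = origin_stride))
    for (k in seq_len(max_lag)) {
      org <- seq.int(1L, T_ - k, by = origin_stride)
      dd <- X[org + k, , drop = FALSE] - X[org, , drop = FALSE]
      msd[k + 1L] <- sum(dd * dd) / length(org) / n_entities
      n_origins[k + 1L] <- length(org)
    }
  }
  dt <- traj$dt
  structure(
    list(data = tibble::tibble(lag = lags,
                               time = if (is.finite(dt)) lags * dt else lags,
                               msd = msd, n_origins = n_origins),
         dt = dt, atoms = atoms, n_entities = n_entities),
    class = "aq_msd"
  )
}

#' @export
print.aq_msd <- function(x, ...) {
  cat("<aq_msd> ", nrow(x$data) - 1L, " lags over ", x$n_entities, " ",
      x$atoms, " entities\n", sep = "")
  invisible(x)
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Unweighted least squares of `MSD = 6 D t + b` on a lag-time window
#' (default the central 25--75% of the available lags), per the Einstein
#' relation in three dimensions.
#'
#' @param msd an `aq_msd` with time in ps.
#' @param fit_window numeric length-2 window of lag times (ps); default
#'   `c(0.25, 0.75) * max(time)`.
#' @param temperature,box_edge,viscosity if all given (K, Angstrom, Pa s),
#'   the finite-size-corrected `D_inf` is attached via
#'   [finite_size_correct()].
#' @return an object of class `aq_diffusion` with `D_L` (Angstrom^2/ps),
#'   `D_L_1e9m2s` (1e-9 m^2/s), the standard error, the window, and
#'   optionally `D_inf`.
#' @export
fit_diffusion <- function(msd, fit_window = NULL, temperature = NA_real_,
                          box_edge = NA_real_, viscosity = NA_real_) {
  stopifnot(inherits(msd, "aq_msd"))
  d <- msd$data
  if (is.null(fit_window)) fit_window <- c(0.25, 0.75) * max(d$time)
  sel <- d$time >= fit_window[1] & d$time <= fit_window[2] & d$lag > 0
  if (sum(sel) < 3L)
    stop("fewer than 3 MSD points in the fit window [",
         paste(format(fit_window, digits = 4), collapse = ", "), "] ps")
  fit <- lm(msd ~ time, data = d[sel, ])
  slope <- coef(fit)[["time"]]
  # suppress the "essentially perfect fit" note on exact synthetic lines
  se <- suppressWarnings(summary(fit)$coefficients["time", "Std. Error"])
  D_L <- slope / 6
  D_inf <- NA_real_
  if (is.finite(temperature) && is.finite(box_edge) && is.finite(viscosity))
    D_inf <- finite_size_correct(D_L, temperature, box_edge, viscosity)
  structure(
    list(D_L = D_L, D_L_se = se / 6,
         D_L_1e9m2s = D_L * aq_constants$A2ps_to_1e9m2s,
         D_inf = D_inf,
         D_inf_1e9m2s = D_inf * aq_constants$A2ps_to_1e9m2s,
         fit_window = fit_window, n_points = sum(sel),
         temperature = temperature, box_edge = box_edge,
         viscosity = viscosity),
    class = "aq_diffusion"
  )
}

#' @export
print.aq_diffusion <- function(x, ...) {
  cat("<aq_diffusion> D_L = ", format(x$D_L, digits = 4), " A^2/ps (",
      format(x$D_L_1e9m2s, digits = 4), " x 1e-9 m^2/s)", sep = "")
  if (is.finite(x$D_inf))
    cat("; D_inf = ", format(x$D_inf, digits = 4), " A^2/ps", sep = "")
  cat("\n")
  invisible(x)
}

#' Hydrodynamic finite-size correction term for a cubic box
#'
#' The correction `xi k_B T / (6 pi eta L)` removes the periodic hydrodynamic
#' self-interaction from a diffusion coefficient measured in a cubic box of
#' edge L; `xi = 2.837297` is the cubic-lattice self-interaction constant
#' (see [ewald_self_constant()]).
#'
#' @param temperature temperature in K (> 0).
#' @param box_edge box edge L in Angstrom (> 0).
#' @param viscosity shear viscosity in Pa s (> 0).
#' @param xi dimensionless lattice constant.
#' @return the correction term in Angstrom^2/ps.
#' @examples
#' diffusion_correction_term(300, 12.445, 0.896e-3)
#' @export
diffusion_correction_term <- function(temperature, box_edge, viscosity,
                                      xi = aq_constants$xi_cubic) {
  if (!is.finite(viscosity) || viscosity <= 0)
    stop("`viscosity` must be positive (Pa s)")
  if (temperature <= 0) stop("`temperature` must be positive (K)")
  if (box_edge <= 0) stop("`box_edge` must be positive (Angstrom)")
  term_si <- xi * aq_constants$k_boltzmann * temperature /
    (6 * pi * viscosity * box_edge * 1e-10)          # m^2/s
  term_si * 1e20 * 1e-12                              # -> A^2/ps
}

#' Finite-size correction of a diffusion coefficient
#'
#' `finite_size_correct()` maps a box-size-limited coefficient `D_L` to the
#' infinite-size limit `D_inf = D_L + xi k_B T / (6 pi eta L)`;
#' `rescale_exp_to_box()` is the exact inverse, mapping an experimental
#' infinite-size coefficient back to the hypothetical value for a box of
#' edge L. Both take and return Angstrom^2/ps (multiply by 10 for
#' 1e-9 m^2/s).
#'
#' @param D diffusion coefficient in Angstrom^2/ps (`D_L` for the forward
#'   map, `D_inf` for the inverse).
#' @inheritParams diffusion_correction_term
#' @return corrected coefficient in Angstrom^2/ps.
#' @export
finite_size_correct <- function(D, temperature, box_edge, viscosity,
                                xi = aq_constants$xi_cubic) {
  D + diffusion_correction_term(temperature, box_edge, viscosity, xi)
}

#' @rdname finite_size_correct
#' @export
rescale_exp_to_box <- function(D, temperature, box_edge, viscosity,
                               xi = aq_constants$xi_cubic) {
  D - diffusion_correction_term(temperature, box_edge, viscosity, xi)
}

#' Cubic-lattice self-interaction constant by Ewald summation
#'
#' Recomputes from scratch the dimensionless constant `xi = 2.837297` of the
#' finite-size diffusion correction: (minus) the self-energy of a unit point
#' charge in a periodic cubic cell of unit edge with a neutralising uniform
#' background, evaluated by Ewald summation
#' `xi = -[ sum_n' erfc(a|n|)/|n| + (4 pi / k^2) sum_k' e^(-k^2/4a^2)
#' - 2a/sqrt(pi) - pi/a^2 ]`.
#' The result is independent of the splitting parameter `alpha` once both
#' sums are converged.
#'
#' @param alpha Ewald splitting parameter (1/length, for unit cell edge).
#' @param n_real real-space image cutoff (sum over `|n_i| <= n_real`).
#' @param n_recip reciprocal-space cutoff (sum over `|m_i| <= n_recip`).
#' @return the constant (about 2.837297).
#' @examples
#' ewald_self_constant()
#' @export
ewald_self_constant <- function(alpha = 2, n_real = 6L, n_recip = 6L) {
  erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
  idx <- as.matrix(expand.grid(-n_real:n_real, -n_real:n_real,
                               -n_real:n_real))
  nn <- sqrt(rowSums(idx^2))
  nn <- nn[nn > 0]
  real_sum <- sum(erfc(alpha * nn) / nn)
  midx <- as.matrix(expand.grid(-n_recip:n_recip, -n_recip:n_recip,
                                -n_recip:n_recip))
  k2 <- (2 * pi)^2 * rowSums(midx^2)
  k2 <- k2[k2 > 0]
  recip_sum <- sum(4 * pi / k2 * exp(-k2 / (4 * alpha^2)))
  -(real_sum + recip_sum - 2 * alpha / sqrt(pi) - pi / alpha^2)
}

# Unit molecular axis vectors for every frame: array T x M x 3, where M is
# the number of axis instances (2 per molecule for OH, 1 otherwise).
molecular_axes <- function(traj, topology, axis = c("OH", "HH", "dipole")) {
  axis <- match.arg(axis)
  mol <- topology$molecules
  nm <- nrow(mol)
  T_ <- n_frames(traj)
  L <- traj$box
  unitize <- function(v) v / sqrt(rowSums(v * v))
  M <- if (axis == "OH") 2L * nm else nm
  U <- array(0, c(T_, M, 3L))
  for (k in seq_len(T_)) {
    o <- matrix(traj$coords[k, mol[, 1], ], nm, 3)
    h1 <- matrix(traj$coords[k, mol[, 2], ], nm, 3)
    h2 <- matrix(traj$coords[k, mol[, 3], ], nm, 3)
    v1 <- minimum_image(h1 - o, L)
    v2 <- minimum_image(h2 - o, L)
    U[k, , ] <- switch(axis,
      OH = rbind(unitize(v1), unitize(v2)),
      HH = unitize(minimum_image(h2 - h1, L)),
      dipole = unitize(unitize(v1) + unitize(v2)))
  }
  U
}

#' Orientational autocorrelation function
#'
#' Computes `C_n(t) = < P_n( u_i(t0 + t) . u_i(t0) ) >` over molecules and
#' all time origins, where `P_1(x) = x`, `P_2(x) = (3 x^2 - 1)/2` and `u_i`
#' is a molecular unit axis: both OH covalent bonds pooled (`"OH"`), the
#' intramolecular H-H direction (`"HH"`), or the H-O-H bisector as the
#' geometric proxy for the dipole direction (`"dipole"`).
#'
#' The average over origins is evaluated exactly with FFT-based correlation
#' sums (for order 2 via the six independent components of the outer-product
#' tensor u u^T).
#'
#' @param traj an [aq_trajectory()] (wrapped is fine; intramolecular vectors
#'   use the minimum image).
#' @param topology an [aq_topology()].
#' @param axis `"OH"`, `"HH"`, or `"dipole"`.
#' @param order Legendre order, 1 or 2.
#' @param max_lag maximal lag in frames (default half the trajectory).
#' @param method `"fft"` (default) or `"direct"` (the loop oracle).
#' @return an object of class `aq_acf` with a `data` tibble
#'   (`lag`, `time`, `C`).
#' @export
orientational_acf <- function(traj, topology, axis = c("OH", "HH", "dipole"),
                              order = 2L, max_lag = NULL,
                              method = c("fft", "direct")) {
  stopifnot(inherits(traj, "aq_traj"), inherits(topology, "aq_topology"))
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2")
  T_ <- n_frames(traj)
  if (is.null(max_lag)) max_lag <- floor(T_ / 2)
  max_lag <- min(max_lag, T_ - 1L)
  U <- molecular_axes(traj, topology, axis)
  M <- dim(U)[2]
  lags <- 0:max_lag

  if (method == "fft") {
    if (order == 1L) {
      X <- matrix(U, T_, M * 3L)
      S <- autocorr_colsum(X, max_lag)
      C <- S / ((T_ - lags) * M)
    } else {
      W <- matrix(0, T_, M * 6L)
      s2 <- sqrt(2)
      for (j in seq_len(M)) {
        x <- U[, j, 1]; y <- U[, j, 2]; z <- U[, j, 3]
        W[, (j - 1L) * 6L + 1:6] <-
          cbind(x * x, y * y, z * z, s2 * x * y, s2 * x * z, s2 * y * z)
      }
      S <- autocorr_colsum(W, max_lag)
      mean_dot2 <- S / ((T_ - lags) * M)
      C <- (3 * mean_dot2 - 1) / 2
    }
  } else {
    C <- numeric(max_lag + 1L)
    C[1] <- 1
    for (k in seq_len(max_lag)) {
      dots <- U[seq_len(T_ - k), , 1] * U[(1L + k):T_, , 1] +
        U[seq_len(T_ - k), , 2] * U[(1L + k):T_, , 2] +
        U[seq_len(T_ - k), , 3] * U[(1L + k):T_, , 3]
      C[k + 1L] <- if (order == 1L) mean(dots) else mean((3 * dots^2 - 1) / 2)
    }
  }
  dt <- traj$dt
  structure(
    list(data = tibble::tibble(lag = lags,
                               time = if (is.finite(dt)) lags * dt else lags,
                               C = C),
         axis = axis, order = as.integer(order), n_vectors = M, dt = dt),
    class = "aq_acf"
  )
}

#' @export
print.aq_acf <- function(x, ...) {
  cat("<aq_acf> C_", x$order, "(t) along ", x$axis, " over ", x$n_vectors,
      " vectors, ", nrow(x$data) - 1L, " lags\n", sep = "")
  invisible(x)
}

#' Fit an exponential relaxation time to an orientational ACF
#'
#' Fits `A exp(-t / tau)` by least squares on `log C` over a window that by
#' default starts after the initial sub-picosecond (librational) decay at
#' `fit_start = 1 ps` and ends where C first drops below 0.05 (or at the end
#' of the data). Optionally refines with a nonlinear fit on the linear scale.
#'
#' A relaxation time can only be trusted when the trajectory is roughly
#' three times longer; shorter fits are flagged (`short_trajectory`) with a
#' warning.
#'
#' @param acf an `aq_acf`.
#' @param fit_start start of the fit window (ps).
#' @param fit_end end of the fit window (ps); default as described.
#' @param floor_C lower C bound defining the default `fit_end`.
#' @param nonlinear refine with `nls` after the log-linear fit.
#' @return an object of class `aq_relax` with `tau` (ps), `A`, the window,
#'   the fit residual (RMS on C), and the `short_trajectory` flag.
#' @export
fit_relaxation_time <- function(acf, fit_start = 1.0, fit_end = NULL,
                                floor_C = 0.05, nonlinear = FALSE) {
  stopifnot(inherits(acf, "aq_acf"))
  d <- acf$data
  if (is.null(fit_end)) {
    below <- which(d$C < floor_C & d$time > fit_start)
    fit_end <- if (length(below) > 0L) d$time[below[1]] else max(d$time)
  }
  sel <- d$time >= fit_start & d$time <= fit_end & d$C > 0
  if (sum(d$time >= fit_start & d$time <= fit_end) >= 3L && sum(sel) < 3L)
    stop("C(t) is non-positive throughout the fit window")
  if (sum(sel) < 3L)
    stop("fit window [", format(fit_start), ", ", format(fit_end),
         "] ps holds fewer than 3 usable points")
  dd <- d[sel, ]
  fit <- lm(log(C) ~ time, data = dd)
  tau <- -1 / coef(fit)[["time"]]
  A <- exp(coef(fit)[["(Intercept)"]])
  if (tau <= 0)
    stop("log-linear fit produced a non-positive relaxation time (C rising?)")
  if (nonlinear) {
    nl <- try(nls(C ~ A * exp(-time / tau), data = dd,
                  start = list(A = A, tau = tau)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      tau <- coef(nl)[["tau"]]
      A <- coef(nl)[["A"]]
    }
  }
  resid_rms <- sqrt(mean((dd$C - A * exp(-dd$time / tau))^2))
  short <- max(d$time) < 3 * tau
  if (short)
    warning("trajectory spans ", format(max(d$time), digits = 3),
            " ps, less than 3 x tau = ", format(3 * tau, digits = 3),
            " ps; the relaxation time is unreliable")
  structure(
    list(tau = tau, A = A, fit_window = c(fit_start, fit_end),
         residual = resid_rms, n_points = nrow(dd),
         short_trajectory = short, axis = acf$axis, order = acf$order),
    class = "aq_relax"
  )
}

#' @export
print.aq_relax <- function(x, ...) {
  cat("<aq_relax> tau_", x$order, " (", x$axis, ") = ",
      format(x$tau, digits = 4), " ps (A = ", format(x$A, digits = 3),
      ")\n", sep = "")
  invisible(x)
}
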