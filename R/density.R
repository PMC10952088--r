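# Equilibrium density from energy-versus-volume scans around trajectory
# snapshots. Intramolecular geometry is held fixed while molecular centres
# of mass are rescaled with the box; a pluggable energy backend supplies
# E(V) at each scaled configuration and the scan minimum is located on an
# interpolant.

#' Rescale molecular centres of mass with the box
#'
#' Returns a frame with box edge `scale * L` in which every molecule has been
#' rigidly translated so that its centre of mass maps to `scale * COM`;
#' intramolecular geometry is preserved bit-for-bit. Molecules are made whole
#' (minimum image around their oxygen) before the centre of mass is taken, so
#' the output frame carries whole molecules.
#'
#' @param frame an [aq_frame()].
#' @param topology an [aq_topology()].
#' @param scale box-edge scale factor (> 0); volume scales as `scale^3`.
#' @return an [aq_frame()].
#' @export
rescale_com_positions <- function(frame, topology, scale) {
  stopifnot(inherits(frame, "aq_frame"), inherits(topology, "aq_topology"))
  if (!is.numeric(scale) || scale <= 0) stop("`scale` must be positive")
  mol <- topology$molecules
  if (max(mol) > nrow(frame$positions))
    stop("topology indexes atoms beyond the frame")
  pos <- frame$positions
  L <- frame$box
  o <- pos[mol[, 1], , drop = FALSE]
  h1 <- o + minimum_image(pos[mol[, 2], , drop = FALSE] - o, L)
  h2 <- o + minimum_image(pos[mol[, 3], , drop = FALSE] - o, L)
  mO <- aq_constants$mass_O
  mH <- topology$mass_h
  com <- (mO * o + mH * h1 + mH * h2) / (mO + 2 * mH)
  shift <- (scale - 1) * com
  new <- pos
  new[mol[, 1], ] <- o + shift
  new[mol[, 2], ] <- h1 + shift
  new[mol[, 3], ] <- h2 + shift
  aq_frame(new, frame$elements, scale * L, time = frame$time)
}

#' Energy scan over box volumes around one snapshot
#'
#' Evaluates the energy backend at scaled copies of the snapshot (rigid
#' molecules, rescaled centres of mass) and locates the minimum of the
#' interpolated E(V): a cubic interpolant through the scan points for four or
#' more scales, the exact parabola vertex for three.
#'
#' @param frame an [aq_frame()].
#' @param topology an [aq_topology()].
#' @param backend a function `(frame, volume) -> energy` (arbitrary units);
#'   see [quadratic_EV_backend()].
#' @param scales box-edge scale factors; default 7 points spanning +-6% in
#'   volume.
#' @param vol_range half-range of the default volume scan (fractional).
#' @param n_points number of default scan points (>= 3).
#' @return an object of class `aq_volscan` with a `data` tibble
#'   (`scale`, `volume`, `energy`), the interpolated `v_eq` and `e_min`, and
#'   a `bracketed` flag. A minimum at the scan boundary triggers a
#'   "minimum not bracketed" warning.
#' @export
volume_scan <- function(frame, topology, backend, scales = NULL,
                        vol_range = 0.06, n_points = 7L) {
  stopifnot(inherits(frame, "aq_frame"), is.function(backend))
  if (is.null(scales)) {
    if (n_points < 3L) stop("at least 3 scan points are required")
    scales <- (1 + seq(-vol_range, vol_range, length.out = n_points))^(1 / 3)
  }
  scales <- sort(scales)
  if (length(scales) < 3L) stop("at least 3 scan points are required")
  vols <- (scales * frame$box)^3
  energies <- vapply(seq_along(scales), function(i) {
    sf <- rescale_com_positions(frame, topology, scales[i])
    as.numeric(backend(sf, vols[i]))
  }, numeric(1))
  if (any(!is.finite(energies)))
    stop("energy backend returned non-finite values")

  if (length(scales) == 3L) {
    fit <- lm(e ~ v + I(v^2), data = data.frame(v = vols, e = energies))
    a2 <- coef(fit)[["I(v^2)"]]
    v_eq <- if (a2 > 0) -coef(fit)[["v"]] / (2 * a2) else NA_real_
    if (!is.finite(v_eq) || v_eq < min(vols) || v_eq > max(vols)) {
      warning("minimum not bracketed by the volume scan")
      v_eq <- vols[which.min(energies)]
    }
    e_min <- unname(predict(fit, newdata = data.frame(v = v_eq)))
  } else {
    s <- splinefun(vols, energies, method = "fmm")
    opt <- optimize(s, range(vols), tol = .Machine$double.eps^0.5)
    v_eq <- opt$minimum
    e_min <- opt$objective
    span <- diff(range(vols))
    if (min(v_eq - min(vols), max(vols) - v_eq) < 1e-4 * span) {
      warning("minimum not bracketed by the volume scan")
      v_eq <- vols[which.min(energies)]
      e_min <- min(energies)
    } else {
      # refine on the spline's analytic derivative
      root <- try(uniroot(function(v) s(v, deriv = 1),
                          c(max(min(vols), v_eq - span / 4),
                            min(max(vols), v_eq + span / 4)),
                          tol = 1e-12)$root, silent = TRUE)
      if (!inherits(root, "try-error")) {
        v_eq <- root
        e_min <- s(v_eq)
      }
    }
  }
  structure(
    list(data = tibble::tibble(scale = scales, volume = vols,
                               energy = energies),
         v_eq = v_eq, e_min = e_min,
         bracketed = v_eq > min(vols) && v_eq < max(vols)),
    class = "aq_volscan"
  )
}

#' @export
print.aq_volscan <- function(x, ...) {
  cat("<aq_volscan> ", nrow(x$data), " points, V_eq = ",
      format(x$v_eq, digits = 6), " A^3",
      if (!x$bracketed) " (NOT bracketed)", "\n", sep = "")
  invisible(x)
}

#' Equilibrium density from snapshot volume scans
#'
#' Runs a volume scan around each of `n_snapshots` trajectory snapshots
#' separated by `snapshot_spacing` (defaults 30 snapshots, 0.2 ps) and
#' converts the snapshot-averaged equilibrium volume into a mass density
#' `rho = n_mol * M / (N_A * mean(V_eq))` in g/cm^3.
#'
#' @param traj an [aq_trajectory()] with known frame spacing.
#' @param topology an [aq_topology()]; assigned from the first snapshot when
#'   `NULL`.
#' @param backend energy backend `(frame, volume) -> energy`.
#' @param n_snapshots number of snapshots (default 30).
#' @param snapshot_spacing spacing between snapshots in ps (default 0.2).
#' @param molar_mass molar mass in g/mol (18.015 for H2O; use 20.027 for
#'   D2O).
#' @param ... passed to [volume_scan()].
#' @return an object of class `aq_density` with per-snapshot results and the
#'   average `density` (g/cm^3).
#' @export
equilibrium_density <- function(traj, topology = NULL, backend,
                                n_snapshots = 30L, snapshot_spacing = 0.2,
                                molar_mass = aq_constants$molar_mass_h2o,
                                ...) {
  stopifnot(inherits(traj, "aq_traj"))
  if (!is.finite(traj$dt) || traj$dt <= 0)
    stop("trajectory frame spacing `dt` must be known for snapshot selection")
  stride <- max(1L, round(snapshot_spacing / traj$dt))
  need <- (n_snapshots - 1L) * stride + 1L
  if (need > n_frames(traj))
    stop("trajectory too short: ", n_snapshots, " snapshots every ",
         snapshot_spacing, " ps need ",
         format((need - 1) * traj$dt, digits = 4), " ps (",
         need, " frames), have ", n_frames(traj))
  idx <- seq.int(1L, by = stride, length.out = n_snapshots)
  if (is.null(topology)) topology <- assign_water_topology(get_frame(traj, idx[1]))
  scans <- lapply(idx, function(k)
    volume_scan(get_frame(traj, k), topology, backend, ...))
  v_eq <- vapply(scans, `[[`, numeric(1), "v_eq")
  nm <- n_molecules(topology)
  vbar <- mean(v_eq)
  dens <- nm * molar_mass / (aq_constants$avogadro * vbar) * 1e24
  structure(
    list(data = tibble::tibble(snapshot = idx,
                               time = (idx - 1L) * traj$dt,
                               v_eq = v_eq,
                               density = nm * molar_mass /
                                 (aq_constants$avogadro * v_eq) * 1e24),
         density = dens, v_eq_mean = vbar, n_mol = nm,
         molar_mass = molar_mass, scans = scans),
    class = "aq_density"
  )
}

#' @export
print.aq_density <- function(x, ...) {
  cat("<aq_density> ", nrow(x$data), " snapshots: mean V_eq = ",
      format(x$v_eq_mean, digits = 6), " A^3, density = ",
      format(x$density, digits = 4), " g/cm^3\n", sep = "")
  invisible(x)
}

#' Mass density of a cubic water box
#'
#' `rho = n_mol * M / (N_A * L^3)` converted to g/cm^3.
#'
#' @param n_mol number of molecules.
#' @param box_edge cubic box edge (Angstrom).
#' @param molar_mass molar mass (g/mol).
#' @return density in g/cm^3.
#' @examples
#' box_density(64, 12.445)   # ~1 g/cm^3
#' @export
box_density <- function(n_mol, box_edge,
                        molar_mass = aq_constants$molar_mass_h2o) {
  stopifnot(n_mol > 0, box_edge > 0, molar_mass > 0)
  n_mol * molar_mass / (aq_constants$avogadro * box_edge^3) * 1e24
}
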