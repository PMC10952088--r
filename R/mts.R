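# Multiple-time-step (r-RESPA) velocity-Verlet integration with pluggable
# force providers. The impulse scheme applies the slow force correction
# F_target - F_inner as symmetric half-kicks at the outer-step boundaries and
# integrates the fast inner forces with velocity Verlet in between; with a
# time-step ratio of 1 and matching providers it reduces exactly to velocity
# Verlet on the target forces.

#' Create an MD state
#'
#' @param positions numeric matrix N x 3 (Angstrom).
#' @param velocities numeric matrix N x 3 (Angstrom/ps).
#' @param masses numeric vector of length N (amu, > 0).
#' @param box_edge cubic box edge (Angstrom), or `Inf` for open boundaries.
#' @param time current time (ps).
#' @return an object of class `aq_mdstate`.
#' @export
md_state <- function(positions, velocities, masses, box_edge = Inf,
                     time = 0) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  if (!identical(dim(positions), dim(velocities)))
    stop("positions and velocities must have identical shapes")
  if (ncol(positions) != 3L) stop("positions must be N x 3")
  if (length(masses) != nrow(positions))
    stop("one mass per atom is required")
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(positions = positions, velocities = velocities,
                 masses = as.numeric(masses), box = box_edge,
                 time = as.numeric(time)),
            class = "aq_mdstate")
}

# normalise a provider result to list(forces, energy)
eval_provider <- function(provider, positions, box, step_label) {
  res <- provider(positions, box)
  if (is.matrix(res)) res <- list(forces = res, energy = NA_real_)
  if (is.null(res$energy)) res$energy <- NA_real_
  if (!all(is.finite(res$forces)))
    stop("non-finite force from provider at ", step_label)
  res
}

kinetic_energy <- function(state) {
  0.5 * sum(state$masses * rowSums(state$velocities^2))
}

#' Plain velocity-Verlet propagation
#'
#' Reference single-time-step integrator used both on its own and as the
#' baseline that [respa_propagate()] must reduce to at time-step ratio 1.
#'
#' @param state an [md_state()].
#' @param provider force provider: a function `(positions, box)` returning
#'   either an N x 3 force matrix (amu Angstrom/ps^2) or a list with elements
#'   `forces` and optionally `energy` (the potential, amu Angstrom^2/ps^2).
#' @param n_steps number of steps.
#' @param dt time step (ps).
#' @param record_every store every k-th step in the output trajectory.
#' @return an object of class `aq_mdrun`: final `state`, recorded `coords`
#'   array, and an `energies` tibble (`step`, `time`, `kinetic`, `potential`,
#'   `total`; potential `NA` when the provider reports no energy).
#' @export
velocity_verlet <- function(state, provider, n_steps, dt, record_every = 1L) {
  stopifnot(inherits(state, "aq_mdstate"), dt > 0, n_steps >= 1)
  x <- state$positions
  v <- state$velocities
  m <- state$masses
  f <- eval_provider(provider, x, state$box, "step 0")
  n_rec <- length(seq.int(0L, n_steps, by = record_every))
  coords <- array(0, c(n_rec, nrow(x), 3L))
  energ <- matrix(NA_real_, n_rec, 3L)
  ri <- 1L
  coords[1L, , ] <- x
  energ[1L, ] <- c(0.5 * sum(m * rowSums(v^2)), f$energy,
                   0.5 * sum(m * rowSums(v^2)) + f$energy)
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f$forces / m
    x <- x + dt * v
    f <- eval_provider(provider, x, state$box, paste("step", s))
    v <- v + 0.5 * dt * f$forces / m
    if (s %% record_every == 0L) {
      ri <- ri + 1L
      coords[ri, , ] <- x
      ke <- 0.5 * sum(m * rowSums(v^2))
      energ[ri, ] <- c(ke, f$energy, ke + f$energy)
    }
  }
  out_state <- md_state(x, v, m, state$box, state$time + n_steps * dt)
  structure(
    list(state = out_state, coords = coords,
         energies = tibble::tibble(
           step = seq.int(0L, n_steps, by = record_every),
           time = state$time + seq.int(0L, n_steps, by = record_every) * dt,
           kinetic = energ[, 1], potential = energ[, 2], total = energ[, 3]),
         dt = dt, scheme = "velocity-verlet"),
    class = "aq_mdrun"
  )
}

#' r-RESPA multiple-time-step propagation
#'
#' Impulse (kick) force splitting: cheap fast forces from `inner_provider`
#' are integrated with velocity Verlet at the inner step `dt_inner`, while
#' the slow correction `F_target - F_inner` is applied as symmetric
#' half-kicks at the outer-step boundaries (`Delta t = n_ratio * dt_inner`),
#' so the target force field is fully recovered at the outer time step. The
#' scheme is symplectic and time-reversible; with `n_ratio = 1` and
#' `target_provider` equal to `inner_provider` it reduces exactly (to
#' round-off) to [velocity_verlet()] on the target forces.
#'
#' @param state an [md_state()].
#' @param inner_provider fast force provider (see [velocity_verlet()]).
#' @param target_provider full (slow + fast) force provider; `NULL` means no
#'   correction (plain Verlet on the inner forces).
#' @param n_outer number of outer steps.
#' @param dt_inner inner time step (ps); the conventional 15 a.u. is
#'   `15 * aq_constants$au_time_to_ps`.
#' @param n_ratio integer time-step ratio n (>= 1), chosen in practice to
#'   maintain sufficient energy conservation (see [energy_drift()]).
#' @return an `aq_mdrun` recorded at outer steps; the `energies` tibble uses
#'   the target potential when the target provider reports one.
#' @export
respa_propagate <- function(state, inner_provider, target_provider = NULL,
                            n_outer, dt_inner, n_ratio = 1L) {
  stopifnot(inherits(state, "aq_mdstate"), dt_inner > 0, n_outer >= 1)
  n_ratio <- as.integer(n_ratio)
  if (n_ratio < 1L) stop("`n_ratio` must be a positive integer")
  x <- state$positions
  v <- state$velocities
  m <- state$masses
  dt_outer <- n_ratio * dt_inner
  has_corr <- !is.null(target_provider)

  f_in <- eval_provider(inner_provider, x, state$box, "outer step 0")
  f_tg <- if (has_corr) eval_provider(target_provider, x, state$box,
                                      "outer step 0") else f_in
  coords <- array(0, c(n_outer + 1L, nrow(x), 3L))
  energ <- matrix(NA_real_, n_outer + 1L, 3L)
  coords[1L, , ] <- x
  ke <- 0.5 * sum(m * rowSums(v^2))
  energ[1L, ] <- c(ke, f_tg$energy, ke + f_tg$energy)

  for (s in seq_len(n_outer)) {
    if (has_corr) {
      f_slow <- f_tg$forces - f_in$forces
      v <- v + 0.5 * dt_outer * f_slow / m
    }
    for (j in seq_len(n_ratio)) {
      v <- v + 0.5 * dt_inner * f_in$forces / m
      x <- x + dt_inner * v
      f_in <- eval_provider(inner_provider, x, state$box,
                            paste0("outer step ", s, ", inner ", j))
      v <- v + 0.5 * dt_inner * f_in$forces / m
    }
    if (has_corr) {
      f_tg <- eval_provider(target_provider, x, state$box,
                            paste("outer step", s))
      f_slow <- f_tg$forces - f_in$forces
      v <- v + 0.5 * dt_outer * f_slow / m
    } else {
      f_tg <- f_in
    }
    coords[s + 1L, , ] <- x
    ke <- 0.5 * sum(m * rowSums(v^2))
    energ[s + 1L, ] <- c(ke, f_tg$energy, ke + f_tg$energy)
  }
  out_state <- md_state(x, v, m, state$box,
                        state$time + n_outer * dt_outer)
  structure(
    list(state = out_state, coords = coords,
         energies = tibble::tibble(
           step = 0:n_outer,
           time = state$time + (0:n_outer) * dt_outer,
           kinetic = energ[, 1], potential = energ[, 2], total = energ[, 3]),
         dt = dt_outer, dt_inner = dt_inner, n_ratio = n_ratio,
         scheme = if (has_corr) "r-respa" else "velocity-verlet(inner)"),
    class = "aq_mdrun"
  )
}

#' @export
print.aq_mdrun <- function(x, ...) {
  cat("<aq_mdrun> ", x$scheme, ": ", nrow(x$energies) - 1L,
      " recorded steps, dt = ", format(x$dt, digits = 4), " ps\n", sep = "")
  invisible(x)
}

#' Energy drift diagnostics
#'
#' Least-squares linear drift of a total-energy series, per ps, plus the
#' maximal absolute deviation from the initial energy.
#'
#' @param energies numeric vector of total energies, or the `energies`
#'   tibble of an `aq_mdrun`.
#' @param times matching times in ps (taken from the tibble when omitted).
#' @return a list with `rate` (energy units per ps), `max_deviation`, and
#'   `relative_rate` (rate / |mean energy|, `NA` for zero mean).
#' @export
energy_drift <- function(energies, times = NULL) {
  if (is.data.frame(energies)) {
    times <- energies$time
    energies <- energies$total
  }
  if (length(energies) < 2L) stop("at least 2 energy samples are required")
  if (is.null(times)) times <- seq_along(energies) - 1
  fit <- lm(e ~ t, data = data.frame(e = energies, t = times))
  rate <- coef(fit)[["t"]]
  mu <- mean(energies)
  list(rate = rate,
       max_deviation = max(abs(energies - energies[1])),
       relative_rate = if (abs(mu) > 0) rate / abs(mu) else NA_real_)
}
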