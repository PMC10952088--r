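# Shared fixture builders: everything is generated in code at test time.

# Wrap a single frame into a 1-frame (or replicated n-frame) trajectory.
frame_to_traj <- function(frame, n = 1L, dt = NA_real_) {
  co <- array(0, c(n, nrow(frame$positions), 3L))
  for (k in seq_len(n)) co[k, , ] <- frame$positions
  aq_trajectory(co, frame$elements, frame$box, dt = dt)
}

# Topology implied by the generators' O,H,H atom order (random ideal-gas
# placements can overlap, so nearest-O assignment is not meaningful there).
consecutive_topology <- function(n_mol) {
  aq_topology(cbind(3 * seq_len(n_mol) - 2L,
                    3 * seq_len(n_mol) - 1L,
                    3 * seq_len(n_mol)))
}

# A single intact water molecule near the box centre.
single_water_frame <- function(box_edge = 10) {
  ctr <- rep(box_edge / 2, 3)
  aq_frame(rbind(ctr,
                 ctr + c(0.97, 0, 0),
                 ctr + c(-0.24, 0.94, 0)),
           c("O", "H", "H"), box_edge)
}

# Build an aq_traj from a list of position matrices sharing elements/box.
traj_from_frames <- function(pos_list, elements, box_edge, dt = NA_real_) {
  co <- array(0, c(length(pos_list), nrow(pos_list[[1]]), 3L))
  for (k in seq_along(pos_list)) co[k, , ] <- pos_list[[k]]
  aq_trajectory(co, elements, box_edge, dt = dt)
}

# Construct an aq_rdf object directly from an analytic g(r) curve, for
# operations that consume RDFs (extrema, coordination, rescaling).
synthetic_rdf <- function(g_fun, bin_width = 0.01, r_max = 6, rho = 0.0332,
                          box = 2 * r_max) {
  r <- seq(bin_width / 2, r_max - bin_width / 2, by = bin_width)
  structure(
    list(data = tibble::tibble(r = r, g = g_fun(r)),
         pair = "OO", bin_width = bin_width, r_max = r_max,
         rho = rho, rho_partner = rho, n_frames = 1L, box = box,
         exclude_intramolecular = FALSE),
    class = "aq_rdf")
}

# Construct an aq_acf object from an analytic C(t) curve.
synthetic_acf <- function(C_fun, dt = 0.05, t_max = 10, order = 2L,
                          axis = "OH") {
  lags <- 0:round(t_max / dt)
  structure(
    list(data = tibble::tibble(lag = lags, time = lags * dt,
                               C = C_fun(lags * dt)),
         axis = axis, order = order, n_vectors = 1L, dt = dt),
    class = "aq_acf")
}
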