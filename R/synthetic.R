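# Synthetic-trajectory generators with known ground truth. Each generator is
# seeded and records its parameters in the trajectory metadata, so analysis
# stages can be validated against closed-form expectations:
#   * Brownian COM walks      -> Einstein diffusion (MSD slope = 6 D t)
#   * isotropic rigid rotors  -> C_n(t) = exp(-n(n+1) D_r t)
#   * proton-disordered ice   -> 4 H-bonds and 4 O neighbours per molecule
#   * ideal gas               -> g(r) = 1, coordination (4/3) pi rho r^3
#   * two-molecule dimers     -> hand-computable H-bond geometry
#   * analytic E(V) backends  -> known equilibrium volume

#' Rigid water template geometry
#'
#' Returns the atom positions (rows O, H1, H2; Angstrom) of a rigid water
#' monomer with its oxygen at the origin and the H-O-H bisector along +x.
#'
#' @param r_oh O-H bond length in Angstrom.
#' @param hoh_angle H-O-H angle in degrees.
#' @return 3 x 3 numeric matrix.
#' @export
water_template <- function(r_oh = 0.97, hoh_angle = 104.5) {
  half <- hoh_angle / 2 * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = r_oh * c(cos(half),  sin(half), 0),
        H2 = r_oh * c(cos(half), -sin(half), 0))
}

# --- quaternion helpers (vectorised over rows; q = (w, x, y, z)) -----------

quat_random <- function(n) {
  # Shoemake's method: uniform over SO(3)
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))[, c(4, 1, 2, 3), drop = FALSE]
}

quat_multiply <- function(p, q) {
  # Hamilton product p * q, rowwise
  cbind(p[, 1] * q[, 1] - p[, 2] * q[, 2] - p[, 3] * q[, 3] - p[, 4] * q[, 4],
        p[, 1] * q[, 2] + p[, 2] * q[, 1] + p[, 3] * q[, 4] - p[, 4] * q[, 3],
        p[, 1] * q[, 3] - p[, 2] * q[, 4] + p[, 3] * q[, 1] + p[, 4] * q[, 2],
        p[, 1] * q[, 4] + p[, 2] * q[, 3] - p[, 3] * q[, 2] + p[, 4] * q[, 1])
}

quat_from_rotvec <- function(v) {
  # exponential map: rotation vector (axis * angle) -> unit quaternion
  theta <- sqrt(rowSums(v * v))
  half <- theta / 2
  s <- ifelse(theta > 1e-300, sin(half) / theta, 0.5)
  cbind(cos(half), v[, 1] * s, v[, 2] * s, v[, 3] * s)
}

quat_to_matrix_elements <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y))
}

# Rotate the rows of `template` (na x 3) by each row-wise rotation matrix in
# `R9` (n x 9, row-major r11..r33) and add the anchors (n x 3). Returns the
# (n * na) x 3 matrix of atom positions, molecules contiguous.
place_rigid <- function(template, R9, anchors) {
  n <- nrow(R9); na <- nrow(template)
  out <- matrix(0, n * na, 3)
  for (a in seq_len(na)) {
    tv <- template[a, ]
    rows <- seq(a, by = na, length.out = n)
    out[rows, 1] <- anchors[, 1] + R9[, 1] * tv[1] + R9[, 2] * tv[2] + R9[, 3] * tv[3]
    out[rows, 2] <- anchors[, 2] + R9[, 4] * tv[1] + R9[, 5] * tv[2] + R9[, 6] * tv[3]
    out[rows, 3] <- anchors[, 3] + R9[, 7] * tv[1] + R9[, 8] * tv[2] + R9[, 9] * tv[3]
  }
  out
}

water_elements <- function(n_mol) rep(c("O", "H", "H"), n_mol)

template_about_com <- function(template, mass_h = aq_constants$mass_H) {
  m <- c(aq_constants$mass_O, mass_h, mass_h)
  com <- colSums(template * m) / sum(m)
  sweep(template, 2, com, "-")
}

#' Brownian centre-of-mass trajectory of rigid waters
#'
#' Every molecule's centre of mass performs an independent Gaussian random
#' walk with per-axis step variance `2 * D_true * dt`; monomers are rigid with
#' a fixed random orientation. Walkers start on a cubic grid (a
#' non-overlapping initial configuration, so topology assignment on the first
#' frame is unambiguous); the walk statistics do not depend on the start.
#' Stored coordinates are wrapped into the box; the continuous (unwrapped)
#' coordinates are kept in `meta$unwrapped` as the ground-truth record for
#' unwrapping and MSD tests. Molecular overlap during the walk is not checked
#' (the walkers are non-interacting by construction).
#'
#' @param n_mol number of water molecules.
#' @param box_edge cubic box edge L (Angstrom).
#' @param D_true ground-truth diffusion coefficient (Angstrom^2/ps, >= 0).
#' @param dt frame spacing (ps, > 0).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param template rigid monomer geometry from [water_template()].
#' @return an [aq_trajectory()] with generator metadata.
#' @export
brownian_com_trajectory <- function(n_mol, box_edge, D_true, dt, n_frames,
                                    seed = 1L, template = water_template()) {
  stopifnot(D_true >= 0, dt > 0, n_frames >= 1, n_mol >= 1)
  set.seed(seed)
  tpl <- template_about_com(template)
  ng <- ceiling(n_mol^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(ng), y = seq_len(ng),
                             z = seq_len(ng)))
  com0 <- (g[seq_len(n_mol), , drop = FALSE] - 0.5) * (box_edge / ng)
  R9 <- quat_to_matrix_elements(quat_random(n_mol))
  sdstep <- sqrt(2 * D_true * dt)
  nat <- 3L * n_mol
  coords <- array(0, c(n_frames, nat, 3L))
  unwrapped <- array(0, c(n_frames, nat, 3L))
  com <- com0
  for (k in seq_len(n_frames)) {
    if (k > 1L) com <- com + matrix(rnorm(n_mol * 3, sd = sdstep), n_mol, 3)
    at <- place_rigid(tpl, R9, com)
    unwrapped[k, , ] <- at
    coords[k, , ] <- at - box_edge * floor(at / box_edge)
  }
  aq_trajectory(coords, water_elements(n_mol), box_edge, dt = dt,
                meta = list(generator = "brownian_com", D_true = D_true,
                            dt = dt, n_mol = n_mol, seed = seed,
                            unwrapped = unwrapped))
}

#' Isotropic rotational-diffusion trajectory of rigid waters
#'
#' Each rigid monomer rotates by a small random rotation per frame, with
#' isotropic axis and per-axis angle variance `2 * D_r * dt` (exponential-map
#' composition, so orientations stay exactly unit-norm). Centres of mass sit
#' on a fixed non-overlapping cubic grid. For this process the orientational
#' autocorrelation functions are `C_n(t) = exp(-n(n+1) D_r t)`.
#'
#' @param n_mol number of molecules.
#' @param D_r rotational diffusion constant (1/ps, >= 0).
#' @param dt frame spacing (ps).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param grid_spacing distance between neighbouring grid anchors (Angstrom).
#' @param template rigid monomer geometry.
#' @return an [aq_trajectory()].
#' @export
rotor_trajectory <- function(n_mol, D_r, dt, n_frames, seed = 1L,
                             grid_spacing = 4, template = water_template()) {
  stopifnot(D_r >= 0, dt > 0, n_frames >= 1)
  set.seed(seed)
  ng <- ceiling(n_mol^(1 / 3))
  box_edge <- ng * grid_spacing
  g <- as.matrix(expand.grid(x = seq_len(ng), y = seq_len(ng), z = seq_len(ng)))
  anchors <- (g[seq_len(n_mol), , drop = FALSE] - 0.5) * grid_spacing
  tpl <- template_about_com(template)
  q <- quat_random(n_mol)
  sdstep <- sqrt(2 * D_r * dt)
  coords <- array(0, c(n_frames, 3L * n_mol, 3L))
  for (k in seq_len(n_frames)) {
    if (k > 1L) {
      dq <- quat_from_rotvec(matrix(rnorm(n_mol * 3, sd = sdstep), n_mol, 3))
      q <- quat_multiply(dq, q)
      q <- q / sqrt(rowSums(q * q))
    }
    coords[k, , ] <- place_rigid(tpl, quat_to_matrix_elements(q), anchors)
  }
  aq_trajectory(coords, water_elements(n_mol), box_edge, dt = dt,
                meta = list(generator = "rotor", D_r = D_r, dt = dt,
                            n_mol = n_mol, seed = seed))
}

#' Proton-disordered cubic ice obeying the Bernal-Fowler rules
#'
#' Oxygens are placed on a diamond (cubic-ice) sublattice with nearest
#' neighbour O-O distance `a_OO` under periodic boundaries; every O-O link
#' carries exactly one hydrogen, placed on the O-O axis at distance `r_oh`
#' from its covalent oxygen, and every oxygen holds exactly two covalent
#' hydrogens. The proton assignment starts random and is repaired by
#' single-bond Monte-Carlo flips on the bond-occupancy graph until the ice
#' rules are satisfied.
#'
#' @param n_cells number of conventional diamond cells per box edge (the box
#'   holds `8 * n_cells^3` molecules).
#' @param a_OO nearest-neighbour O-O distance (Angstrom; 2.4--3.4 recommended).
#' @param seed RNG seed for the proton assignment.
#' @param r_oh covalent O-H bond length (Angstrom).
#' @param max_sweeps maximum Monte-Carlo sweeps before giving up.
#' @return a list with elements `frame` (an [aq_frame()], oxygens first) and
#'   `topology` (an [aq_topology()]).
#' @examples
#' ice <- make_tetrahedral_ice(1, a_OO = 2.75, seed = 7)
#' n_molecules(ice$topology)
#' @export
make_tetrahedral_ice <- function(n_cells, a_OO = 2.75, seed = 1L, r_oh = 0.97,
                                 max_sweeps = 2000L) {
  stopifnot(n_cells >= 1, a_OO > 0)
  set.seed(seed)
  a <- 4 * a_OO / sqrt(3)
  L <- n_cells * a
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  cells <- as.matrix(expand.grid(0:(n_cells - 1), 0:(n_cells - 1),
                                 0:(n_cells - 1)))
  o_frac <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    base <- sweep(fcc, 2, as.numeric(cells[i, ]), "+")
    rbind(base, sweep(base, 2, c(.25, .25, .25), "+"))
  }))
  o_pos <- o_frac * a
  n_o <- nrow(o_pos)

  d <- pair_distances(o_pos, o_pos, L)
  adj <- which(d > 0 & d < 1.2 * a_OO, arr.ind = TRUE)
  bonds <- unique(t(apply(adj, 1, sort)))
  if (nrow(bonds) != 2L * n_o || any(tabulate(c(bonds), n_o) != 4L))
    stop("diamond lattice construction failed: wrong neighbour counts")

  # donor[b] is the bond endpoint (1 or 2) that covalently holds the hydrogen
  donor <- sample(1:2, nrow(bonds), replace = TRUE)
  holder <- function() bonds[cbind(seq_len(nrow(bonds)), donor)]
  cov <- tabulate(holder(), n_o)
  energy <- sum((cov - 2L)^2)
  it <- 0L
  nb <- nrow(bonds)
  while (energy > 0L && it < max_sweeps * nb) {
    it <- it + 1L
    b <- sample.int(nb, 1L)
    i <- bonds[b, donor[b]]
    j <- bonds[b, 3L - donor[b]]
    de <- ((cov[i] - 3L)^2 + (cov[j] - 1L)^2) - ((cov[i] - 2L)^2 + (cov[j] - 2L)^2)
    if (de < 0L || (de == 0L && runif(1) < 0.5)) {
      donor[b] <- 3L - donor[b]
      cov[i] <- cov[i] - 1L
      cov[j] <- cov[j] + 1L
      energy <- energy + de
    }
  }
  if (energy > 0L)
    stop("ice-rule assignment did not converge; retry with another seed")

  hold <- holder()
  acc <- bonds[cbind(seq_len(nb), ifelse(hold == bonds[, 1], 2L, 1L))]
  u <- minimum_image(o_pos[acc, , drop = FALSE] - o_pos[hold, , drop = FALSE], L)
  u <- u / sqrt(rowSums(u * u))
  h_pos <- o_pos[hold, , drop = FALSE] + r_oh * u

  positions <- rbind(o_pos, h_pos)
  elements <- c(rep("O", n_o), rep("H", nb))
  frame <- aq_frame(positions, elements, L)
  mol <- t(vapply(seq_len(n_o), function(i) {
    hs <- n_o + which(hold == i)
    c(i, hs[1], hs[2])
  }, integer(3)))
  list(frame = frame, topology = aq_topology(mol))
}

#' Ideal-gas water configurations
#'
#' Molecule centres are uniform in the box and independent across frames,
#' with independent random orientations: the null model for RDF
#' normalisation, for which g(r) = 1 at all resolvable distances.
#'
#' @param n_mol number of molecules (>= 2).
#' @param box_edge cubic box edge (Angstrom).
#' @param n_frames number of independent frames.
#' @param seed RNG seed.
#' @param template rigid monomer geometry.
#' @return an [aq_trajectory()].
#' @export
ideal_gas_trajectory <- function(n_mol, box_edge, n_frames, seed = 1L,
                                 template = water_template()) {
  stopifnot(n_mol >= 2, n_frames >= 1)
  set.seed(seed)
  tpl <- template_about_com(template)
  coords <- array(0, c(n_frames, 3L * n_mol, 3L))
  for (k in seq_len(n_frames)) {
    com <- matrix(runif(n_mol * 3, 0, box_edge), n_mol, 3)
    R9 <- quat_to_matrix_elements(quat_random(n_mol))
    at <- place_rigid(tpl, R9, com)
    coords[k, , ] <- at - box_edge * floor(at / box_edge)
  }
  aq_trajectory(coords, water_elements(n_mol), box_edge, dt = NA_real_,
                meta = list(generator = "ideal_gas", n_mol = n_mol,
                            seed = seed))
}

#' Two-water hydrogen-bond geometry
#'
#' Builds a donor--acceptor pair with a prescribed O-O distance and donor
#' tilt: the donor O-H axis makes an angle `tilt_deg` with the O-O axis (so
#' the hydrogen-bond path-length excess is zero at zero tilt and grows with
#' the tilt), and the acceptor is oriented to accept, with its hydrogens
#' pointing away from the donor.
#'
#' @param d_OO donor-acceptor oxygen distance (Angstrom, > 0).
#' @param tilt_deg donor O-H tilt from the O-O axis, in degrees (0 <= tilt < 90).
#' @param box_edge cubic box edge; defaults to a box large enough that
#'   periodic images play no role.
#' @param r_oh O-H bond length; `hoh_angle` H-O-H angle (degrees).
#' @param hoh_angle H-O-H angle in degrees.
#' @return a list with `frame` (atoms O_d, H1, H2, O_a, H3, H4) and `topology`;
#'   molecule 1 is the donor and its H1 is the donating hydrogen.
#' @examples
#' dim28 <- dimer_frame(2.8, tilt_deg = 0)
#' dim28$frame$positions
#' @export
dimer_frame <- function(d_OO, tilt_deg = 0, box_edge = max(20, 3 * d_OO),
                        r_oh = 0.97, hoh_angle = 104.5) {
  stopifnot(d_OO > 0, tilt_deg >= 0, tilt_deg < 90)
  tilt <- tilt_deg * pi / 180
  ang <- hoh_angle * pi / 180
  ctr <- rep(box_edge / 2, 3)
  o_d <- ctr - c(d_OO / 2, 0, 0)
  o_a <- ctr + c(d_OO / 2, 0, 0)
  h1 <- o_d + r_oh * c(cos(tilt), sin(tilt), 0)
  h2 <- o_d + r_oh * c(cos(tilt - ang), sin(tilt - ang), 0)
  half <- ang / 2
  h3 <- o_a + r_oh * c(cos(half), 0, sin(half))
  h4 <- o_a + r_oh * c(cos(half), 0, -sin(half))
  frame <- aq_frame(rbind(o_d, h1, h2, o_a, h3, h4),
                    c("O", "H", "H", "O", "H", "H"), box_edge)
  list(frame = frame,
       topology = aq_topology(rbind(c(1L, 2L, 3L), c(4L, 5L, 6L))))
}

#' Analytic quadratic energy-versus-volume backend
#'
#' Returns an energy backend (a function of a scaled frame and its box
#' volume) with `E(V) = curvature * (V - V0)^2`, independent of the atomic
#' coordinates -- ground truth for equilibrium-density estimation: the scan
#' minimum sits exactly at `V0`.
#'
#' @param V0 equilibrium volume (Angstrom^3, > 0).
#' @param curvature quadratic coefficient (> 0, arbitrary energy units).
#' @return a function `(frame, volume) -> energy`.
#' @examples
#' be <- quadratic_EV_backend(1000, 1e-3)
#' be(NULL, 1000)
#' @export
quadratic_EV_backend <- function(V0, curvature = 1e-3) {
  stopifnot(V0 > 0, curvature > 0)
  force(V0); force(curvature)
  function(frame, volume) curvature * (volume - V0)^2
}
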