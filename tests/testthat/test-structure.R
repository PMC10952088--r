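test_that("RDF normalisation gives the ideal-gas limit and honours r_max", {
  ig <- ideal_gas_trajectory(48, 12, n_frames = 80, seed = 21)
  rdf <- compute_rdf(ig, "OO", bin_width = 0.1)
  expect_true(all(rdf$data$g >= 0))
  expect_equal(max(rdf$data$r), 6 - 0.05)
  expect_lt(abs(mean(rdf$data$g[rdf$data$r > 2]) - 1), 0.02)

  expect_error(compute_rdf(ig, "OO", r_max = 7), "half the box")
  expect_error(compute_rdf(ig, "OO", bin_width = 0), "bin_width")
})

test_that("a single O-O pair lands all its mass in the right bin", {
  L <- 12
  f <- aq_frame(rbind(c(2, 2, 2), c(2 + 2.5, 2, 2)), c("O", "O"), L)
  traj <- frame_to_traj(f)
  rdf <- compute_rdf(traj, "OO", bin_width = 0.1)
  hit <- which(rdf$data$g > 0)
  expect_length(hit, 1L)
  expect_lt(abs(rdf$data$r[hit] - 2.5), 0.1)
  # normalisation consistency: integrating rho_partner * 4 pi r^2 g over the
  # occupied bin returns exactly one neighbour per particle
  expect_equal(coordination_number(rdf, "fixed", cutoff = 3), 1)
})

test_that("the RDF sum rule matches direct pair counting", {
  ig <- ideal_gas_trajectory(32, 10, n_frames = 6, seed = 33)
  rdf <- compute_rdf(ig, "OO", bin_width = 0.05)
  r_cut <- 4.95   # a bin edge, so histogram integration is exact
  n_int <- coordination_number(rdf, "fixed", cutoff = r_cut)
  # oracle: average neighbour count within r_cut by direct distance loops
  o_idx <- which(ig$elements == "O")
  counts <- numeric(0)
  for (k in seq_len(n_frames(ig))) {
    p <- ig$coords[k, o_idx, ]
    d <- aquatraj:::pair_distances(p, p, 10)
    counts <- c(counts, rowSums(d > 0 & d < r_cut))
  }
  expect_equal(n_int, mean(counts), tolerance = 1e-9)
  # bounded by N - 1, approached as the cutoff fills the sphere
  expect_lt(coordination_number(rdf, "fixed", cutoff = 4.95), 31)
})

test_that("intramolecular pairs can be excluded from g_OH", {
  # grid-anchored rotors: molecules never overlap, so every O-H pair below
  # ~1.5 A is intramolecular by construction
  ig <- rotor_trajectory(27, 0.1, 0.02, 4, seed = 4)
  top <- consecutive_topology(n_atoms(ig) / 3)
  with_intra <- compute_rdf(ig, "OH", bin_width = 0.05)
  without <- compute_rdf(ig, "OH", topology = top, bin_width = 0.05,
                         exclude_intramolecular = TRUE)
  # the covalent peak near 0.97 A exists only with intramolecular pairs
  cov_bin <- which(abs(with_intra$data$r - 0.975) < 0.026)
  expect_gt(sum(with_intra$data$g[cov_bin]), 1)
  expect_equal(sum(without$data$g[cov_bin]), 0)
  expect_error(compute_rdf(ig, "OH", exclude_intramolecular = TRUE),
               "topology")
})

test_that("first extrema are located on the spline to sub-bin accuracy", {
  g1 <- function(r) 1 + exp(-(r - 2.8)^2 / 0.02)
  rdf1 <- synthetic_rdf(g1)
  pk <- find_first_extrema(rdf1, temperature = 300)
  expect_lt(abs(pk$r_max1 - 2.8), 0.005)
  expect_equal(pk$g_max1, 2, tolerance = 1e-4)
  expect_equal(pk$temperature, 300)

  # two Gaussians: the inter-peak minimum solves g'(r) = 0 analytically
  g2 <- function(r) exp(-(r - 2.8)^2 / 0.08) + 0.8 * exp(-(r - 4.4)^2 / 0.5)
  dg2 <- function(r) {
    -2 * (r - 2.8) / 0.08 * exp(-(r - 2.8)^2 / 0.08) -
      2 * 0.8 * (r - 4.4) / 0.5 * exp(-(r - 4.4)^2 / 0.5)
  }
  r_min_true <- uniroot(dg2, c(3.2, 4.0), tol = 1e-12)$root
  pk2 <- find_first_extrema(synthetic_rdf(g2))
  expect_lt(abs(pk2$r_min1 - r_min_true), 1e-3)
  expect_lt(pk2$r_max1, pk2$r_min1)

  # r_c from the r^2 g integrand: at its minimum 2 r g + r^2 g' = 0, so
  # g' = -2 g / r < 0 there -- the integrand minimum sits on the decaying
  # flank, before the g minimum. Verify against the analytic root.
  d_r2g2 <- function(r) 2 * r * g2(r) + r^2 * dg2(r)
  r_c_true <- uniroot(d_r2g2, c(3.2, r_min_true), tol = 1e-12)$root
  expect_lt(pk2$r_c, pk2$r_min1)
  expect_lt(abs(pk2$r_c - r_c_true), 1e-3)

  # monotone decreasing curve has no first peak
  expect_error(find_first_extrema(synthetic_rdf(function(r) exp(-r))),
               "no first peak")
})

test_that("coordination numbers integrate analytic and lattice cases", {
  # g = 1 with rho* = 0.0332 and r_c = 3.0: (4/3) pi rho r^3 exactly
  rdf1 <- synthetic_rdf(function(r) rep(1, length(r)), bin_width = 0.01)
  expect_equal(coordination_number(rdf1, "fixed", cutoff = 3, rho = 0.0332),
               4 / 3 * pi * 0.0332 * 27, tolerance = 1e-12)
  # spline integration agrees on the smooth curve
  expect_equal(coordination_number(rdf1, "fixed", cutoff = 3, rho = 0.0332,
                                   method = "spline"),
               4 / 3 * pi * 0.0332 * 27, tolerance = 1e-6)

  # tetrahedral ice: exactly 4 neighbours under every convention
  ice <- make_tetrahedral_ice(2, a_OO = 2.75, seed = 13)
  traj <- frame_to_traj(ice$frame)
  rdf <- compute_rdf(traj, "OO", bin_width = 0.02)
  expect_equal(coordination_number(rdf, "fixed", cutoff = 3.4), 4,
               tolerance = 1e-9)
  pk <- find_first_extrema(rdf)
  # both cutoff conventions fall between the first (2.75 A) and second
  # (4.49 A) neighbour shells, so both count exactly 4
  expect_gt(pk$r_min1, 2.75); expect_lt(pk$r_min1, 4.49)
  expect_gt(pk$r_c, 2.75);    expect_lt(pk$r_c, 4.49)
  expect_equal(coordination_number(rdf, "r2g_min"), 4, tolerance = 1e-9)
  expect_equal(coordination_number(rdf, "g_min"), 4, tolerance = 1e-9)

  expect_error(coordination_number(rdf, "fixed", cutoff = 20), "beyond")
})

test_that("coordination is robust to bin-width doubling on smooth curves", {
  g <- function(r) 1 + 1.5 * exp(-(r - 2.8)^2 / 0.1)
  n1 <- coordination_number(synthetic_rdf(g, bin_width = 0.01),
                            "fixed", cutoff = 3.3, rho = 0.0332)
  n2 <- coordination_number(synthetic_rdf(g, bin_width = 0.02),
                            "fixed", cutoff = 3.3, rho = 0.0332)
  expect_lt(abs(n2 - n1) / n1, 0.01)
})

test_that("RDFs are invariant under rigid translation and frame relabeling", {
  ig <- ideal_gas_trajectory(24, 10, n_frames = 5, seed = 17)
  ref <- compute_rdf(ig, "OO", bin_width = 0.1)
  shifted <- ig
  shifted$coords <- ig$coords + 1.7
  expect_equal(compute_rdf(shifted, "OO", bin_width = 0.1)$data$g,
               ref$data$g)
  rev_traj <- ig
  rev_traj$coords <- ig$coords[n_frames(ig):1, , , drop = FALSE]
  expect_equal(compute_rdf(rev_traj, "OO", bin_width = 0.1)$data$g,
               ref$data$g)
})

test_that("descriptor rescaling to 298 K shifts along the reference fit", {
  tab <- data.frame(temperature = c(268, 288, 308, 328),
                    g_max1 = 3.5 - 0.01 * c(268, 288, 308, 328))
  # identity at the reference temperature
  expect_equal(rescale_descriptor_to_298K(2.7, "g_max1", 298, tab), 2.7)
  # a linear table with slope s moves the value by -(T_sim - 298) * s
  expect_equal(rescale_descriptor_to_298K(2.7, "g_max1", 308, tab),
               2.7 + 10 * 0.01, tolerance = 1e-10)
  # involution: rescaling there and back restores the value
  fwd <- rescale_descriptor_to_298K(2.7, "g_max1", 313, tab)
  expect_equal(rescale_descriptor_to_298K(fwd, "g_max1", 298, tab,
                                          T_ref = 313), 2.7,
               tolerance = 1e-10)
  # validation
  expect_error(rescale_descriptor_to_298K(2.7, "g_max1", 298, tab[1, ]),
               "two rows")
  expect_warning(rescale_descriptor_to_298K(2.7, "g_max1", 400, tab),
                 "extrapolates")
  expect_error(rescale_descriptor_to_298K(2.7, "nope", 298, tab),
               "not found")
})

test_that("the shipped synthetic reference table loads and round-trips", {
  path <- system.file("extdata", "reference_descriptors_synthetic.csv",
                      package = "aquatraj")
  tab <- read_reference_table(path)
  expect_true(all(c("temperature", "r_max1", "g_max1", "r_min1", "g_min1")
                  %in% names(tab)))
  expect_true(all(diff(tab$temperature) > 0))
  v <- rescale_descriptor_to_298K(2.9, "g_max1", 310, tab)
  expect_equal(rescale_descriptor_to_298K(v, "g_max1", 298, tab,
                                          T_ref = 310), 2.9,
               tolerance = 1e-10)
})
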