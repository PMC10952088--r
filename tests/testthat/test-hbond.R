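test_that("the smoothed rectangle switch honours its printed anchors", {
  sw_oo <- switch_params(2.8, 0.45, 10, 16)
  sw_dp <- switch_params(0, 0.4, 4, 8)

  # centre value and the removable singularity at the rectangle edge
  expect_identical(rect_switch(2.8, sw_oo), 1)
  expect_equal(rect_switch(2.8 + 0.45, sw_oo), 10 / 16)
  expect_equal(rect_switch(2.8 - 0.45, sw_oo), 10 / 16)
  expect_identical(rect_switch(0, sw_dp), 1)
  expect_equal(rect_switch(0.4, sw_dp), 0.5)   # n/m = 4/8

  # path-excess switch: 1 at zero, rapid decay beyond ~0.5 A
  expect_lt(rect_switch(0.6, sw_dp), 0.05)
  expect_lt(rect_switch(0.5, sw_dp), 0.2)
  expect_gt(rect_switch(0.2, sw_dp), 0.95)

  # continuity across the removable singularity
  eps <- 1e-7
  expect_lt(abs(rect_switch(3.25 + eps, sw_oo) - 10 / 16), 1e-4)
  expect_lt(abs(rect_switch(3.25 - eps, sw_oo) - 10 / 16), 1e-4)

  # monotone non-increasing in |d - d0|, values in [0, 1]
  d <- seq(2.8, 6, by = 0.01)
  v <- rect_switch(d, sw_oo)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v >= 0 & v <= 1))
  v2 <- rect_switch(seq(2.8, -0.4, by = -0.01), sw_oo)
  expect_true(all(diff(v2) <= 1e-12))

  # far outside the window the switch vanishes instead of overflowing
  expect_equal(rect_switch(1e8, sw_dp), 0)

  # parameter validation
  expect_error(switch_params(0, -1, 4, 8), "delta")
  expect_error(switch_params(0, 0.4, 8, 4), "smaller")
  expect_error(switch_params(0, 0.4, 2.5, 8), "integers")
  expect_error(hbond_criterion(threshold = 1.2), "threshold")
})

test_that("path-length excess is zero when collinear and grows with tilt", {
  L <- 20
  expect_equal(excess_path_length(c(0, 0, 0), c(0.97, 0, 0), c(2.8, 0, 0), L),
               0, tolerance = 1e-12)

  # hand trigonometry at 30 degrees, checked against a plain distance oracle
  h30 <- 0.97 * c(cos(pi / 6), sin(pi / 6), 0)
  oracle <- 0.97 + sqrt(sum((c(2.8, 0, 0) - h30)^2)) - 2.8
  expect_equal(excess_path_length(c(0, 0, 0), h30, c(2.8, 0, 0), L), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 0.18907, tolerance = 1e-4)

  # monotone in the donor tilt
  ex_at_tilt <- function(t) {
    d <- dimer_frame(2.8, tilt_deg = t)
    p <- d$frame$positions
    excess_path_length(p[1, ], p[2, ], p[4, ], d$frame$box)
  }
  expect_gt(ex_at_tilt(20), ex_at_tilt(5))
  expect_gt(ex_at_tilt(40), ex_at_tilt(20))

  # periodic images are honoured: same geometry split across a face
  o_d <- c(19.5, 5, 5); h <- c(0.47, 5, 5); o_a <- c(2.3, 5, 5)
  expect_equal(excess_path_length(o_d, h, o_a, L), 0, tolerance = 1e-12)
})

test_that("is_hbonded accepts the linear dimer and rejects distant pairs", {
  d28 <- dimer_frame(2.8, 0)
  r <- is_hbonded(d28$frame, d28$topology, donor = 1, h = 2, acceptor = 2)
  expect_true(r$bonded)
  expect_gt(r$product, 0.95)
  expect_equal(r$d_oo, 2.8, tolerance = 1e-12)

  d60 <- dimer_frame(6.0, 0)
  r6 <- is_hbonded(d60$frame, d60$topology, donor = 1, h = 2, acceptor = 2)
  expect_false(r6$bonded)
  expect_lt(r6$product, 1e-4)

  # the non-donating hydrogen of the donor molecule does not bond
  r_h2 <- is_hbonded(d28$frame, d28$topology, donor = 1, h = 3, acceptor = 2)
  expect_false(r_h2$bonded)

  # contract violation: H must belong to the donor
  expect_error(is_hbonded(d28$frame, d28$topology, donor = 1, h = 5,
                          acceptor = 2), "not a covalent hydrogen")
  expect_error(is_hbonded(d28$frame, d28$topology, donor = 1, h = 2,
                          acceptor = 1), "must differ")
})

test_that("proton-ordered ice carries exactly four H-bonds per molecule", {
  ice <- make_tetrahedral_ice(2, a_OO = 2.75, seed = 19)
  traj <- frame_to_traj(ice$frame)
  hb <- hbond_stats(traj, ice$topology)
  expect_equal(hb$h, 4, tolerance = 1e-12)
  expect_equal(hb$h_donated, 2, tolerance = 1e-12)
  expect_true(all(hb$total == 4L))
  expect_true(all(hb$donated == 2L))
  expect_true(all(hb$accepted == 2L))
  # every counted bond sits far inside the switch windows
  expect_true(all(hb$products > 0.9))

  # the smoothed criterion agrees with the conventional distance + angle one
  hb_conv <- hbond_stats(traj, ice$topology,
                         criterion = conventional_criterion())
  expect_equal(hb_conv$h, hb$h, tolerance = 1e-12)
})

test_that("dilute ideal gas has essentially no hydrogen bonds", {
  ig <- ideal_gas_trajectory(8, 30, n_frames = 10, seed = 23)
  top <- consecutive_topology(n_atoms(ig) / 3)
  hb <- hbond_stats(ig, top)
  expect_lt(hb$h, 0.1)
})

test_that("neighbour-list counting equals the brute-force double loop", {
  # a dense disordered 32-molecule system (liquid-like box edge)
  ig <- ideal_gas_trajectory(32, 9.939, n_frames = 4, seed = 29)
  top <- consecutive_topology(n_atoms(ig) / 3)
  a <- hbond_stats(ig, top, method = "neighbour")
  b <- hbond_stats(ig, top, method = "brute")
  expect_identical(a$donated, b$donated)
  expect_identical(a$accepted, b$accepted)
  expect_equal(a$h, b$h)
})

test_that("H-bond counts are invariant under wrapping and relabeling", {
  ice <- make_tetrahedral_ice(1, a_OO = 2.75, seed = 31)
  traj <- frame_to_traj(ice$frame)
  ref <- hbond_stats(traj, ice$topology)

  # wrap a handful of atoms by whole box lengths
  set.seed(7)
  co <- traj$coords
  idx <- sample(dim(co)[2], 6)
  co[1, idx, 2] <- co[1, idx, 2] + traj$box
  wrapped <- aq_trajectory(co, traj$elements, traj$box)
  expect_equal(hbond_stats(wrapped, ice$topology)$h, ref$h)

  # relabel molecules (permute topology rows)
  perm <- sample(n_molecules(ice$topology))
  top_p <- aq_topology(ice$topology$molecules[perm, ])
  hb_p <- hbond_stats(traj, top_p)
  expect_equal(hb_p$h, ref$h)
  expect_equal(sort(colSums(hb_p$total)), sort(colSums(ref$total)))
})

test_that("switch products are bimodal on near-ice ensembles", {
  ice <- make_tetrahedral_ice(2, a_OO = 2.75, seed = 37)
  set.seed(41)
  pos <- ice$frame$positions + matrix(rnorm(length(ice$frame$positions),
                                            sd = 0.04),
                                      nrow(ice$frame$positions), 3)
  traj <- frame_to_traj(aq_frame(pos, ice$frame$elements, ice$frame$box))
  hb <- hbond_stats(traj, ice$topology)
  expect_gt(mean(hb$products > 0.8), 0.9)
  expect_equal(hb$h, 4, tolerance = 0.1)
})

test_that("angle distributions are sharp for ice and dimers and normalised", {
  ice <- make_tetrahedral_ice(1, a_OO = 2.75, seed = 43)
  traj <- frame_to_traj(ice$frame)
  ang <- angle_distribution(traj, ice$topology)
  # hydrogens sit on the O-O axes: every qualifying beta is numerically zero
  expect_gt(ang$n_pairs, 0)
  expect_true(all(ang$beta_values < 1e-6))
  expect_true(all(ang$alpha_values < 1e-6))
  expect_equal(sum(ang$data$beta_density) * ang$bin_width, 1,
               tolerance = 1e-6)

  # a 20-degree dimer contributes a single beta at 20 within the grid
  d20 <- dimer_frame(2.8, tilt_deg = 20)
  tr20 <- frame_to_traj(d20$frame)
  a20 <- angle_distribution(tr20, d20$topology, bin_width = 0.5)
  expect_equal(a20$n_pairs, 1L)
  expect_equal(a20$beta_values, 20, tolerance = 1e-9)
  expect_equal(sum(a20$data$beta_density) * a20$bin_width, 1,
               tolerance = 1e-6)
  # the complementary hydrogen-centred angle, against a vector oracle:
  # alpha = 180 - angle(H->O_d, H->O_a)
  p <- d20$frame$positions
  v1 <- p[1, ] - p[2, ]; v2 <- p[4, ] - p[2, ]
  alpha_oracle <- 180 -
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(a20$alpha_values, alpha_oracle, tolerance = 1e-9)

  # far-apart dimer: no qualifying pairs -> empty-distribution warning
  d9 <- dimer_frame(9, 0, box_edge = 30)
  expect_warning(angle_distribution(frame_to_traj(d9$frame), d9$topology),
                 "empty")
})
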