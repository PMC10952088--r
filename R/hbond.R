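# Hydrogen-bond detection with a smoothed two-switching-function criterion.
#
# Two rational "smoothed rectangle" functions are evaluated per candidate
# bond: one on the donor-acceptor O-O distance (centred on the first g_OO
# peak) and one on the path-length excess d' = |O_dH| + |HO_a| - |O_dO_a|,
# which is zero for a collinear bond and grows as the donor O-H direction
# tilts away from the O-O axis. A bond is counted when the product of the two
# functions exceeds a threshold (default 0.5).

#' Parameters of a smoothed rectangle switching function
#'
#' The switching function is the rational form
#' `f(d) = (1 - X^n) / (1 - X^m)` with `X = ((d - d0) / delta)^2`, which is 1
#' at `d = d0`, symmetric about `d0`, passes through `n/m` at
#' `|d - d0| = delta` (a removable singularity, evaluated as the limit), and
#' decays monotonically to zero outside the rectangle. Squaring the reduced
#' distance enforces the symmetry, so `n` and `m` need not be even.
#'
#' @param d0 centre of the rectangle (Angstrom).
#' @param delta half-width of the rectangle (Angstrom, > 0).
#' @param n,m positive integer exponents with `n < m`.
#' @return an object of class `aq_switch`.
#' @examples
#' sp <- switch_params(2.8, 0.45, 10, 16)
#' rect_switch(c(2.8, 3.25, 3.4), sp)
#' @export
switch_params <- function(d0, delta, n, m) {
  if (!is.numeric(delta) || delta <= 0) stop("`delta` must be positive")
  if (n <= 0 || m <= 0 || n != round(n) || m != round(m))
    stop("`n` and `m` must be positive integers")
  if (n >= m) stop("`n` must be smaller than `m`")
  structure(list(d0 = d0, delta = delta, n = as.integer(n), m = as.integer(m)),
            class = "aq_switch")
}

#' Evaluate a smoothed rectangle switching function
#'
#' @param d distance argument(s), Angstrom.
#' @param params an [switch_params()] object.
#' @return value(s) in `[0, 1]`.
#' @export
rect_switch <- function(d, params) {
  stopifnot(inherits(params, "aq_switch"))
  x2 <- ((d - params$d0) / params$delta)^2
  n <- params$n; m <- params$m
  num <- 1 - x2^n
  den <- 1 - x2^m
  out <- ifelse(abs(den) < 1e-12, n / m, num / den)
  out[!is.finite(out) & x2 > 1] <- 0   # x2^m overflow far outside the window
  out
}

#' Hydrogen-bond counting criterion
#'
#' Bundles the two switching functions and the product threshold. Defaults
#' are the liquid-water parameters: the O-O distance switch is centred on the
#' first g_OO peak (d0 = 2.8 A, half-width 0.45 A, exponents 10/16, covering
#' the 2.4--3.4 A first coordination shell) and the path-excess switch is
#' centred at zero (half-width 0.4 A, exponents 4/8, equal to 1 at 0 A and
#' decaying rapidly to 0 beyond about 0.5 A).
#'
#' @param dist_switch [switch_params()] for the donor-acceptor O-O distance.
#' @param path_switch [switch_params()] for the path-length excess d'.
#' @param threshold product threshold in (0, 1); a bond is counted when
#'   `f(d_OO) * f(d') > threshold`.
#' @return an object of class `aq_hbond_criterion`.
#' @export
hbond_criterion <- function(dist_switch = switch_params(2.8, 0.45, 10, 16),
                            path_switch = switch_params(0, 0.4, 4, 8),
                            threshold = 0.5) {
  stopifnot(inherits(dist_switch, "aq_switch"),
            inherits(path_switch, "aq_switch"))
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)")
  structure(list(dist_switch = dist_switch, path_switch = path_switch,
                 threshold = threshold),
            class = "aq_hbond_criterion")
}

#' Conventional distance-plus-angle hydrogen-bond criterion
#'
#' The classic geometric alternative: a bond is counted when the
#' donor-acceptor O-O distance is below `r_cut` and the angle between the
#' O_d -> O_a and O_d -> H directions is below `angle_max`.
#'
#' @param r_cut O-O distance cutoff (Angstrom).
#' @param angle_max maximal O_dO_a / O_dH angle (degrees).
#' @return an object of class `aq_hbond_conventional`.
#' @export
conventional_criterion <- function(r_cut = 3.5, angle_max = 30) {
  structure(list(r_cut = r_cut, angle_max = angle_max),
            class = "aq_hbond_conventional")
}

#' Path-length excess of a donor-H-acceptor triple
#'
#' Returns `|O_dH| + |HO_a| - |O_dO_a|` with all three distances taken under
#' the minimum-image convention: the triangle-inequality slack, zero iff H
#' lies on the O_d--O_a segment, growing as the donor O-H direction tilts.
#'
#' @param donor_o,h,acceptor_o length-3 coordinate vectors (Angstrom).
#' @param box_edge cubic box edge (Angstrom).
#' @return non-negative scalar (Angstrom).
#' @examples
#' excess_path_length(c(0, 0, 0), c(0.97, 0, 0), c(2.8, 0, 0), 20)
#' @export
excess_path_length <- function(donor_o, h, acceptor_o, box_edge) {
  nrm <- function(v) sqrt(sum(minimum_image(v, box_edge)^2))
  nrm(h - donor_o) + nrm(acceptor_o - h) - nrm(acceptor_o - donor_o)
}

# geometry of one candidate bond, vectorised over acceptor rows
hbond_geometry <- function(o_d, h, o_a, box_edge) {
  doh <- sqrt(sum(minimum_image(h - o_d, box_edge)^2))
  dho <- sqrt(rowSums(disp_to(h, o_a, box_edge)^2))
  doo <- sqrt(rowSums(disp_to(o_d, o_a, box_edge)^2))
  list(d_oo = doo, d_excess = doh + dho - doo)
}

#' Evaluate the hydrogen-bond criterion for one donor-H-acceptor candidate
#'
#' @param frame an [aq_frame()].
#' @param topology an [aq_topology()].
#' @param donor,acceptor molecule indices (rows of `topology$molecules`).
#' @param h atom index of the donating hydrogen; must be covalently bound to
#'   the donor molecule.
#' @param criterion an [hbond_criterion()].
#' @return a list with `bonded` (logical), `product`, `d_oo`, `d_excess`.
#' @export
is_hbonded <- function(frame, topology, donor, h, acceptor,
                       criterion = hbond_criterion()) {
  stopifnot(inherits(frame, "aq_frame"), inherits(topology, "aq_topology"))
  mol <- topology$molecules
  if (donor == acceptor) stop("donor and acceptor must differ")
  if (!h %in% mol[donor, c("H1", "H2")])
    stop("atom ", h, " is not a covalent hydrogen of donor molecule ", donor)
  o_d <- frame$positions[mol[donor, "O"], ]
  o_a <- frame$positions[mol[acceptor, "O"], , drop = FALSE]
  geo <- hbond_geometry(o_d, frame$positions[h, ], o_a, frame$box)
  prod <- rect_switch(geo$d_oo, criterion$dist_switch) *
    rect_switch(geo$d_excess, criterion$path_switch)
  list(bonded = prod > criterion$threshold, product = prod,
       d_oo = geo$d_oo, d_excess = geo$d_excess)
}

# All counted bonds in one frame: matrix with columns donor, h, acceptor,
# plus the product value. `method` "neighbour" prescreens acceptors by the
# O-O distance (beyond d0 + 2*delta the distance switch cannot reach the
# threshold); "brute" evaluates every ordered pair.
frame_hbonds <- function(frame, topology, criterion,
                         method = c("neighbour", "brute")) {
  method <- match.arg(method)
  mol <- topology$molecules
  nm <- nrow(mol)
  L <- frame$box
  o_pos <- frame$positions[mol[, "O"], , drop = FALSE]
  if (inherits(criterion, "aq_hbond_conventional")) {
    cutoff <- criterion$r_cut
  } else {
    cutoff <- criterion$dist_switch$d0 + 2 * criterion$dist_switch$delta
  }
  doo <- pair_distances(o_pos, o_pos, L)
  res <- list(); nres <- 0L
  for (i in seq_len(nm)) {
    acc <- if (method == "neighbour") {
      which(doo[i, ] < cutoff & seq_len(nm) != i)
    } else {
      setdiff(seq_len(nm), i)
    }
    if (length(acc) == 0L) next
    o_a <- o_pos[acc, , drop = FALSE]
    for (hcol in c("H1", "H2")) {
      h_idx <- mol[i, hcol]
      hp <- frame$positions[h_idx, ]
      if (inherits(criterion, "aq_hbond_conventional")) {
        d_oa <- doo[i, acc]
        u_oh <- minimum_image(hp - o_pos[i, ], L)
        v_oa <- disp_to(o_pos[i, ], o_a, L)
        cosang <- (v_oa %*% u_oh) /
          (sqrt(sum(u_oh^2)) * sqrt(rowSums(v_oa^2)))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        ok <- d_oa < criterion$r_cut & ang < criterion$angle_max
        pv <- as.numeric(ok)
      } else {
        geo <- hbond_geometry(o_pos[i, ], hp, o_a, L)
        pv <- rect_switch(geo$d_oo, criterion$dist_switch) *
          rect_switch(geo$d_excess, criterion$path_switch)
        ok <- pv > criterion$threshold
      }
      sel <- which(ok)
      if (length(sel) > 0L) {
        nres <- nres + 1L
        res[[nres]] <- cbind(donor = i, h = h_idx, acceptor = acc[sel],
                             product = pv[sel])
      }
    }
  }
  if (nres == 0L)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("donor", "h", "acceptor", "product"))))
  do.call(rbind, res)
}

#' Hydrogen-bond statistics over a trajectory
#'
#' Counts hydrogen bonds in every frame (each bond is a (donor H, acceptor O)
#' realisation, counted at most once) and reports per-molecule participation:
#' a molecule's count is the number of bonds it donates plus the number it
#' accepts, so the trajectory average `h` credits each bond to both partners
#' (`h = 2 * bonds / n_mol` averaged over frames).
#'
#' @param traj an [aq_trajectory()].
#' @param topology an [aq_topology()].
#' @param criterion an [hbond_criterion()] (smoothed product criterion) or
#'   [conventional_criterion()] (distance + angle).
#' @param frames optional frame indices.
#' @param method `"neighbour"` (O-O distance prescreen, default) or
#'   `"brute"` (all ordered pairs; the test oracle).
#' @return an object of class `aq_hbond`: per-frame per-molecule counts,
#'   donated/accepted breakdown, and the average `h`.
#' @examples
#' ice <- make_tetrahedral_ice(1, seed = 2)
#' traj <- aq_trajectory(array(ice$frame$positions,
#'                             c(1, nrow(ice$frame$positions), 3)),
#'                       ice$frame$elements, ice$frame$box)
#' glance(hbond_stats(traj, ice$topology))$h
#' @export
hbond_stats <- function(traj, topology, criterion = hbond_criterion(),
                        frames = NULL, method = c("neighbour", "brute")) {
  stopifnot(inherits(traj, "aq_traj"), inherits(topology, "aq_topology"))
  method <- match.arg(method)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nm <- n_molecules(topology)
  donated <- matrix(0L, length(frames), nm)
  accepted <- matrix(0L, length(frames), nm)
  products <- list()
  for (j in seq_along(frames)) {
    fr <- get_frame(traj, frames[j])
    hb <- frame_hbonds(fr, topology, criterion, method)
    if (nrow(hb) > 0L) {
      donated[j, ] <- tabulate(hb[, "donor"], nm)
      accepted[j, ] <- tabulate(hb[, "acceptor"], nm)
    }
    products[[j]] <- hb[, "product"]
  }
  total <- donated + accepted
  structure(
    list(donated = donated, accepted = accepted, total = total,
         frames = frames, h = mean(rowMeans(total)),
         h_donated = mean(rowMeans(donated)),
         products = unlist(products), criterion = criterion),
    class = "aq_hbond"
  )
}

#' @export
print.aq_hbond <- function(x, ...) {
  cat("<aq_hbond> ", length(x$frames), " frames x ", ncol(x$total),
      " molecules: h = ", format(x$h, digits = 4),
      " H-bonds per molecule\n", sep = "")
  invisible(x)
}

#' Hydrogen-bond angle distributions
#'
#' Histograms the H-bonding angle beta -- the angle at the donor oxygen
#' between the O_d -> H and O_d -> O_a directions -- over all (H, acceptor)
#' pairs within the first coordination shell (donor-acceptor distance below
#' `cutoff_OO` and hydrogen-acceptor distance below `cutoff_HO`), normalised
#' to unit integral. The complementary hydrogen-centred angle
#' `alpha = 180 deg - angle(O_d-H-O_a)` is histogrammed alongside.
#'
#' @param traj an [aq_trajectory()].
#' @param topology an [aq_topology()].
#' @param cutoff_OO donor-acceptor distance cutoff (Angstrom, default 3.4).
#' @param cutoff_HO hydrogen-acceptor distance cutoff (Angstrom, default 2.5).
#' @param bin_width histogram bin width in degrees.
#' @param frames optional frame indices.
#' @return an object of class `aq_angledist` with a `data` tibble
#'   (`angle`, `beta_density`, `alpha_density` on a 0--90 degree grid) and the
#'   cutoffs used. Densities integrate to 1 over degrees; with no qualifying
#'   pairs a warning is issued and the densities are zero.
#' @export
angle_distribution <- function(traj, topology, cutoff_OO = 3.4,
                               cutoff_HO = 2.5, bin_width = 1,
                               frames = NULL) {
  stopifnot(inherits(traj, "aq_traj"), inherits(topology, "aq_topology"))
  if (cutoff_OO <= 0 || cutoff_HO <= 0) stop("cutoffs must be positive")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  mol <- topology$molecules
  nm <- nrow(mol)
  L <- traj$box
  betas <- list(); alphas <- list(); nacc <- 0L
  for (k in frames) {
    fr <- get_frame(traj, k)
    o_pos <- fr$positions[mol[, "O"], , drop = FALSE]
    doo <- pair_distances(o_pos, o_pos, L)
    for (i in seq_len(nm)) {
      acc <- which(doo[i, ] < cutoff_OO & seq_len(nm) != i)
      if (length(acc) == 0L) next
      for (hcol in c("H1", "H2")) {
        hp <- fr$positions[mol[i, hcol], ]
        v_oh <- minimum_image(hp - o_pos[i, ], L)
        o_a <- o_pos[acc, , drop = FALSE]
        v_ha <- disp_to(hp, o_a, L)
        d_ha <- sqrt(rowSums(v_ha^2))
        sel <- which(d_ha < cutoff_HO)
        if (length(sel) == 0L) next
        v_oa <- disp_to(o_pos[i, ], o_a[sel, , drop = FALSE], L)
        cosb <- (v_oa %*% v_oh) /
          (sqrt(sum(v_oh^2)) * sqrt(rowSums(v_oa^2)))
        beta <- acos(pmin(1, pmax(-1, cosb))) * 180 / pi
        v_ho <- v_ha[sel, , drop = FALSE]
        cosoho <- (v_ho %*% (-v_oh)) /
          (sqrt(sum(v_oh^2)) * sqrt(rowSums(v_ho^2)))
        alpha <- 180 - acos(pmin(1, pmax(-1, cosoho))) * 180 / pi
        nacc <- nacc + 1L
        betas[[nacc]] <- as.numeric(beta)
        alphas[[nacc]] <- as.numeric(alpha)
      }
    }
  }
  beta <- unlist(betas); alpha <- unlist(alphas)
  edges <- seq(0, 90, by = bin_width)
  grid <- edges[-1] - bin_width / 2
  hist_density <- function(v) {
    if (length(v) == 0L) return(numeric(length(grid)))
    v <- v[v >= 0 & v <= 90]
    counts <- tabulate(pmin(length(grid), floor(v / bin_width) + 1L),
                       nbins = length(grid))
    counts / (length(v) * bin_width)
  }
  if (length(beta) == 0L)
    warning("no (H, acceptor) pairs passed the cutoffs; empty distribution")
  structure(
    list(data = tibble::tibble(angle = grid,
                               beta_density = hist_density(beta),
                               alpha_density = hist_density(alpha)),
         cutoff_OO = cutoff_OO, cutoff_HO = cutoff_HO,
         n_pairs = length(beta), bin_width = bin_width,
         beta_values = beta, alpha_values = alpha),
    class = "aq_angledist"
  )
}

#' @export
print.aq_angledist <- function(x, ...) {
  cat("<aq_angledist> ", x$n_pairs, " qualifying (H, acceptor) pairs; ",
      "cutoffs O-O < ", x$cutoff_OO, " A, H-O < ", x$cutoff_HO, " A\n",
      sep = "")
  invisible(x)
}
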