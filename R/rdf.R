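# Radial distribution functions and first-shell descriptors.
#
# Normalisation uses the actual pair-type counts (N(N-1)/2 for same-species,
# N_A * N_B for distinct species) and the box volume, which makes the
# ideal-gas limit exactly 1. Extrema are located on a cubic-spline
# interpolant of the binned curve; the coordination number integrates
# 4 pi rho r^2 g(r) on the same interpolant.

#' Compute a radial distribution function
#'
#' Histograms minimum-image pair distances for one pair type (OO, OH or HH)
#' over the frames of a trajectory and normalises each bin by the ideal-gas
#' shell expectation for the same pair counts and box volume.
#'
#' Intramolecular O-H and H-H pairs are included by default (matching
#' experimental g_OH with its covalent peak); set `exclude_intramolecular`
#' (which requires `topology`) to drop them.
#'
#' @param traj an [aq_trajectory()].
#' @param pair one of `"OO"`, `"OH"`, `"HH"`.
#' @param topology an [aq_topology()]; only needed when
#'   `exclude_intramolecular = TRUE`.
#' @param bin_width histogram bin width in Angstrom (default 0.01).
#' @param r_max histogram range; defaults to L/2 and must not exceed it (the
#'   minimum image is invalid beyond half the box).
#' @param exclude_intramolecular drop pairs within one molecule.
#' @param frames optional integer vector of frame indices to use.
#' @return an object of class `aq_rdf`: a list with a `data` tibble
#'   (`r`, `g`) plus the pair type, bin width, molecular number density
#'   `rho` (N_mol/V), the partner-species density used for coordination
#'   integrals, and the frame count.
#' @examples
#' ig <- ideal_gas_trajectory(32, 12, n_frames = 5, seed = 1)
#' rdf <- compute_rdf(ig, pair = "OO", bin_width = 0.1)
#' mean(rdf$data$g[rdf$data$r > 2])
#' @export
compute_rdf <- function(traj, pair = c("OO", "OH", "HH"), topology = NULL,
                        bin_width = 0.01, r_max = NULL,
                        exclude_intramolecular = FALSE, frames = NULL) {
  stopifnot(inherits(traj, "aq_traj"))
  pair <- match.arg(pair)
  L <- traj$box
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-9)
    stop("r_max (", r_max, " A) exceeds half the box edge (", L / 2,
         " A); the minimum image is invalid beyond L/2")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))

  el <- traj$elements
  hyd <- el %in% c("H", "D")
  idx_a <- switch(pair, OO = which(el == "O"), OH = which(el == "O"),
                  HH = which(hyd))
  idx_b <- switch(pair, OO = which(el == "O"), OH = which(hyd),
                  HH = which(hyd))
  same <- pair != "OH"
  if (length(idx_a) < ifelse(same, 2L, 1L) || length(idx_b) < 1L)
    stop("not enough atoms of the requested species for pair ", pair)

  intra <- NULL
  if (exclude_intramolecular) {
    if (is.null(topology))
      stop("`topology` is required when excluding intramolecular pairs")
    mol_of <- integer(length(el))
    mol <- topology$molecules
    for (m in seq_len(nrow(mol))) mol_of[mol[m, ]] <- m
    intra <- outer(mol_of[idx_a], mol_of[idx_b], "==")
  }

  # only complete bins: a trailing partial bin cannot be filled out to its
  # full shell volume and would bias g low there
  nbin <- floor(r_max / bin_width + 1e-9)
  r_max <- nbin * bin_width
  counts <- numeric(nbin)
  n_pairs <- 0
  for (k in frames) {
    pa <- traj$coords[k, idx_a, , drop = FALSE][1, , , drop = TRUE]
    pb <- traj$coords[k, idx_b, , drop = FALSE][1, , , drop = TRUE]
    pa <- matrix(pa, length(idx_a), 3)
    pb <- matrix(pb, length(idx_b), 3)
    d <- pair_distances(pa, pb, L)
    keep <- if (same) upper.tri(d) else matrix(TRUE, nrow(d), ncol(d))
    if (!is.null(intra)) keep <- keep & !intra
    dv <- d[keep]
    n_pairs <- sum(keep)
    dv <- dv[dv < r_max & dv > 0]
    bins <- pmin.int(nbin, floor(dv / bin_width) + 1L)
    counts <- counts + tabulate(bins, nbins = nbin)
  }
  V <- L^3
  edges <- bin_width * (0:nbin)
  shell <- 4 / 3 * pi * diff(edges^3)
  expected <- length(frames) * n_pairs * shell / V
  g <- counts / expected
  r_mid <- edges[-1] - bin_width / 2

  n_b <- length(idx_b)
  rho_partner <- (if (same) n_b - 1L else n_b) / V
  structure(
    list(data = tibble::tibble(r = r_mid, g = g),
         pair = pair, bin_width = bin_width, r_max = r_max,
         rho = sum(el == "O") / V, rho_partner = rho_partner,
         n_frames = length(frames), box = L,
         exclude_intramolecular = exclude_intramolecular),
    class = "aq_rdf"
  )
}

#' @export
print.aq_rdf <- function(x, ...) {
  cat("<aq_rdf> g_", x$pair, "(r): ", nrow(x$data), " bins of ",
      x$bin_width, " A over ", x$n_frames, " frames (rho* = ",
      format(x$rho, digits = 4), " / A^3)\n", sep = "")
  invisible(x)
}

# Cubic-spline interpolant of a binned curve ("fmm" reproduces polynomial
# data exactly up to cubics).
rdf_spline <- function(r, y) splinefun(r, y, method = "fmm")

# Locate the first interior maximum and the following minimum of a smooth
# interpolant of (r, y). Discrete extrema bracket the spline-derivative root.
# Candidate maxima must rise at least 5% of the curve's range above its
# minimum, which rejects sub-epsilon float plateaus and baseline ripple.
first_max_then_min <- function(r, y) {
  s <- rdf_spline(r, y)
  n <- length(y)
  lo <- min(y)
  prom <- lo + 0.05 * (max(y) - lo)
  imax <- NA_integer_
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] > prom) {
      imax <- i
      break
    }
  }
  if (is.na(imax)) stop("no first peak: curve has no interior maximum")
  refine <- function(i) {
    lo <- r[max(1, i - 1)]; hi <- r[min(n, i + 1)]
    dlo <- s(lo, deriv = 1); dhi <- s(hi, deriv = 1)
    if (is.finite(dlo) && is.finite(dhi) && dlo * dhi < 0)
      uniroot(function(t) s(t, deriv = 1), c(lo, hi), tol = 1e-10)$root
    else r[i]
  }
  r_max1 <- refine(imax)
  imin <- NA_integer_
  if (imax + 1 <= n - 1) {
    for (i in (imax + 1):(n - 1)) {
      if (y[i] < y[i - 1] && y[i] <= y[i + 1]) { imin <- i; break }
    }
  }
  if (is.na(imin))
    return(list(r_max1 = r_max1, g_max1 = s(r_max1),
                r_min1 = NA_real_, g_min1 = NA_real_))
  r_min1 <- refine(imin)
  list(r_max1 = r_max1, g_max1 = s(r_max1), r_min1 = r_min1, g_min1 = s(r_min1))
}

#' Locate the first-shell extrema of an RDF
#'
#' Finds the position and height of the first maximum and first minimum of
#' g(r), and the position `r_c` of the first minimum of the coordination
#' integrand r^2 g(r), on cubic-spline interpolants of the binned curve
#' (extrema are bracketed by the discrete extrema and refined on the spline's
#' analytic derivative).
#'
#' @param rdf an `aq_rdf`.
#' @param temperature simulation temperature in K, carried along for
#'   rescaling (optional).
#' @return an object of class `aq_peaks` with fields `r_max1`, `g_max1`,
#'   `r_min1`, `g_min1`, `r_c`, `temperature`.
#' @export
find_first_extrema <- function(rdf, temperature = NA_real_) {
  stopifnot(inherits(rdf, "aq_rdf"))
  r <- rdf$data$r; g <- rdf$data$g
  ex <- first_max_then_min(r, g)
  ex2 <- first_max_then_min(r, r^2 * g)
  structure(
    list(r_max1 = ex$r_max1, g_max1 = ex$g_max1,
         r_min1 = ex$r_min1, g_min1 = ex$g_min1,
         r_c = ex2$r_min1, temperature = temperature, pair = rdf$pair),
    class = "aq_peaks"
  )
}

#' @export
print.aq_peaks <- function(x, ...) {
  cat("<aq_peaks> first g_", x$pair, " maximum at ",
      format(x$r_max1, digits = 4), " A (height ",
      format(x$g_max1, digits = 4), "), first minimum at ",
      format(x$r_min1, digits = 4), " A (height ",
      format(x$g_min1, digits = 4), "); r_c = ",
      format(x$r_c, digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Coordination number from an RDF
#'
#' Integrates `4 pi rho r^2 g(r)` from 0 to a first-shell cutoff on a
#' cubic-spline interpolant of the binned g(r). The cutoff convention is
#' either the first minimum of the actual integrand r^2 g(r) (`"r2g_min"`,
#' the convention used for comparison with experiment), the first minimum of
#' g(r) itself (`"g_min"`), or a fixed cutoff in Angstrom (`"fixed"`, with
#' `cutoff`).
#'
#' @param rdf an `aq_rdf`.
#' @param convention cutoff convention (see above).
#' @param cutoff fixed cutoff in Angstrom, for `convention = "fixed"`.
#' @param rho number density (1/Angstrom^3) to integrate against; defaults to
#'   the finite-N partner density stored in the RDF, which makes neighbour
#'   counts on gapped shell structures exact. Pass `N/V` explicitly to use
#'   the bulk molecular density of the textbook formula.
#' @param method `"histogram"` (default) integrates the binned g(r) exactly
#'   with the shell volumes of each bin (a partial last bin is taken in
#'   r^3 proportion), which reproduces discrete neighbour counts exactly;
#'   `"spline"` integrates the cubic-spline interpolant. On smooth curves the
#'   two differ negligibly.
#' @return the coordination number (scalar).
#' @examples
#' ice <- make_tetrahedral_ice(2, a_OO = 2.75, seed = 3)
#' traj <- aq_trajectory(array(ice$frame$positions,
#'                             c(1, nrow(ice$frame$positions), 3)),
#'                       ice$frame$elements, ice$frame$box)
#' rdf <- compute_rdf(traj, "OO", bin_width = 0.05)
#' coordination_number(rdf, "fixed", cutoff = 3.4)
#' @export
coordination_number <- function(rdf,
                                convention = c("r2g_min", "g_min", "fixed"),
                                cutoff = NULL, rho = NULL,
                                method = c("histogram", "spline")) {
  stopifnot(inherits(rdf, "aq_rdf"))
  convention <- match.arg(convention)
  method <- match.arg(method)
  r_c <- switch(convention,
    fixed = {
      if (is.null(cutoff)) stop("`cutoff` required for the fixed convention")
      cutoff
    },
    g_min = find_first_extrema(rdf)$r_min1,
    r2g_min = find_first_extrema(rdf)$r_c
  )
  if (is.na(r_c)) stop("no first minimum found to set the integration cutoff")
  if (r_c > rdf$r_max + 1e-9)
    stop("cutoff ", format(r_c), " A lies beyond the RDF range (",
         rdf$r_max, " A)")
  if (is.null(rho)) rho <- rdf$rho_partner
  if (method == "spline") {
    s <- rdf_spline(rdf$data$r, rdf$data$g)
    return(integrate(function(t) 4 * pi * rho * t^2 * pmax(0, s(t)),
                     lower = 0, upper = r_c, subdivisions = 2000L,
                     rel.tol = 1e-8)$value)
  }
  bw <- rdf$bin_width
  lo <- rdf$data$r - bw / 2
  hi <- pmin(rdf$data$r + bw / 2, r_c)
  sel <- lo < r_c
  shell <- 4 / 3 * pi * (hi[sel]^3 - lo[sel]^3)
  sum(rho * shell * rdf$data$g[sel])
}

#' Rescale a first-shell descriptor to a 298 K reference
#'
#' Simulations run at slightly different temperatures; to compare their
#' first-peak descriptors on a common footing, a least-squares polynomial
#' (default degree 1) is fitted through a user-supplied reference table of
#' descriptor values versus temperature, and the simulated value is shifted
#' by the fitted difference between the simulation temperature and 298 K:
#' `value - fit(T_sim) + fit(298)`.
#'
#' @param value descriptor value at `T_sim`.
#' @param descriptor column name in `ref_table` (e.g. `"r_max1"`, `"g_max1"`,
#'   `"r_min1"`, `"g_min1"`).
#' @param T_sim simulation temperature (K).
#' @param ref_table data frame with a `temperature` column (strictly
#'   increasing, at least two rows) and one column per descriptor. See
#'   [read_reference_table()].
#' @param degree polynomial degree of the fit (default 1).
#' @param T_ref reference temperature (default 298 K).
#' @return the rescaled descriptor value.
#' @export
rescale_descriptor_to_298K <- function(value, descriptor, T_sim, ref_table,
                                       degree = 1L, T_ref = 298) {
  if (!is.data.frame(ref_table) || nrow(ref_table) < 2L)
    stop("`ref_table` must be a data frame with at least two rows")
  if (!"temperature" %in% names(ref_table))
    stop("`ref_table` must have a `temperature` column")
  if (any(diff(ref_table$temperature) <= 0))
    stop("reference temperatures must be strictly increasing")
  if (!descriptor %in% names(ref_table))
    stop("descriptor '", descriptor, "' not found in the reference table")
  rng <- range(ref_table$temperature)
  if (T_sim < rng[1] - 30 || T_sim > rng[2] + 30)
    warning("T_sim = ", T_sim, " K extrapolates more than 30 K beyond the ",
            "reference range [", rng[1], ", ", rng[2], "] K")
  fit <- lm(y ~ poly(x, degree, raw = TRUE),
            data = data.frame(x = ref_table$temperature,
                              y = ref_table[[descriptor]]))
  pred <- function(t) unname(predict(fit, newdata = data.frame(x = t)))
  value - pred(T_sim) + pred(T_ref)
}

#' Read a descriptor reference table from CSV
#'
#' The file must have a header row with a `temperature` column (K) and one
#' column per descriptor. The package ships a synthetic example table at
#' `system.file("extdata", "reference_descriptors_synthetic.csv",
#' package = "aquatraj")`; it is generated data illustrating the format, not
#' digitised experimental values.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_reference_table <- function(path) {
  tab <- tibble::as_tibble(read.csv(path))
  if (!"temperature" %in% names(tab))
    stop("reference table must have a `temperature` column")
  tab
}
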