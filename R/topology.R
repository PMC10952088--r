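# Water topology: assignment of hydrogens to their covalent oxygens under
# periodic boundary conditions. Deuterium ("D") is treated as hydrogen with a
# different mass label; geometry is identical.

#' Construct a water topology object
#'
#' @param molecules integer matrix with one row per molecule and columns
#'   `O`, `H1`, `H2` giving atom indices into the frame.
#' @param mass_h hydrogen mass in amu used for centre-of-mass conventions
#'   (1.008 for H, 2.014 for D).
#' @return an object of class `aq_topology`.
#' @export
aq_topology <- function(molecules, mass_h = aq_constants$mass_H) {
  molecules <- as.matrix(molecules)
  if (ncol(molecules) != 3L) stop("`molecules` must have columns O, H1, H2")
  storage.mode(molecules) <- "integer"
  if (anyDuplicated(c(molecules)))
    stop("atom indices shared between molecules")
  colnames(molecules) <- c("O", "H1", "H2")
  structure(list(molecules = molecules, mass_h = mass_h),
            class = "aq_topology")
}

#' @export
print.aq_topology <- function(x, ...) {
  cat("<aq_topology> ", nrow(x$molecules), " water molecules (mass_H = ",
      x$mass_h, " amu)\n", sep = "")
  invisible(x)
}

#' Number of molecules in a topology
#' @param topology an `aq_topology`.
#' @export
n_molecules <- function(topology) nrow(topology$molecules)

#' Assign water topology from a frame
#'
#' Attaches every hydrogen (or deuterium) to its nearest oxygen under the
#' minimum-image convention, so that molecules straddling a periodic face are
#' assembled correctly. The assignment must satisfy the water invariants:
#' every O carries exactly two H, and every covalent O--H minimum-image
#' distance is below `max_oh`.
#'
#' @param frame an [aq_frame()] containing only O and H (or D) atoms with
#'   twice as many hydrogens as oxygens.
#' @param max_oh upper bound on the covalent O--H minimum-image distance in
#'   Angstrom. The default 1.25 A accommodates stretched bonds while rejecting
#'   hydrogen-bond partners (1.7--2 A).
#' @param mass_h hydrogen mass convention passed to [aq_topology()]; by
#'   default inferred from the element labels (D gives the deuterium mass).
#' @return an `aq_topology`.
#' @examples
#' f <- aq_frame(rbind(c(0, 0, 0), c(0.97, 0, 0), c(-0.24, 0.94, 0)),
#'               c("O", "H", "H"), box_edge = 10)
#' assign_water_topology(f)
#' @export
assign_water_topology <- function(frame, max_oh = 1.25, mass_h = NULL) {
  stopifnot(inherits(frame, "aq_frame"))
  el <- frame$elements
  o_idx <- which(el == "O")
  h_idx <- which(el %in% c("H", "D"))
  if (length(o_idx) + length(h_idx) != length(el))
    stop("frame contains elements other than O, H, D: ",
         paste(unique(setdiff(el, c("O", "H", "D"))), collapse = ", "))
  if (length(h_idx) != 2L * length(o_idx))
    stop("expected 2 hydrogens per oxygen; found ", length(h_idx), " H for ",
         length(o_idx), " O")
  if (is.null(mass_h))
    mass_h <- if (any(el == "D")) aq_constants$mass_D else aq_constants$mass_H

  d <- pair_distances(frame$positions[h_idx, , drop = FALSE],
                      frame$positions[o_idx, , drop = FALSE], frame$box)
  nearest <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_along(h_idx), nearest)]
  too_far <- which(dmin > max_oh)
  if (length(too_far) > 0L)
    stop("hydrogens ", paste(h_idx[too_far], collapse = ", "),
         " have no oxygen within the covalent bound (", max_oh, " A); ",
         "nearest O--H distance ", format(min(dmin[too_far]), digits = 4), " A")
  counts <- tabulate(nearest, nbins = length(o_idx))
  bad <- which(counts != 2L)
  if (length(bad) > 0L)
    stop("oxygens ", paste(o_idx[bad], collapse = ", "),
         " have ", paste(counts[bad], collapse = ", "),
         " assigned hydrogens (expected exactly 2 each)")
  mol <- t(vapply(seq_along(o_idx), function(i) {
    hs <- h_idx[which(nearest == i)]
    c(o_idx[i], hs[1], hs[2])
  }, integer(3)))
  aq_topology(mol, mass_h = mass_h)
}

# Per-molecule centres of mass for one frame (n_mol x 3), with each molecule
# made whole via minimum image around its oxygen before averaging.
com_positions <- function(frame, topology) {
  mol <- topology$molecules
  mO <- aq_constants$mass_O
  mH <- topology$mass_h
  mtot <- mO + 2 * mH
  o <- frame$positions[mol[, 1], , drop = FALSE]
  h1 <- o + minimum_image(frame$positions[mol[, 2], , drop = FALSE] - o, frame$box)
  h2 <- o + minimum_image(frame$positions[mol[, 3], , drop = FALSE] - o, frame$box)
  (mO * o + mH * h1 + mH * h2) / mtot
}
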