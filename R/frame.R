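# Core containers: a single configuration (aq_frame) and a time-ordered
# trajectory (aq_traj). Coordinates are stored as numeric matrices/arrays in
# Angstrom; frame spacing in ps.

#' Create a single-configuration frame
#'
#' A frame holds per-atom Cartesian coordinates (Angstrom), element symbols,
#' and the edge length of the cubic periodic box.
#'
#' @param positions numeric matrix, one row per atom, three columns (Angstrom).
#' @param elements character vector of atomic symbols, one per atom.
#' @param box_edge cubic box edge length L in Angstrom (positive).
#' @param time optional time stamp in ps.
#' @return an object of class `aq_frame`.
#' @examples
#' f <- aq_frame(rbind(c(0, 0, 0), c(0.97, 0, 0)), c("O", "H"), box_edge = 10)
#' f$box
#' @export
aq_frame <- function(positions, elements, box_edge, time = NA_real_) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (ncol(positions) != 3L)
    stop("`positions` must have three columns (x, y, z)")
  if (nrow(positions) != length(elements))
    stop("`positions` has ", nrow(positions), " rows but `elements` has length ",
         length(elements))
  if (!all(is.finite(positions)))
    stop("all coordinates must be finite")
  if (!is.numeric(box_edge) || length(box_edge) != 1L || !is.finite(box_edge) ||
      box_edge <= 0)
    stop("`box_edge` must be a single positive number")
  structure(
    list(positions = positions, elements = as.character(elements),
         box = as.numeric(box_edge), time = as.numeric(time)),
    class = "aq_frame"
  )
}

#' @export
print.aq_frame <- function(x, ...) {
  cat("<aq_frame> ", nrow(x$positions), " atoms, box edge ",
      format(x$box), " A\n", sep = "")
  invisible(x)
}

#' Create a trajectory from a coordinate array
#'
#' A trajectory stores the time-ordered coordinates of a fixed set of atoms in
#' a cubic periodic box, as a `n_frames x n_atoms x 3` array in Angstrom.
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param elements character vector of atomic symbols (length `n_atoms`).
#' @param box_edge cubic box edge L (Angstrom).
#' @param dt frame spacing in ps (`NA` if unknown).
#' @param times optional explicit frame times (ps), strictly increasing.
#' @param meta named list of provenance metadata (generator name, parameters,
#'   seed, source file, ...).
#' @return an object of class `aq_traj`.
#' @export
aq_trajectory <- function(coords, elements, box_edge, dt = NA_real_,
                          times = NULL, meta = list()) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("`coords` must be an n_frames x n_atoms x 3 array")
  storage.mode(coords) <- "double"
  if (dim(coords)[2] != length(elements))
    stop("`elements` length must match the number of atoms")
  if (!is.numeric(box_edge) || box_edge <= 0 || !is.finite(box_edge))
    stop("`box_edge` must be a single positive number")
  if (!is.null(times)) {
    if (length(times) != dim(coords)[1])
      stop("`times` must have one entry per frame")
    if (any(diff(times) <= 0))
      stop("frame times must be strictly increasing")
  }
  structure(
    list(coords = coords, elements = as.character(elements),
         box = as.numeric(box_edge), dt = as.numeric(dt), times = times,
         meta = meta),
    class = "aq_traj"
  )
}

#' @export
print.aq_traj <- function(x, ...) {
  cat("<aq_traj> ", n_frames(x), " frames x ", n_atoms(x), " atoms, box edge ",
      format(x$box), " A, dt = ", format(x$dt), " ps\n", sep = "")
  if (!is.null(x$meta$generator))
    cat("  generator: ", x$meta$generator, "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `aq_traj`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame of a trajectory
#'
#' @param traj an `aq_traj`.
#' @param i frame index (1-based).
#' @return an `aq_frame`.
#' @export
get_frame <- function(traj, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index ", i, " out of range")
  tm <- if (!is.null(traj$times)) traj$times[i]
        else if (is.finite(traj$dt)) (i - 1L) * traj$dt else NA_real_
  aq_frame(traj$coords[i, , , drop = TRUE], traj$elements, traj$box, time = tm)
}

#' Frame times of a trajectory
#' @param traj an `aq_traj`.
#' @return numeric vector of times in ps (from explicit times or frame spacing).
#' @export
frame_times <- function(traj) {
  if (!is.null(traj$times)) return(traj$times)
  (seq_len(n_frames(traj)) - 1L) * traj$dt
}

#' Map displacement components to the minimum image
#'
#' Each component is mapped into the half-open interval `(-L/2, L/2]`; a
#' component exactly equal to `L/2` is returned as `+L/2` (deterministic
#' tie-break on the positive side).
#'
#' @param v numeric vector, matrix, or array of displacement components
#'   (Angstrom).
#' @param box_edge cubic box edge L (Angstrom, positive).
#' @return object of the same shape with every component in `(-L/2, L/2]`.
#' @examples
#' minimum_image(c(0.9, 0.4, 0.5) * 10, 10)
#' @export
minimum_image <- function(v, box_edge) {
  if (!is.numeric(box_edge) || box_edge <= 0)
    stop("`box_edge` must be positive")
  v - box_edge * ceiling(v / box_edge - 0.5)
}

# Minimum-image distances between two coordinate sets (na x 3, nb x 3).
# Returns the na x nb distance matrix.
pair_distances <- function(a, b, box_edge) {
  dx <- minimum_image(outer(a[, 1], b[, 1], "-"), box_edge)
  dy <- minimum_image(outer(a[, 2], b[, 2], "-"), box_edge)
  dz <- minimum_image(outer(a[, 3], b[, 3], "-"), box_edge)
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Minimum-image displacement vectors from point a (length-3) to rows of b.
disp_to <- function(a, b, box_edge) {
  minimum_image(sweep(b, 2, a, "-"), box_edge)
}
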