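# Trajectory file I/O. Supported dialects:
#  * multi-frame XYZ (atom count line / comment line / "El x y z" records,
#    coordinates in Angstrom);
#  * CPMD-style TRAJECTORY files (one line per atom per step: step index then
#    x y z [vx vy vz], positions in Bohr, no element symbols).
# Neither format stores the box edge or the frame spacing, so both are
# supplied by the caller.

#' Read a multi-frame XYZ trajectory
#'
#' @param path path to an XYZ file. Each frame block is an atom-count header
#'   line, a comment line, then one `element x y z` record per atom
#'   (coordinates in Angstrom).
#' @param box_edge cubic box edge L in Angstrom (the XYZ format does not store
#'   it).
#' @param frame_spacing frame spacing in ps (optional).
#' @return an [aq_trajectory()].
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("2", "frame 0", "O 0 0 0", "H 0.97 0 0"), f)
#' traj <- read_xyz_trajectory(f, box_edge = 10)
#' n_frames(traj)
#' @export
read_xyz_trajectory <- function(path, box_edge, frame_spacing = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(box_edge) || is.null(box_edge) || !is.numeric(box_edge) ||
      length(box_edge) != 1L || box_edge <= 0)
    stop("a positive cubic `box_edge` must be supplied (XYZ stores no box)")
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  frames <- list()
  elems <- NULL
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    fidx <- fidx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0L)
      stop("frame ", fidx, ": malformed atom-count line '", lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("frame ", fidx, ": declares ", nat, " atoms but file ends early")
    rec <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(rec), "\\s+")
    bad <- which(vapply(tok, length, 1L) < 4L)
    if (length(bad) > 0L)
      stop("frame ", fidx, ": malformed atom record at line ", i + 1L + bad[1])
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("frame ", fidx, ": non-numeric coordinates")
    if (is.null(elems)) elems <- el
    else if (!identical(elems, el))
      stop("frame ", fidx, ": element order differs from frame 1")
    frames[[fidx]] <- xyz
    i <- i + 2L + nat
    # a block must be followed by another count line or EOF
    if (i <= length(lines)) {
      nxt <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(nxt))
        stop("frame ", fidx, ": trailing records beyond declared atom count")
    }
  }
  if (fidx == 0L)
    return(aq_trajectory(array(0, c(0L, 0L, 3L)), character(0), box_edge,
                         dt = frame_spacing, meta = list(source = path)))
  coords <- array(0, c(fidx, length(elems), 3L))
  for (k in seq_len(fidx)) coords[k, , ] <- frames[[k]]
  aq_trajectory(coords, elems, box_edge, dt = frame_spacing,
                meta = list(source = path, format = "xyz"))
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are written in Angstrom with six decimal places, so
#' `read_xyz_trajectory(write_xyz_trajectory(traj, f), ...)` round-trips to
#' 1e-6 Angstrom.
#'
#' @param traj an [aq_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "aq_traj"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  for (k in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d", k), con)
    writeLines(sprintf("%s %14.6f %14.6f %14.6f", traj$elements,
                       traj$coords[k, , 1], traj$coords[k, , 2],
                       traj$coords[k, , 3]), con)
  }
  invisible(path)
}

#' Read a CPMD-style TRAJECTORY file
#'
#' The format holds one line per atom per saved step: the MD step index
#' followed by x, y, z (and optionally velocities, ignored), all in atomic
#' units. It stores no element symbols, so the per-step element order is
#' supplied by the caller. Positions are converted from Bohr to Angstrom on
#' ingest.
#'
#' @param path path to the TRAJECTORY file.
#' @param element_order character vector giving the element of each atom
#'   within one step, in file order.
#' @param box_edge cubic box edge in Angstrom.
#' @param frame_spacing frame spacing in ps (optional; the file stores only
#'   step indices).
#' @return an [aq_trajectory()]; the original step indices are kept in
#'   `meta$steps`.
#' @export
read_cpmd_trajectory <- function(path, element_order, box_edge,
                                 frame_spacing = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = FALSE)
  if (ncol(tab) < 4L)
    stop("TRAJECTORY lines must hold a step index plus three coordinates")
  steps_col <- tab[[1]]
  ustep <- unique(steps_col)
  counts <- table(factor(steps_col, levels = ustep))
  nat <- length(element_order)
  if (any(counts != nat))
    stop("inconsistent atom count between steps: expected ", nat,
         ", found ", paste(unique(counts), collapse = ", "))
  if (is.unsorted(ustep, strictly = TRUE)) {
    warning("non-monotone step indices; frames reordered by step")
    ord <- order(ustep)
    ustep <- ustep[ord]
  }
  nf <- length(ustep)
  coords <- array(0, c(nf, nat, 3L))
  pos <- as.matrix(tab[, 2:4]) * aq_constants$bohr_to_angstrom
  for (k in seq_len(nf)) {
    rows <- which(steps_col == ustep[k])
    coords[k, , ] <- pos[rows, , drop = FALSE]
  }
  aq_trajectory(coords, element_order, box_edge, dt = frame_spacing,
                meta = list(source = path, format = "cpmd", steps = ustep))
}
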