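#' Construct a trajectory
#'
#' A trajectory is an ordered set of frames sharing one topology: coordinates
#' in nm, orthorhombic box edge lengths per frame, and strictly increasing
#' frame times in ns.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (nm)
#' @param box numeric matrix `n_frames x 3` of box edge lengths (nm), or
#'   length-3 vector recycled over frames
#' @param time numeric frame times (ns); defaults to `0, 1, 2, ...`
#' @param topology a [topology()] with `n_atoms` rows
#' @return an object of class `md_trajectory`
#' @export
md_trajectory <- function(coords, box, time = NULL, topology) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  n_atoms <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3)
  if (any(box <= 0)) stop("box edge lengths must be > 0")
  if (is.null(time)) time <- seq_len(n_frames) - 1
  stopifnot(length(time) == n_frames)
  if (n_frames > 1 && any(diff(time) <= 0))
    stop("frame times must be strictly increasing")
  if (nrow(topology) != n_atoms)
    stop(sprintf("topology has %d atoms but coordinates have %d",
                 nrow(topology), n_atoms))
  structure(list(coords = coords, box = box, time = as.numeric(time),
                 topology = topology),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, t = %.4g..%.4g ns\n",
              n_atoms(x), n_frames(x), x$time[1], x$time[n_frames(x)]))
  cat(sprintf("  box (last frame): %.3f x %.3f x %.3f nm\n",
              x$box[n_frames(x), 1], x$box[n_frames(x), 2], x$box[n_frames(x), 3]))
  print(x$topology)
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an [md_trajectory()]
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj an [md_trajectory()]
#' @param i frame index
#' @return `n_atoms x 3` matrix (nm)
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Restrict a trajectory to a time window
#'
#' Time-independent analyses are typically run on the final, equilibrated part
#' of a trajectory (e.g. its last 100 ns); this returns the frames with
#' `start <= t <= end`.
#'
#' @param traj an [md_trajectory()]
#' @param start,end window bounds in ns (`NULL` = open)
#' @return an [md_trajectory()]
#' @export
trim_trajectory <- function(traj, start = NULL, end = NULL) {
  keep <- rep(TRUE, n_frames(traj))
  if (!is.null(start)) keep <- keep & traj$time >= start
  if (!is.null(end)) keep <- keep & traj$time <= end
  if (!any(keep)) stop("time window contains no frames")
  md_trajectory(traj$coords[, , keep, drop = FALSE],
                traj$box[keep, , drop = FALSE],
                traj$time[keep], traj$topology)
}

#' Convert coordinates between nm and Angstrom at the package boundary
#'
#' Internally everything is nm; use this when ingesting Angstrom data.
#'
#' @param traj an [md_trajectory()]
#' @param from unit the stored coordinates are currently in
#' @return trajectory in nm
#' @export
as_nm <- function(traj, from = c("nm", "angstrom")) {
  from <- match.arg(from)
  if (from == "angstrom") {
    traj$coords <- traj$coords / 10
    traj$box <- traj$box / 10
  }
  traj
}
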