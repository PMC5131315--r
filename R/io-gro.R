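# GRO coordinate files (GROMACS ecosystem): fixed-column layout, nm units,
# 3-decimal positions. Multiple concatenated frames are supported. Velocities
# are ignored on read and never written. Only orthorhombic boxes are accepted.

#' Read a GRO file (single- or multi-frame)
#'
#' Frame times are taken from a `t=` field on the title line when present in
#' every frame, otherwise frames are numbered `0, 1, 2, ...`. A group map may
#' be supplied to tag atoms on the fly.
#'
#' @param path file path
#' @param map optional [group_map()] applied to the parsed topology
#' @return an [md_trajectory()]
#' @export
read_gro <- function(path, map = NULL) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  boxes <- list()
  times <- numeric()
  top <- NULL
  n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (i == length(lines) && !nzchar(trimws(lines[i]))) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0)
      stop(sprintf("malformed atom-count line at line %d of '%s'", i + 1L, path))
    if (is.na(n_ref)) n_ref <- nat
    if (nat != n_ref)
      stop(sprintf(
        "inconsistent atom counts across frames (%d vs %d) at line %d",
        nat, n_ref, i + 1L))
    atom_lines <- if (nat > 0) lines[(i + 2L):(i + 1L + nat)] else character()
    box_line <- lines[i + 2L + nat]
    if (is.na(box_line)) stop("truncated frame: missing box line")
    bx <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
    if (length(bx) < 3 || anyNA(bx[1:3]))
      stop("box line must contain at least 3 numbers")
    if (length(bx) > 3 && any(abs(bx[-(1:3)]) > 1e-9))
      stop("triclinic boxes are not supported (off-diagonal box components present)")
    box <- bx[1:3]
    xyz <- parse_gro_atoms(atom_lines)
    if (is.null(top)) {
      top <- topology(atom = xyz$atom, resname = xyz$resname, resid = xyz$resid)
    }
    frames[[length(frames) + 1L]] <- xyz$pos
    boxes[[length(boxes) + 1L]] <- box
    times <- c(times, parse_gro_time(title))
    i <- i + 3L + nat
  }
  if (length(frames) == 0) stop("no frames found in '", path, "'")
  if (anyNA(times)) times <- seq_along(frames) - 1
  coords <- array(unlist(frames), c(n_ref, 3, length(frames)))
  if (!is.null(map)) top <- apply_group_map(top, map)
  md_trajectory(coords, do.call(rbind, boxes), times, top)
}

parse_gro_time <- function(title) {
  m <- regmatches(title, regexec("t\\s*=\\s*([-+0-9.eE]+)", title))[[1]]
  if (length(m) == 2) as.numeric(m[2]) else NA_real_
}

parse_gro_atoms <- function(atom_lines) {
  n <- length(atom_lines)
  if (n == 0)
    return(list(atom = character(), resname = character(),
                resid = integer(), pos = matrix(numeric(), 0, 3)))
  resid <- as.integer(substr(atom_lines, 1, 5))
  resname <- trimws(substr(atom_lines, 6, 10))
  atom <- trimws(substr(atom_lines, 11, 15))
  pos <- cbind(as.numeric(substr(atom_lines, 21, 28)),
               as.numeric(substr(atom_lines, 29, 36)),
               as.numeric(substr(atom_lines, 37, 44)))
  if (anyNA(pos) || anyNA(resid))
    stop("malformed atom line (fixed columns expected)")
  # residue numbers wrap modulo 100000 in the format; rebuild a monotone index
  resid <- unwrap_modulo(resid)
  list(atom = atom, resname = resname, resid = resid, pos = pos)
}

unwrap_modulo <- function(x, m = 100000L) {
  if (length(x) < 2) return(x)
  jump <- c(0L, as.integer(diff(x) < 0L))
  x + m * cumsum(jump)
}

#' Write a trajectory (or one frame) as a GRO file
#'
#' Fixed-column output, positions to 3 decimals; atom and residue numbers wrap
#' modulo 100000 per the format convention. Multi-frame trajectories are
#' concatenated, each frame carrying a `t=` title field.
#'
#' @param traj an [md_trajectory()]
#' @param path output path
#' @param title title-line prefix
#' @return `path`, invisibly
#' @export
write_gro <- function(traj, path, title = "written by lipidion") {
  stopifnot(inherits(traj, "md_trajectory"))
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$coords[, , f, drop = FALSE]
    dim(pos) <- dim(traj$coords)[1:2]
    writeLines(sprintf("%s, t= %.5f", title, traj$time[f]), con)
    writeLines(sprintf("%5d", nrow(pos)), con)
    if (nrow(pos) > 0) {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         top$resid %% 100000L, substr(top$resname, 1, 5),
                         substr(top$atom, 1, 5), seq_len(nrow(pos)) %% 100000L,
                         pos[, 1], pos[, 2], pos[, 3]), con)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
  }
  invisible(path)
}
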