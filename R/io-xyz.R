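# Multi-frame XYZ with box lengths on the comment line. Dialect: standard XYZ
# (count line, comment line, one "name x y z" line per atom) where the comment
# line carries "t= <ns> box <Lx> <Ly> <Lz>". Coordinates are nm (not the
# conventional Angstrom); pass unit = "angstrom" to convert on read.

#' Read a multi-frame XYZ-with-box file
#'
#' @param path file path
#' @param unit unit of the stored coordinates (converted to nm internally)
#' @param topology optional full [topology()]; if omitted, a minimal one is
#'   built with the XYZ name column as both atom and residue name
#' @return an [md_trajectory()]
#' @export
read_xyz <- function(path, unit = c("nm", "angstrom"), topology = NULL) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  i <- 1L
  frames <- list(); boxes <- list(); times <- numeric(); nm <- NULL
  n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0)
      stop(sprintf("malformed atom-count line at line %d", i))
    if (is.na(n_ref)) n_ref <- nat
    if (nat != n_ref) stop("inconsistent atom counts across frames")
    comment <- lines[i + 1L]
    mb <- regmatches(comment,
                     regexec("box\\s+([-+0-9.eE]+)\\s+([-+0-9.eE]+)\\s+([-+0-9.eE]+)",
                             comment))[[1]]
    if (length(mb) != 4) stop("comment line must contain 'box Lx Ly Lz'")
    box <- as.numeric(mb[2:4])
    tm <- regmatches(comment, regexec("t\\s*=\\s*([-+0-9.eE]+)", comment))[[1]]
    atom_lines <- if (nat > 0) lines[(i + 2L):(i + 1L + nat)] else character()
    tok <- strsplit(trimws(atom_lines), "\\s+")
    pos <- if (nat > 0)
      t(vapply(tok, function(w) as.numeric(w[2:4]), numeric(3)))
    else matrix(numeric(), 0, 3)
    if (is.null(nm)) nm <- vapply(tok, `[`, character(1), 1)
    frames[[length(frames) + 1L]] <- pos
    boxes[[length(boxes) + 1L]] <- box
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    i <- i + 2L + nat
  }
  if (length(frames) == 0) stop("no frames found in '", path, "'")
  if (anyNA(times)) times <- seq_along(frames) - 1
  if (is.null(topology))
    topology <- topology(atom = nm, resname = nm, resid = seq_len(n_ref))
  traj <- md_trajectory(array(unlist(frames), c(n_ref, 3, length(frames))),
                        do.call(rbind, boxes), times, topology)
  as_nm(traj, from = unit)
}

#' Write a trajectory as multi-frame XYZ-with-box
#'
#' @param traj an [md_trajectory()]
#' @param path output path
#' @param digits decimal places for coordinates
#' @return `path`, invisibly
#' @export
write_xyz <- function(traj, path, digits = 6) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%-6s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$coords[, , f, drop = FALSE]
    dim(pos) <- dim(traj$coords)[1:2]
    writeLines(sprintf("%d", nrow(pos)), con)
    writeLines(sprintf("t= %.6f box %.6f %.6f %.6f", traj$time[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    if (nrow(pos) > 0)
      writeLines(sprintf(fmt, traj$topology$atom, pos[, 1], pos[, 2], pos[, 3]),
                 con)
  }
  invisible(path)
}
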