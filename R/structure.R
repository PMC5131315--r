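# Structural observables of bilayer trajectories: area per lipid with
# block-averaged errors, number-density profiles along the membrane normal,
# phosphate-peak bilayer thickness, and P-N headgroup angle distributions.

lipid_tags <- c("PHOS_P", "CHOL_N", "CARBONYL_O_SN1", "CARBONYL_O_SN2", "COO_PS")

#' Area per lipid time series
#'
#' `APL = Lx * Ly / lipids_per_leaflet`, per frame. Cation adsorption
#' compresses bilayers laterally, so APL is the first-line readout of binding.
#'
#' @param traj an [md_trajectory()]
#' @param lipids_per_leaflet lipids in one leaflet (> 0)
#' @return data frame with columns `time` (ns) and `value` (nm^2), class
#'   `scalar_series`
#' @export
area_per_lipid <- function(traj, lipids_per_leaflet) {
  if (lipids_per_leaflet <= 0) stop("lipids_per_leaflet must be > 0")
  if (any(traj$box[, 1:2] == 0)) stop("zero lateral box dimension")
  out <- data.frame(time = traj$time,
                    value = traj$box[, 1] * traj$box[, 2] / lipids_per_leaflet)
  attr(out, "units") <- "nm^2"
  class(out) <- c("scalar_series", "data.frame")
  out
}

#' Block-average a correlated time series
#'
#' The series is split into `n_blocks` contiguous equal-length blocks (any
#' remainder is dropped from the front), and the standard error is the
#' standard deviation of the block means divided by `sqrt(n_blocks)`. For
#' positively autocorrelated series this exceeds the naive SE that wrongly
#' assumes independent frames.
#'
#' @param series numeric vector or a `scalar_series` data frame
#' @param n_blocks number of blocks (>= 2)
#' @return object of class `block_stats`: `mean`, `se`, `n_blocks`,
#'   `block_means`, and the naive SE for comparison
#' @export
block_average <- function(series, n_blocks = 5) {
  x <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  n <- length(x)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  len <- n %/% n_blocks
  x <- x[(n - n_blocks * len + 1):n]           # drop remainder from the front
  bm <- colMeans(matrix(x, nrow = len))
  structure(list(mean = mean(bm), se = stats::sd(bm) / sqrt(n_blocks),
                 n_blocks = n_blocks, block_means = bm,
                 naive_se = stats::sd(x) / sqrt(length(x))),
            class = "block_stats")
}

#' @export
print.block_stats <- function(x, ...) {
  cat(sprintf("block average: %.6g +/- %.3g (SE, %d blocks; naive SE %.3g)\n",
              x$mean, x$se, x$n_blocks, x$naive_se))
  invisible(x)
}

#' Recenter frame z-coordinates on the lipid center of mass
#'
#' @return matrix n_atoms x n_frames of recentered, wrapped z (nm), plus the
#'   per-frame box heights as attribute
#' @noRd
recentered_z <- function(traj, center_tags = lipid_tags) {
  cidx <- which(traj$topology$group %in% center_tags)
  if (length(cidx) == 0) cidx <- seq_len(n_atoms(traj))
  w <- traj$topology$mass[cidx]
  z <- matrix(NA_real_, n_atoms(traj), n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    zf <- traj$coords[, 3, f]
    com <- sum(w * zf[cidx]) / sum(w)
    # wrap into (-Lz/2, Lz/2] around the bilayer center
    Lz <- traj$box[f, 3]
    z[, f] <- min_image(zf - com, Lz)
  }
  z
}

#' Number-density profile along the bilayer normal
#'
#' Frames are recentered so the lipid center of mass sits at z = 0, then the
#' selected atoms are binned in z on a grid of bin centers `k * bin_width`
#' (a bin center at the bilayer midplane). Counts are divided by the per-frame
#' bin volume `Lx * Ly * bin_width` and by the frame count. With
#' `symmetrize = TRUE` the profile is averaged with its z -> -z mirror
#' (leaflet averaging).
#'
#' @param traj an [md_trajectory()]
#' @param selection integer atom indices (e.g. from [select_atoms()])
#' @param bin_width bin width in nm (> 0)
#' @param symmetrize average the two leaflets?
#' @return data frame with `z` (bin centers, nm) and `density` (nm^-3), class
#'   `density_profile`; mean box area and the options used are attached as
#'   attributes
#' @export
density_profile <- function(traj, selection, bin_width = 0.1,
                            symmetrize = FALSE) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (length(selection) == 0) stop("empty selection")
  z <- recentered_z(traj)
  half_n <- ceiling((max(traj$box[, 3]) / 2) / bin_width - 0.5) + 1L
  centers <- seq(-half_n, half_n) * bin_width
  edges <- c(centers - bin_width / 2, centers[length(centers)] + bin_width / 2)
  dens <- numeric(length(centers))
  for (f in seq_len(n_frames(traj))) {
    counts <- tabulate(
      findInterval(z[selection, f], edges, rightmost.closed = FALSE),
      nbins = length(centers))
    dens <- dens + counts / (traj$box[f, 1] * traj$box[f, 2] * bin_width)
  }
  dens <- dens / n_frames(traj)
  if (symmetrize) dens <- (dens + rev(dens)) / 2
  out <- data.frame(z = centers, density = dens)
  class(out) <- c("density_profile", "data.frame")
  attr(out, "bin_width") <- bin_width
  attr(out, "symmetrized") <- symmetrize
  attr(out, "mean_area") <- mean(traj$box[, 1] * traj$box[, 2])
  attr(out, "n_selected") <- length(selection)
  out
}

#' Bilayer thickness from a phosphate density profile
#'
#' Thickness is the distance between the phosphate-density peaks of the two
#' leaflets. Each leaflet peak is located at the maximal bin refined by
#' 3-point parabolic interpolation; the reported uncertainty is one bin width
#' (the peak-position estimation inaccuracy).
#'
#' @param profile a [density_profile()] of the phosphate atoms
#' @return thickness in nm, with attributes `peaks` (the two peak positions)
#'   and `uncertainty` (one bin width)
#' @export
bilayer_thickness <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$z; d <- profile$density
  find_peak <- function(side) {
    i <- which(side)[which.max(d[side])]
    if (length(i) == 0 || d[i] == 0) stop("no density peak found in leaflet")
    if (i == 1 || i == length(d))
      stop("monotone profile: no interior peak (degenerate input)")
    # 3-point parabola through (z[i-1..i+1], d[i-1..i+1])
    denom <- d[i - 1] - 2 * d[i] + d[i + 1]
    offset <- if (denom == 0) 0 else 0.5 * (d[i - 1] - d[i + 1]) / denom
    z[i] + offset * attr(profile, "bin_width")
  }
  upper <- z > 0; lower <- z < 0
  if (!any(d[upper] > 0) || !any(d[lower] > 0))
    stop("profile has density in only one leaflet")
  zp <- find_peak(upper); zm <- find_peak(lower)
  structure(abs(zp - zm), peaks = c(zm, zp),
            uncertainty = attr(profile, "bin_width"))
}

#' P-N headgroup angle distribution
#'
#' For every lipid and frame, the angle between the phosphorus-to-nitrogen
#' vector and the *outward* leaflet normal (+z for the upper leaflet, -z for
#' the lower, leaflets assigned by the sign of the recentered P z). With this
#' convention a mean below 90 deg means headgroups point toward the water
#' phase; cation adsorption raises PC headgroups (lowers the angle).
#'
#' @param traj an [md_trajectory()]
#' @param bin_width histogram bin width in degrees
#' @return object of class `angle_distribution`: data frame `angle` (bin
#'   centers, deg) / `density` (deg^-1, unit integral), with attributes
#'   `mean_angle` (deg, over raw samples) and `n_samples`
#' @export
pn_angle_distribution <- function(traj, bin_width = 2) {
  top <- traj$topology
  p_idx <- which(top$group == "PHOS_P")
  if (length(p_idx) == 0) stop("no PHOS_P atoms in topology")
  n_of_res <- stats::setNames(which(top$group == "CHOL_N"),
                              top$resid[top$group == "CHOL_N"])
  n_idx <- n_of_res[as.character(top$resid[p_idx])]
  if (anyNA(n_idx))
    stop("missing CHOL_N for lipid residue(s): ",
         paste(utils::head(top$resid[p_idx][is.na(n_idx)], 5), collapse = ", "))
  zc <- recentered_z(traj)
  angles <- numeric(0)
  for (f in seq_len(n_frames(traj))) {
    v <- traj$coords[n_idx, , f, drop = FALSE] - traj$coords[p_idx, , f, drop = FALSE]
    dim(v) <- c(length(p_idx), 3)
    for (k in 1:3) v[, k] <- min_image(v[, k], traj$box[f, k])
    outward <- sign(zc[p_idx, f])
    cosphi <- (v[, 3] * outward) / sqrt(rowSums(v^2))
    angles <- c(angles, acos(pmin(1, pmax(-1, cosphi))) * 180 / pi)
  }
  breaks <- seq(0, 180, by = bin_width)
  h <- hist(angles, breaks = breaks, plot = FALSE)
  out <- data.frame(angle = h$mids, density = h$density)
  class(out) <- c("angle_distribution", "data.frame")
  attr(out, "mean_angle") <- mean(angles)
  attr(out, "n_samples") <- length(angles)
  out
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf(
    "P-N headgroup angle distribution: mean %.2f deg (%d samples, %d bins)\n",
    attr(x, "mean_angle"), attr(x, "n_samples"), nrow(x)))
  invisible(x)
}
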