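# Ion-binding statistics: radial distribution functions with cumulative
# coordination counts, first-shell cutoffs, coordination numbers in both
# directions (ions per lipid group; groups per adsorbed ion), contact-based
# adsorption ratios, lipid hydration numbers, and bound-interval residence
# times. All pair distances use the orthorhombic minimum-image convention.

binding_tags <- c("PHOS_P", "CARBONYL_O_SN1", "CARBONYL_O_SN2", "COO_PS")

#' Radial distribution function between two selections
#'
#' `g(r)` is the histogram of A-B minimum-image pair distances normalized by
#' the spherical shell volume `4 pi r^2 dr`, the frame count, the number of A
#' atoms, and the mean number density of B over the whole box. The cumulative
#' coordination `n(r)` is computed by direct pair counting per A atom, not by
#' integrating `g`. Note the whole-box reference density is a convention:
#' bilayer systems are inhomogeneous, so first-shell cutoffs read off `g(r)`
#' should be cross-checked or supplied explicitly.
#'
#' @param traj an [md_trajectory()]
#' @param sel_a,sel_b integer atom index selections (self-pairs excluded)
#' @param r_max maximum distance, must be at most half the smallest box edge
#' @param bin_width histogram bin width (nm)
#' @return data frame `r`, `g`, `n` of class `rdf_result`, with the reference
#'   density attached
#' @export
rdf <- function(traj, sel_a, sel_b, r_max, bin_width = 0.002) {
  if (length(sel_a) == 0 || length(sel_b) == 0) stop("empty selection")
  if (r_max > min(traj$box) / 2)
    stop("r_max exceeds half the smallest box edge")
  nb <- ceiling(r_max / bin_width)
  edges <- seq(0, nb * bin_width, by = bin_width)
  counts <- numeric(nb)
  rho_sum <- 0
  for (f in seq_len(n_frames(traj))) {
    d <- pair_distances(traj$coords[sel_a, , f, drop = FALSE],
                        traj$coords[sel_b, , f, drop = FALSE],
                        traj$box[f, ])
    if (length(common <- intersect(sel_a, sel_b)) > 0)
      d[cbind(match(common, sel_a), match(common, sel_b))] <- Inf
    counts <- counts + tabulate(findInterval(d[d < edges[nb + 1]],
                                             edges, left.open = TRUE),
                                nbins = nb)
    rho_sum <- rho_sum + length(sel_b) / prod(traj$box[f, ])
  }
  rho <- rho_sum / n_frames(traj)
  r_mid <- edges[-1] - bin_width / 2
  shell <- 4 * pi * r_mid^2 * bin_width
  g <- counts / (n_frames(traj) * length(sel_a) * shell * rho)
  n_cum <- cumsum(counts) / (n_frames(traj) * length(sel_a))
  out <- data.frame(r = r_mid, g = g, n = n_cum)
  class(out) <- c("rdf_result", "data.frame")
  attr(out, "reference_density") <- rho
  attr(out, "bin_width") <- bin_width
  out
}

#' First coordination-shell cutoff from an RDF
#'
#' The first local minimum of `g(r)` (smoothed with a 3-bin moving average)
#' after its first maximum. If no interior minimum exists below `r_max`, the
#' user-supplied fallback is returned with `"user"` provenance.
#'
#' @param rdf_result an [rdf()] result
#' @param fallback optional user cutoff (nm)
#' @return cutoff in nm with attribute `provenance` (`"rdf"` or `"user"`)
#' @export
first_shell_cutoff <- function(rdf_result, fallback = NULL) {
  g <- as.numeric(stats::filter(rdf_result$g, rep(1 / 3, 3), sides = 2))
  r <- rdf_result$r
  ok <- !is.na(g)
  g <- g[ok]; r <- r[ok]
  i_max <- NA_integer_
  for (i in 2:(length(g) - 1)) {
    if (is.na(i_max) && g[i] > g[i - 1] && g[i] >= g[i + 1] && g[i] > 0) {
      i_max <- i
    } else if (!is.na(i_max) && g[i] < g[i - 1] && g[i] <= g[i + 1]) {
      return(structure(r[i], provenance = "rdf"))
    }
  }
  if (!is.null(fallback)) return(structure(fallback, provenance = "user"))
  stop("no first-shell minimum found in g(r) and no user cutoff supplied")
}

#' Mean ions in the first coordination shell of a lipid group
#'
#' `n1` = mean over frames and group instances of the number of ions within
#' the cutoff. Multi-atom groups (e.g. the two carboxylate oxygens) count an
#' ion once per group even if it is close to both atoms.
#'
#' @param traj an [md_trajectory()]
#' @param groups list of integer vectors, one per group instance (see
#'   [group_instances()])
#' @param ion_sel integer ion atom indices
#' @param cutoff first-shell cutoff (nm, > 0; 0 gives n1 = 0)
#' @return mean coordination number, with per-frame means as attribute
#'   `"per_frame"`
#' @export
coordination_per_group <- function(traj, groups, ion_sel, cutoff) {
  if (length(groups) == 0 || length(ion_sel) == 0) stop("empty selection")
  if (cutoff < 0) stop("cutoff must be >= 0")
  gidx <- unlist(groups, use.names = FALSE)
  gid <- rep(seq_along(groups), lengths(groups))
  per_frame <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    d <- pair_distances(traj$coords[gidx, , f, drop = FALSE],
                        traj$coords[ion_sel, , f, drop = FALSE],
                        traj$box[f, ])
    near <- d <= cutoff
    # once-per-group: collapse atoms of one group before counting
    cnt <- rowsum(near + 0, gid) > 0
    per_frame[f] <- sum(cnt) / length(groups)
  }
  structure(mean(per_frame), per_frame = per_frame, cutoff = cutoff)
}

#' Adsorbed ions in one frame
#'
#' An ion is adsorbed when at least one lipid atom of the analyzed binding
#' groups lies within the contact cutoff (0.42 nm by default, the all-contacts
#' criterion).
#'
#' @param traj an [md_trajectory()]
#' @param frame frame index
#' @param ion_sel integer ion indices
#' @param lipid_sel integer indices of lipid binding-group atoms
#' @param contact_cutoff nm
#' @return integer subset of `ion_sel` adsorbed in this frame
#' @export
adsorbed_ions <- function(traj, frame, ion_sel, lipid_sel,
                          contact_cutoff = 0.42) {
  d <- pair_distances(traj$coords[ion_sel, , frame, drop = FALSE],
                      traj$coords[lipid_sel, , frame, drop = FALSE],
                      traj$box[frame, ])
  ion_sel[apply(d <= contact_cutoff, 1, any)]
}

#' Lipids per adsorbed ion
#'
#' Ratio of the total lipid count to the time-averaged number of adsorbed
#' ions. With no ion ever adsorbed the ratio is infinite (with a warning).
#'
#' @param traj an [md_trajectory()]
#' @param ion_sel integer ion indices
#' @param lipid_sel lipid binding-group atom indices; defaults to all
#'   phosphate-P, carbonyl-O and carboxylate-O atoms
#' @param n_lipids total lipid count; defaults to the number of PHOS_P atoms
#' @param contact_cutoff nm
#' @return the ratio, with attributes `mean_adsorbed` and `per_frame`
#' @export
lipids_per_adsorbed_ion <- function(traj, ion_sel, lipid_sel = NULL,
                                    n_lipids = NULL, contact_cutoff = 0.42) {
  if (is.null(lipid_sel)) lipid_sel <- select_atoms(traj$topology, binding_tags)
  if (is.null(n_lipids)) n_lipids <- sum(traj$topology$group == "PHOS_P")
  per_frame <- vapply(seq_len(n_frames(traj)), function(f)
    length(adsorbed_ions(traj, f, ion_sel, lipid_sel, contact_cutoff)),
    numeric(1))
  mean_ads <- mean(per_frame)
  if (mean_ads == 0) {
    warning("no adsorbed ions in any frame; ratio is infinite")
    ratio <- Inf
  } else ratio <- n_lipids / mean_ads
  structure(ratio, mean_adsorbed = mean_ads, per_frame = per_frame)
}

#' Coordination numbers of adsorbed ions
#'
#' For each adsorbed ion (free ions are excluded) count the distinct group
#' instances of each type within that type's cutoff, then average over
#' adsorbed ions and frames.
#'
#' @param traj an [md_trajectory()]
#' @param ion_sel integer ion indices
#' @param group_sets named list of group-instance lists (each as from
#'   [group_instances()])
#' @param cutoffs named numeric, one cutoff (nm) per group set
#' @param lipid_sel,contact_cutoff adsorption criterion (see
#'   [adsorbed_ions()])
#' @return named numeric of per-group means, with attributes `sd` (over
#'   ion-frame samples) and `n_samples`
#' @export
coordination_of_adsorbed <- function(traj, ion_sel, group_sets, cutoffs,
                                     lipid_sel = NULL, contact_cutoff = 0.42) {
  stopifnot(all(names(group_sets) %in% names(cutoffs)))
  if (is.null(lipid_sel)) lipid_sel <- select_atoms(traj$topology, binding_tags)
  samples <- stats::setNames(vector("list", length(group_sets)),
                             names(group_sets))
  for (f in seq_len(n_frames(traj))) {
    ads <- adsorbed_ions(traj, f, ion_sel, lipid_sel, contact_cutoff)
    if (length(ads) == 0) next
    for (nm in names(group_sets)) {
      groups <- group_sets[[nm]]
      if (length(groups) == 0) { samples[[nm]] <- c(samples[[nm]], rep(0, length(ads))); next }
      gidx <- unlist(groups, use.names = FALSE)
      gid <- rep(seq_along(groups), lengths(groups))
      d <- pair_distances(traj$coords[ads, , f, drop = FALSE],
                          traj$coords[gidx, , f, drop = FALSE],
                          traj$box[f, ])
      near <- d <= cutoffs[[nm]]
      # distinct groups per ion: collapse group atoms
      per_ion <- rowSums(t(rowsum(t(near + 0), gid)) > 0)
      samples[[nm]] <- c(samples[[nm]], per_ion)
    }
  }
  if (all(lengths(samples) == 0))
    stop("no adsorbed ions in any frame; coordination of adsorbed undefined")
  means <- vapply(samples, mean, numeric(1))
  structure(means,
            sd = vapply(samples, stats::sd, numeric(1)),
            n_samples = lengths(samples))
}

#' Lipid hydration numbers
#'
#' For every lipid and frame, count the water oxygens within the
#' group-specific cutoff of the lipid's group atoms; a water is counted once
#' per lipid group even when close to both carbonyl oxygens. Default cutoffs
#' follow the first solvation-shell minima: 0.24 nm for carbonyl oxygens and
#' 0.335 nm for phosphate phosphorus.
#'
#' @param traj an [md_trajectory()]
#' @param cutoffs named numeric (nm), names `carbonyl` and `phosphate`
#' @return data frame with one row per group (`group`, `mean`, `sd`,
#'   `cutoff`, `n_samples`), class `hydration_report`; SD is over lipid-frame
#'   samples
#' @export
hydration_numbers <- function(traj,
                              cutoffs = c(carbonyl = 0.24, phosphate = 0.335)) {
  top <- traj$topology
  w_idx <- which(top$group == "WATER_O")
  if (length(w_idx) == 0) stop("no WATER_O atoms in the system")
  sets <- list(
    carbonyl = group_instances(top, c("CARBONYL_O_SN1", "CARBONYL_O_SN2")),
    phosphate = group_instances(top, "PHOS_P")
  )
  rows <- list()
  for (nm in names(sets)) {
    groups <- sets[[nm]]
    if (length(groups) == 0) next
    gidx <- unlist(groups, use.names = FALSE)
    gid <- rep(seq_along(groups), lengths(groups))
    samples <- numeric(0)
    for (f in seq_len(n_frames(traj))) {
      d <- pair_distances(traj$coords[gidx, , f, drop = FALSE],
                          traj$coords[w_idx, , f, drop = FALSE],
                          traj$box[f, ])
      near <- d <= cutoffs[[nm]]
      per_lipid <- rowSums(rowsum(near + 0, gid) > 0)
      samples <- c(samples, per_lipid)
    }
    rows[[nm]] <- data.frame(group = nm, mean = mean(samples),
                             sd = stats::sd(samples), cutoff = cutoffs[[nm]],
                             n_samples = length(samples))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hydration_report", "data.frame")
  out
}

#' Per-ion contact timeline with a partner selection
#'
#' @param traj an [md_trajectory()]
#' @param ion_sel integer ion indices
#' @param partner_sel integer partner atom indices
#' @param cutoff contact cutoff (nm)
#' @return logical matrix ions x frames, class `contact_timeline`, with the
#'   frame times attached
#' @export
contact_timeline <- function(traj, ion_sel, partner_sel, cutoff = 0.42) {
  tl <- matrix(FALSE, length(ion_sel), n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    d <- pair_distances(traj$coords[ion_sel, , f, drop = FALSE],
                        traj$coords[partner_sel, , f, drop = FALSE],
                        traj$box[f, ])
    tl[, f] <- apply(d <= cutoff, 1, any)
  }
  structure(tl, class = "contact_timeline", time = traj$time)
}

#' Residence-time statistics from contact timelines
#'
#' Bound intervals are maximal runs of bound frames, where unbound gaps of at
#' most `gap_tolerance` frames are bridged. Interval durations are the number
#' of bound frames times the frame spacing. Intervals touching either end of
#' the trajectory are flagged as censored (and excluded from the mean when
#' `drop_censored = TRUE`, the default, since their true length is unknown).
#'
#' @param timeline logical matrix ions x frames (see [contact_timeline()]),
#'   or a logical vector for a single ion
#' @param dt frame spacing (ns); taken from the timeline attribute if present
#' @param gap_tolerance frames
#' @param drop_censored exclude end-censored intervals from the summary
#' @return object of class `residence_stats`: per-interval table (`ion`,
#'   `start`, `length_ns`, `censored`), mean/max interval, the
#'   censoring-robust `mean_mle_ns` (total bound time divided by the number
#'   of observed desorption events — the exponential-residence MLE under
#'   right censoring), and the first-desorption time per ion (duration of the
#'   initial bound run, NA if unbound at t = 0)
#' @export
residence_times <- function(timeline, dt = NULL, gap_tolerance = 0,
                            drop_censored = FALSE) {
  if (is.null(dim(timeline))) timeline <- matrix(timeline, nrow = 1)
  if (is.null(dt)) {
    tm <- attr(timeline, "time")
    dt <- if (!is.null(tm) && length(tm) > 1) tm[2] - tm[1] else 1
  }
  nf <- ncol(timeline)
  intervals <- list()
  first_desorption <- rep(NA_real_, nrow(timeline))
  for (i in seq_len(nrow(timeline))) {
    x <- as.logical(timeline[i, ])
    if (gap_tolerance > 0) {
      r <- rle(x)
      gaps <- !r$values & r$lengths <= gap_tolerance
      # only interior gaps (flanked by bound runs) are bridged
      interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
      r$values[gaps & interior] <- TRUE
      x <- inverse.rle(r)
    }
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      right_cens <- ends[j] == nf
      censored <- starts[j] == 1 || right_cens
      intervals[[length(intervals) + 1L]] <-
        data.frame(ion = i, start = (starts[j] - 1) * dt,
                   length_ns = r$lengths[j] * dt, censored = censored,
                   right_censored = right_cens)
    }
    if (x[1]) first_desorption[i] <- r$lengths[1] * dt
  }
  tab <- if (length(intervals) > 0) do.call(rbind, intervals) else
    data.frame(ion = integer(), start = numeric(), length_ns = numeric(),
               censored = logical(), right_censored = logical())
  use <- if (drop_censored) tab$length_ns[!tab$censored] else tab$length_ns
  # terminations: intervals whose end (desorption) is observed inside the
  # window; right-censored intervals contribute observation time only
  n_terminations <- sum(!tab$right_censored)
  structure(list(
    intervals = tab,
    mean_ns = if (length(use) > 0) mean(use) else NA_real_,
    # censoring-robust estimate: total bound time over observed desorption
    # events (the exponential-residence MLE under right censoring)
    mean_mle_ns = if (n_terminations > 0) sum(tab$length_ns) / n_terminations
                  else NA_real_,
    max_ns = if (nrow(tab) > 0) max(tab$length_ns) else NA_real_,
    n_intervals = length(use),
    n_complete = n_terminations,
    first_desorption_ns = first_desorption,
    dt = dt, gap_tolerance = gap_tolerance
  ), class = "residence_stats")
}

#' @export
print.residence_stats <- function(x, ...) {
  cat(sprintf(
    "residence times: %d intervals, mean %.3g ns, max %.3g ns (dt %.3g ns, gap tol %d)\n",
    x$n_intervals, x$mean_ns, x$max_ns, x$dt, x$gap_tolerance))
  invisible(x)
}
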