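# Independent brute-force oracles and small fixture builders used across the
# suite. The distance oracle enumerates the {-1, 0, 1} periodic images per
# dimension explicitly (the implementation path uses the round()-based
# minimum-image convention instead).

oracle_min_image_dist <- function(a, b, box) {
  best <- rep(Inf, 3)
  d2 <- 0
  for (k in 1:3) {
    dk <- a[k] - b[k]
    cand <- abs(c(dk - box[k], dk, dk + box[k]))
    d2 <- d2 + min(cand)^2
  }
  sqrt(d2)
}

oracle_pair_distances <- function(A, B, box) {
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk_min <- pmin(abs(dk - box[k]), abs(dk), abs(dk + box[k]))
    d2 <- d2 + dk_min^2
  }
  sqrt(d2)
}

# count, per group instance, the ions within `cutoff` (once per group)
oracle_group_counts <- function(pos, groups, ion_idx, box, cutoff) {
  vapply(groups, function(g) {
    d <- oracle_pair_distances(pos[g, , drop = FALSE],
                               pos[ion_idx, , drop = FALSE], box)
    sum(apply(d <= cutoff, 2, any))
  }, numeric(1))
}

random_trajectory <- function(n_atoms, n_frames, box = c(4, 4, 4),
                              groups = NULL) {
  top <- topology(atom = sprintf("A%d", seq_len(n_atoms)),
                  resname = "RND", resid = seq_len(n_atoms),
                  group = groups %||% "OTHER")
  coords <- array(stats::runif(n_atoms * 3 * n_frames), c(n_atoms, 3, n_frames))
  for (k in 1:3) coords[, k, ] <- coords[, k, ] * box[k]
  md_trajectory(coords, box, seq_len(n_frames) - 1, top)
}

# two-atom-per-lipid toy bilayer used in a few structural tests
toy_bilayer <- function(z_p = 2, z_n = 2.1, n_per_leaflet = 4, box = c(4, 4, 8)) {
  n_lip <- 2 * n_per_leaflet
  top <- topology(atom = rep(c("P", "N"), n_lip),
                  resname = "POPC",
                  resid = rep(seq_len(n_lip), each = 2),
                  group = rep(c("PHOS_P", "CHOL_N"), n_lip))
  xy <- cbind(rep(seq_len(n_per_leaflet), 2), 1)
  pos <- matrix(NA_real_, 2 * n_lip, 3)
  sgn <- rep(c(1, -1), each = n_per_leaflet)
  pos[seq(1, 2 * n_lip, 2), ] <- cbind(xy[, 1], xy[, 2], box[3] / 2 + sgn * z_p)
  pos[seq(2, 2 * n_lip, 2), ] <- cbind(xy[, 1], xy[, 2], box[3] / 2 + sgn * z_n)
  md_trajectory(pos, box, 0, top)
}

# per (ion, group) 0/1 contact matrix for one frame (rows = ions)
oracle_group_counts_per_ion <- function(pos, groups, ion_idx, box, cutoff) {
  m <- vapply(groups, function(g) {
    d <- oracle_pair_distances(pos[ion_idx, , drop = FALSE],
                               pos[g, , drop = FALSE], box)
    apply(d <= cutoff, 1, any) + 0
  }, numeric(length(ion_idx)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ion_idx))
  m
}

pair_dists_helper <- function(traj, a, b, f) {
  oracle_pair_distances(frame_coords(traj, f)[a, , drop = FALSE],
                        frame_coords(traj, f)[b, , drop = FALSE],
                        traj$box[f, ])
}
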