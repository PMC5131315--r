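# Synthetic two-leaflet bilayer trajectories with known ground truth. The
# generator emulates only the head-region architecture the analyses touch:
# lipids on a jittered square lattice per leaflet at a scheduled area per
# lipid, one phosphate P / choline N / two carbonyl O per lipid (plus two
# carboxylate O for PS), Ca2+ ions alternating between bound (attached to a
# sampled site at a fixed shell radius) and free (uniform in the water slab)
# states via a two-state Markov chain, Cl- and slab waters, optional
# first-shell waters, and isotropic Gaussian positional noise. There are no
# forces or energies: this is a statistical stand-in whose expectations are
# known in closed form, not a physical model.

#' Specification of a synthetic bilayer trajectory
#'
#' Defaults mirror the simulated systems the analyses are designed for:
#' 64 lipids per leaflet (128 total), an optional 4:1 PC:PS mixture via 12
#' PS per leaflet, phosphate planes at |z| = 2.0 nm.
#'
#' @param lipids_per_leaflet lipids in each leaflet
#' @param ps_per_leaflet PS lipids per leaflet (12 gives the 4:1 mixture)
#' @param apl area per lipid in nm^2: scalar (constant) or length-`n_frames`
#'   schedule (e.g. a linear ramp)
#' @param n_frames,dt frame count and spacing (ns)
#' @param z_phos,z_carb_sn1,z_carb_sn2,z_coo mean |z| of the group planes (nm)
#' @param d_pn P-to-N vector length (nm)
#' @param tilt_mean,tilt_sd P-N tilt angle from the outward leaflet normal:
#'   truncated normal on \[0, 180\] deg
#' @param tilt_isotropic draw P-N orientations isotropically instead
#'   (density proportional to sin(angle), mean 90 deg)
#' @param noise_sd isotropic positional noise per atom (nm)
#' @param n_ca,n_cl ion counts
#' @param p_phos,p_carb,p_coo per-ion probabilities of being bound to a
#'   phosphate / sn-2 carbonyl / PS carboxylate site (stationary occupancies
#'   of the binding chain; their sum is the total bound probability, <= 1)
#' @param bound_distance ion-site shell radius when bound (nm)
#' @param mean_residence mean bound-state residence time (ns)
#' @param waters_per_lipid slab waters per lipid (uniform in the water slab)
#' @param shell_waters_carbonyl,shell_waters_phosphate first-shell waters
#'   placed per lipid at `shell_distance_*` from the sn-2 carbonyl O / the P
#' @param shell_distance_carbonyl,shell_distance_phosphate placement radii (nm)
#' @param water_pad water slab thickness beyond the slab gap (nm); the free
#'   ion/water slab starts 0.5 nm above the outermost headgroup plane so that
#'   free species can never fall inside the 0.42 nm contact cutoff
#' @return object of class `membrane_spec`
#' @export
membrane_spec <- function(lipids_per_leaflet = 64, ps_per_leaflet = 0,
                          apl = 0.64, n_frames = 50, dt = 0.1,
                          z_phos = 2.0, z_carb_sn1 = 1.45, z_carb_sn2 = 1.5,
                          z_coo = 2.1, d_pn = 0.45,
                          tilt_mean = 80, tilt_sd = 20, tilt_isotropic = FALSE,
                          noise_sd = 0.02,
                          n_ca = 0, n_cl = 0,
                          p_phos = 0, p_carb = 0, p_coo = 0,
                          bound_distance = 0.28, mean_residence = 10,
                          waters_per_lipid = 0,
                          shell_waters_carbonyl = 0, shell_waters_phosphate = 0,
                          shell_distance_carbonyl = 0.20,
                          shell_distance_phosphate = 0.30,
                          water_pad = 1.5) {
  spec <- as.list(environment())
  with(spec, {
    stopifnot(lipids_per_leaflet >= 1, ps_per_leaflet >= 0,
              ps_per_leaflet <= lipids_per_leaflet,
              all(apl > 0), n_frames >= 1, dt > 0, noise_sd >= 0,
              n_ca >= 0, n_cl >= 0, p_phos >= 0, p_carb >= 0, p_coo >= 0,
              mean_residence > 0, waters_per_lipid >= 0)
    if (p_phos + p_carb + p_coo > 1)
      stop("per-ion site occupancies must sum to at most 1")
    if (p_coo > 0 && ps_per_leaflet == 0)
      stop("carboxylate occupancy requires PS lipids")
  })
  if (!length(spec$apl) %in% c(1L, spec$n_frames))
    stop("apl must be scalar or one value per frame")
  structure(spec, class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    "membrane_spec: %d+%d lipids (%d PS/leaflet), %d frames x %.3g ns, APL %.3g..%.3g nm^2\n",
    x$lipids_per_leaflet, x$lipids_per_leaflet, x$ps_per_leaflet,
    x$n_frames, x$dt, min(x$apl), max(x$apl)))
  cat(sprintf("  %d Ca2+ (p_phos %.2g, p_carb %.2g, p_coo %.2g), %d Cl-, noise %.3g nm\n",
              x$n_ca, x$p_phos, x$p_carb, x$p_coo, x$n_cl, x$noise_sd))
  invisible(x)
}

# derived geometry shared by generator and expectations
membrane_geometry <- function(spec) {
  z_head_max <- max(spec$z_phos + spec$d_pn, spec$z_coo, spec$z_phos)
  slab_min <- z_head_max + 0.5
  lz <- 2 * (slab_min + spec$water_pad)
  list(z_head_max = z_head_max, slab_min = slab_min, lz = lz)
}

#' Closed-form expected statistics of a synthetic bilayer
#'
#' The ground truth the recovery tests compare against. Geometric inclusion
#' probabilities at a cutoff account for the positional noise exactly via the
#' noncentral chi-square distance distribution. Standard errors of
#' time-averaged bound fractions account for the Markov-chain autocorrelation
#' through the effective sample size `n * (1 - rho) / (1 + rho)` with
#' `rho = exp(-dt * (k_on + k_off))`.
#'
#' @param spec a [membrane_spec()]
#' @param cutoffs named cutoffs (nm) used by the downstream coordination
#'   analysis (`phosphate`, `carbonyl`, `carboxylate`, `contact`)
#' @return list of expectations, class `membrane_truth`
#' @export
expected_statistics <- function(spec,
                                cutoffs = c(phosphate = 0.33, carbonyl = 0.33,
                                            carboxylate = 0.33, contact = 0.42),
                                hydration_cutoffs = c(carbonyl = 0.24,
                                                      phosphate = 0.335),
                                n_mc = 2e5) {
  n_lip <- 2L * spec$lipids_per_leaflet
  n_ps <- 2L * spec$ps_per_leaflet
  p_tot <- spec$p_phos + spec$p_carb + spec$p_coo
  apl <- rep_len(spec$apl, spec$n_frames)
  p_geom <- function(cut) p_within_cutoff(cut, spec$bound_distance, spec$noise_sd)
  mc <- local_binding_expectations(spec, cutoffs, hydration_cutoffs, n_mc)
  p_site <- c(phos = spec$p_phos, carb = spec$p_carb, coo = spec$p_coo)
  ps_frac <- if (n_lip > 0) n_ps / n_lip else 0
  # expected ions within cutoff of one group instance: contributions of ions
  # bound to any site of the same lipid (cross-lipid reach is shorter than
  # the lattice spacing at realistic APL, hence neglected); phosphate/carbonyl
  # sites live on a PS lipid with probability n_ps/n_lip
  n1 <- c(
    phosphate = if (n_lip > 0)
      spec$n_ca * sum(p_site * mc$p_near[, "phosphate"]) / n_lip else 0,
    carbonyl = if (n_lip > 0)
      spec$n_ca * sum(p_site * mc$p_near[, "carbonyl"]) / n_lip else 0,
    carboxylate = if (n_ps > 0)
      spec$n_ca * (p_site[["coo"]] * mc$p_near["coo", "carboxylate"] +
                     ps_frac * (p_site[["phos"]] * mc$p_near["phos", "carboxylate"] +
                                  p_site[["carb"]] * mc$p_near["carb", "carboxylate"])) /
        n_ps
    else NA_real_
  )
  p_contact <- sum(p_site * mc$p_adsorbed)
  coord_ads <- if (p_contact > 0) c(
    phosphate = sum(p_site * mc$p_near[, "phosphate"]) / p_contact,
    carbonyl = sum(p_site * mc$p_near[, "carbonyl"]) / p_contact,
    carboxylate = if (n_ps > 0)
      (p_site[["coo"]] * mc$p_near["coo", "carboxylate"] +
         ps_frac * (p_site[["phos"]] * mc$p_near["phos", "carboxylate"] +
                      p_site[["carb"]] * mc$p_near["carb", "carboxylate"])) / p_contact
    else NA_real_
  ) else c(phosphate = NA_real_, carbonyl = NA_real_, carboxylate = NA_real_)
  # two-state chain: k_off = 1/mean_residence, stationary bound prob p_tot
  k_off <- 1 / spec$mean_residence
  k_on <- if (p_tot < 1) k_off * p_tot / (1 - p_tot) else Inf
  rho <- if (is.finite(k_on)) exp(-spec$dt * (k_on + k_off)) else 0
  ess_factor <- (1 - rho) / (1 + rho)
  n_eff <- spec$n_ca * spec$n_frames * ess_factor
  se_bound_fraction <- if (n_eff > 0) sqrt(p_tot * (1 - p_tot) / n_eff) else NA_real_
  structure(list(
    apl = apl,
    thickness = 2 * spec$z_phos,
    mean_angle = if (spec$tilt_isotropic) 90 else spec$tilt_mean,
    bound_fraction = p_tot,
    se_bound_fraction = se_bound_fraction,
    ess_factor = ess_factor,
    expected_adsorbed = spec$n_ca * p_contact,
    adsorbed_fraction = p_contact,
    lipids_per_adsorbed_ion =
      if (spec$n_ca * p_contact > 0) n_lip / (spec$n_ca * p_contact) else Inf,
    n1 = n1,
    coordination_of_adsorbed = coord_ads,
    geometric_inclusion = vapply(cutoffs, p_geom, numeric(1)),
    hydration = mc$hydration,
    mc_se = mc$se,
    mean_residence = spec$mean_residence,
    n_lipids = n_lip, n_ps = n_ps
  ), class = "membrane_truth")
}

# Monte-Carlo expectations over the exact single-lipid local geometry:
# probabilities that an ion bound to each site type falls within the analysis
# cutoffs of each group of the same lipid (including cross terms, e.g. a
# carboxylate-bound ion sitting within the phosphate cutoff), the adsorption
# (contact) probability, and hydration numbers including cross-shell waters.
# Deterministic: runs under a fixed internal RNG substream, state restored.
local_binding_expectations <- function(spec, cutoffs, hydration_cutoffs, n_mc) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(20260101)
  n_mc <- as.integer(n_mc)
  # one lipid, upper leaflet, lattice origin: P, OA (sn-1), OB (sn-2), OC1/2
  base <- rbind(P = c(0, 0, spec$z_phos),
                OA = c(0.06, 0, spec$z_carb_sn1),
                OB = c(-0.06, 0, spec$z_carb_sn2),
                OC1 = c(0.06, 0, spec$z_coo),
                OC2 = c(-0.06, 0, spec$z_coo))
  groups <- list(phosphate = "P", carbonyl = c("OA", "OB"),
                 carboxylate = c("OC1", "OC2"))
  anchors <- c(phos = "P", carb = "OB", coo = "OC1")
  jitter <- function(n) if (spec$noise_sd > 0)
    matrix(stats::rnorm(3 * n, 0, spec$noise_sd), n, 3) else matrix(0, n, 3)
  dist_to <- function(pts, atom_pos) sqrt(rowSums((pts - atom_pos)^2))
  p_near <- matrix(NA_real_, 3, 3,
                   dimnames = list(names(anchors), names(groups)))
  p_ads <- stats::setNames(numeric(3), names(anchors))
  binding_atoms <- c("P", "OA", "OB", "OC1", "OC2")
  for (s in names(anchors)) {
    atom_j <- lapply(rownames(base), function(a)
      matrix(base[a, ], n_mc, 3, byrow = TRUE) + jitter(n_mc))
    names(atom_j) <- rownames(base)
    # ion sits on a shell around the noiseless anchor, then gets its own jitter
    ion <- matrix(base[anchors[[s]], ], n_mc, 3, byrow = TRUE) +
      spec$bound_distance * runit(n_mc) + jitter(n_mc)
    d <- vapply(rownames(base), function(a) dist_to(ion, atom_j[[a]]),
                numeric(n_mc))
    for (g in names(groups))
      p_near[s, g] <- mean(rowSums(d[, groups[[g]], drop = FALSE] <=
                                     cutoffs[[g]]) > 0)
    p_ads[s] <- mean(rowSums(d[, binding_atoms, drop = FALSE] <=
                               cutoffs[["contact"]]) > 0)
  }
  # hydration: shell waters of both kinds against both hydration groups
  atom_j <- lapply(rownames(base), function(a)
    matrix(base[a, ], n_mc, 3, byrow = TRUE) + jitter(n_mc))
  names(atom_j) <- rownames(base)
  shell <- list(
    carb = matrix(base["OB", ], n_mc, 3, byrow = TRUE) +
      spec$shell_distance_carbonyl * runit(n_mc) + jitter(n_mc),
    phos = matrix(base["P", ], n_mc, 3, byrow = TRUE) +
      spec$shell_distance_phosphate * runit(n_mc) + jitter(n_mc))
  near_group <- function(w, g, cut) {
    d <- vapply(groups[[g]], function(a) dist_to(w, atom_j[[a]]), numeric(n_mc))
    rowSums(d <= cut) > 0
  }
  hc <- hydration_cutoffs[["carbonyl"]]
  hp <- hydration_cutoffs[["phosphate"]]
  hyd <- c(
    carbonyl = spec$shell_waters_carbonyl * mean(near_group(shell$carb, "carbonyl", hc)) +
      spec$shell_waters_phosphate * mean(near_group(shell$phos, "carbonyl", hc)),
    phosphate = spec$shell_waters_phosphate * mean(near_group(shell$phos, "phosphate", hp)) +
      spec$shell_waters_carbonyl * mean(near_group(shell$carb, "phosphate", hp))
  )
  list(p_near = p_near, p_adsorbed = p_ads, hydration = hyd,
       se = 0.5 / sqrt(n_mc))
}

rtrunc_angle <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, x[x >= 0 & x <= 180])
  }
  out
}

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' Identical `(spec, seed)` pairs give bit-identical output. The returned
#' ground truth extends [expected_statistics()] with the realized per-ion
#' bound-state and site sequences.
#'
#' @param spec a [membrane_spec()]
#' @param seed integer RNG seed
#' @return list with elements `trajectory` (an [md_trajectory()]) and
#'   `truth` (a `membrane_truth` with `bound_state` and `site_type` matrices,
#'   ions x frames)
#' @export
generate_membrane <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "membrane_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  L <- spec$lipids_per_leaflet
  n_lip <- 2L * L
  geom <- membrane_geometry(spec)
  lz <- geom$lz
  apl <- rep_len(spec$apl, spec$n_frames)

  # lattice fractional coordinates, fixed over time; box breathes with APL
  nx <- ceiling(sqrt(L))
  cell <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(nx) - 0.5)[seq_len(L), ] / nx
  is_ps_leaflet <- function() {
    v <- rep(FALSE, L)
    if (spec$ps_per_leaflet > 0) v[sample.int(L, spec$ps_per_leaflet)] <- TRUE
    v
  }
  is_ps <- c(is_ps_leaflet(), is_ps_leaflet())
  leaflet <- rep(c(1, -1), each = L)
  frac_x <- rep(cell$ix, 2)
  frac_y <- rep(cell$iy, 2)

  # per-lipid atom templates -> topology
  atoms_per_lipid <- ifelse(is_ps, 6L, 4L)
  lip_names <- list(pc = c("P", "N", "OA", "OB"),
                    ps = c("P", "N", "OA", "OB", "OC1", "OC2"))
  atom <- unlist(lapply(is_ps, function(ps) if (ps) lip_names$ps else lip_names$pc))
  resname <- rep(ifelse(is_ps, "POPS", "POPC"), atoms_per_lipid)
  resid <- rep(seq_len(n_lip), atoms_per_lipid)
  n_shell <- n_lip * (spec$shell_waters_carbonyl + spec$shell_waters_phosphate)
  n_slab_w <- spec$waters_per_lipid * n_lip
  n_water <- n_shell + n_slab_w
  extra_res <- max(resid, 0L)
  add <- function(a, rn, k) {
    if (k > 0) {
      atom <<- c(atom, rep(a, k))
      resname <<- c(resname, rep(rn, k))
      resid <<- c(resid, extra_res + seq_len(k))
      extra_res <<- extra_res + k
    }
  }
  add("CA", "CA", spec$n_ca)
  add("CL", "CL", spec$n_cl)
  add("OW", "SOL", n_water)
  top <- topology(atom, resname, resid)
  top <- apply_group_map(top, default_group_map(), quiet = TRUE)
  n_at <- nrow(top)

  # overlap feasibility: water slab volume per particle must exceed a
  # 0.08 nm exclusion sphere
  slab_vol <- 2 * spec$water_pad * L * min(apl)
  n_slab_particles <- n_slab_w + spec$n_ca + spec$n_cl
  if (n_slab_particles > 0 &&
      slab_vol / n_slab_particles < (4 / 3) * pi * 0.08^3)
    stop("box too small to place requested atoms without overlap below 0.08 nm")

  p_vec <- c(spec$p_phos, spec$p_carb, spec$p_coo)
  p_tot <- sum(p_vec)
  q_off <- min(1, spec$dt / spec$mean_residence)
  q_on <- if (p_tot < 1) min(1, q_off * p_tot / (1 - p_tot)) else 1

  # per-lipid atom offsets within the lipid (before noise)
  lip_row0 <- c(0, cumsum(atoms_per_lipid))[seq_len(n_lip)]
  i_p <- lip_row0 + 1L
  i_n <- lip_row0 + 2L
  i_oa <- lip_row0 + 3L
  i_ob <- lip_row0 + 4L
  ps_ids <- which(is_ps)
  i_oc1 <- lip_row0[ps_ids] + 5L
  i_oc2 <- lip_row0[ps_ids] + 6L

  # site bookkeeping for bound ions: site atom row index per (type, instance)
  site_rows <- list(phos = i_p, carb = i_ob,
                    coo = if (length(ps_ids) > 0) i_oc1 else integer())

  bound_state <- matrix(FALSE, max(spec$n_ca, 1), spec$n_frames)[seq_len(spec$n_ca), , drop = FALSE]
  site_type <- matrix(NA_integer_, spec$n_ca, spec$n_frames)
  site_inst <- matrix(NA_integer_, spec$n_ca, spec$n_frames)

  draw_site_type <- function(k) {
    if (k == 0 || p_tot == 0) return(integer(0))
    sample.int(3, k, replace = TRUE, prob = p_vec)
  }
  n_inst <- c(n_lip, n_lip, length(ps_ids))

  if (spec$n_ca > 0) {
    st <- stats::runif(spec$n_ca) < p_tot
    ty <- rep(NA_integer_, spec$n_ca)
    inst <- rep(NA_integer_, spec$n_ca)
    ty[st] <- draw_site_type(sum(st))
    # initial instances distinct per site type where possible
    for (tt in 1:3) {
      sel <- which(st & ty == tt)
      if (length(sel) > 0)
        inst[sel] <- sample.int(n_inst[tt], length(sel),
                                replace = length(sel) > n_inst[tt])
    }
    for (f in seq_len(spec$n_frames)) {
      if (f > 1) {
        for (i in seq_len(spec$n_ca)) {
          if (st[i]) {
            if (stats::runif(1) < q_off) { st[i] <- FALSE; ty[i] <- NA; inst[i] <- NA }
          } else if (stats::runif(1) < q_on) {
            st[i] <- TRUE
            ty[i] <- draw_site_type(1)
            inst[i] <- sample.int(n_inst[ty[i]], 1)
          }
        }
      }
      bound_state[, f] <- st
      site_type[, f] <- ty
      site_inst[, f] <- inst
    }
  }

  coords <- array(NA_real_, c(n_at, 3, spec$n_frames))
  box <- matrix(NA_real_, spec$n_frames, 3)
  for (f in seq_len(spec$n_frames)) {
    lxy <- sqrt(L * apl[f])
    box[f, ] <- c(lxy, lxy, lz)
    pos <- matrix(NA_real_, n_at, 3)
    lx <- frac_x * lxy
    ly <- frac_y * lxy
    zc <- lz / 2                           # bilayer midplane
    pos[i_p, ] <- cbind(lx, ly, zc + leaflet * spec$z_phos)
    # P -> N direction from the tilt distribution about the outward normal
    if (spec$tilt_isotropic) {
      u <- runit(n_lip)           # full sphere: density ~ sin(angle), mean 90
    } else {
      phi <- rtrunc_angle(n_lip, spec$tilt_mean, spec$tilt_sd) * pi / 180
      psi <- stats::runif(n_lip, 0, 2 * pi)
      u <- cbind(sin(phi) * cos(psi), sin(phi) * sin(psi), cos(phi))
    }
    u[, 3] <- u[, 3] * leaflet             # outward component per leaflet
    pos[i_n, ] <- pos[i_p, ] + spec$d_pn * u
    pos[i_oa, ] <- cbind(lx + 0.06, ly, zc + leaflet * spec$z_carb_sn1)
    pos[i_ob, ] <- cbind(lx - 0.06, ly, zc + leaflet * spec$z_carb_sn2)
    if (length(ps_ids) > 0) {
      pos[i_oc1, ] <- cbind(lx[ps_ids] + 0.06, ly[ps_ids],
                            zc + leaflet[ps_ids] * spec$z_coo)
      pos[i_oc2, ] <- cbind(lx[ps_ids] - 0.06, ly[ps_ids],
                            zc + leaflet[ps_ids] * spec$z_coo)
    }
    row <- n_lip_atoms <- sum(atoms_per_lipid)
    place_slab <- function(k) {
      side <- sample(c(-1, 1), k, replace = TRUE)
      z <- zc + side * stats::runif(k, geom$slab_min, lz / 2)
      cbind(stats::runif(k, 0, lxy), stats::runif(k, 0, lxy), z)
    }
    if (spec$n_ca > 0) {
      ca_rows <- row + seq_len(spec$n_ca)
      free <- !bound_state[, f]
      if (any(free)) pos[ca_rows[free], ] <- place_slab(sum(free))
      if (any(!free)) {
        b <- which(!free)
        anchor_rows <- vapply(b, function(i)
          site_rows[[site_type[i, f]]][site_inst[i, f]], numeric(1))
        pos[ca_rows[b], ] <- pos[anchor_rows, , drop = FALSE] +
          spec$bound_distance * runit(length(b))
      }
      row <- row + spec$n_ca
    }
    if (spec$n_cl > 0) {
      pos[row + seq_len(spec$n_cl), ] <- place_slab(spec$n_cl)
      row <- row + spec$n_cl
    }
    if (n_water > 0) {
      w0 <- row
      kc <- spec$shell_waters_carbonyl
      kp <- spec$shell_waters_phosphate
      if (kc > 0) {
        anchors <- rep(i_ob, each = kc)
        pos[w0 + seq_along(anchors), ] <- pos[anchors, , drop = FALSE] +
          spec$shell_distance_carbonyl * runit(length(anchors))
        w0 <- w0 + length(anchors)
      }
      if (kp > 0) {
        anchors <- rep(i_p, each = kp)
        pos[w0 + seq_along(anchors), ] <- pos[anchors, , drop = FALSE] +
          spec$shell_distance_phosphate * runit(length(anchors))
        w0 <- w0 + length(anchors)
      }
      if (n_slab_w > 0) pos[w0 + seq_len(n_slab_w), ] <- place_slab(n_slab_w)
    }
    if (spec$noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(3 * n_at, 0, spec$noise_sd), n_at, 3)
    pos[, 1] <- wrap_box(pos[, 1], lxy)
    pos[, 2] <- wrap_box(pos[, 2], lxy)
    pos[, 3] <- wrap_box(pos[, 3], lz)
    coords[, , f] <- pos
  }

  traj <- md_trajectory(coords, box, (seq_len(spec$n_frames) - 1) * spec$dt, top)
  truth <- expected_statistics(spec)
  truth$bound_state <- bound_state
  truth$site_type <- site_type
  truth$seed <- seed
  list(trajectory = traj, truth = truth)
}

#' Write generator ground truth as JSON
#'
#' @param truth `membrane_truth` from [generate_membrane()]
#' @param path output path
#' @export
write_ground_truth <- function(truth, path) {
  out <- unclass(truth)
  out$bound_state <- NULL; out$site_type <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
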