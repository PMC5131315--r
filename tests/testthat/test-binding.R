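test_that("g(r) of a uniform random gas is 1 within Poisson error", {
  set.seed(30)
  box <- c(4, 4, 4)
  na <- 40; nb <- 400
  traj <- random_trajectory(na + nb, 10, box = box)
  res <- rdf(traj, seq_len(na), na + seq_len(nb), r_max = 1.9, bin_width = 0.1)
  # expected pair count per bin for a Poisson gas
  rho <- nb / prod(box)
  mu <- 10 * na * 4 * pi * res$r^2 * 0.1 * rho
  expect_true(all(abs(res$g - 1) < 3.5 / sqrt(mu)))
})

test_that("n(r) steps at the true pair distance, also across the boundary", {
  top <- topology(c("A", "B"), c("X", "X"), 1:2)
  pos <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.8))
  traj <- md_trajectory(pos, c(2, 2, 2), 0, top)
  res <- rdf(traj, 1L, 2L, r_max = 0.9, bin_width = 0.01)
  expect_equal(res$n[res$r < 0.295], rep(0, sum(res$r < 0.295)))
  expect_equal(res$n[res$r > 0.305], rep(1, sum(res$r > 0.305)))
  # pair split across the periodic boundary at true distance 0.25
  pos2 <- rbind(c(0.1, 1.0, 1.0), c(1.85, 1.0, 1.0))
  traj2 <- md_trajectory(pos2, c(2, 2, 2), 0, top)
  expect_equal(oracle_min_image_dist(pos2[1, ], pos2[2, ], c(2, 2, 2)), 0.25)
  res2 <- rdf(traj2, 1L, 2L, r_max = 0.9, bin_width = 0.01)
  expect_equal(min(res2$r[res2$n > 0]) , 0.245, tolerance = 0.011)
  expect_error(rdf(traj2, 1L, 2L, r_max = 1.5), "half the smallest")
})

test_that("first-shell cutoff sits at the first minimum after the first peak", {
  r <- seq(0.005, 0.8, by = 0.01)
  g1 <- 3 * exp(-(r - 0.27)^2 / (2 * 0.03^2)) + 1 / (1 + exp(-(r - 0.4) * 40))
  res <- structure(data.frame(r = r, g = g1, n = cumsum(g1)),
                   class = c("rdf_result", "data.frame"))
  cut <- first_shell_cutoff(res)
  expect_gt(cut, 0.3); expect_lt(cut, 0.42)
  expect_identical(attr(cut, "provenance"), "rdf")
  # two peaks: the first minimum is returned, not the global one
  g2 <- 3 * exp(-(r - 0.25)^2 / (2 * 0.03^2)) +
    2 * exp(-(r - 0.5)^2 / (2 * 0.05^2)) + 0.05
  res2 <- structure(data.frame(r = r, g = g2, n = cumsum(g2)),
                    class = c("rdf_result", "data.frame"))
  cut2 <- first_shell_cutoff(res2)
  expect_gt(cut2, 0.27); expect_lt(cut2, 0.45)
  # monotone g(r): user cutoff passthrough, else an error
  g3 <- 1 - exp(-r * 5)
  res3 <- structure(data.frame(r = r, g = g3, n = cumsum(g3)),
                    class = c("rdf_result", "data.frame"))
  cut3 <- first_shell_cutoff(res3, fallback = 0.42)
  expect_equal(as.numeric(cut3), 0.42)
  expect_identical(attr(cut3, "provenance"), "user")
  expect_error(first_shell_cutoff(res3), "no user cutoff")
})

test_that("coordination per group counts constructed neighbours exactly", {
  top <- topology(c("P", "CA", "CA"), c("POPC", "CA", "CA"), 1:3,
                  group = c("PHOS_P", "CA", "CA"))
  pos <- rbind(c(1, 1, 1), c(1.2, 1, 1), c(1, 1.2, 1))
  traj <- md_trajectory(pos, c(4, 4, 4), 0, top)
  g <- group_instances(top, "PHOS_P")
  expect_equal(as.numeric(coordination_per_group(traj, g, 2:3, 0.33)), 2)
  expect_equal(as.numeric(coordination_per_group(traj, g, 2:3, 0)), 0)
  expect_error(coordination_per_group(traj, list(), 2:3, 0.3), "empty")
})

test_that("pair counting matches the brute-force image-enumeration oracle", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(60:120, 1)
    box <- stats::runif(3, 1.5, 3)
    traj <- random_trajectory(n, 3, box = box)
    n_g <- 10
    groups <- split(seq_len(20), rep(seq_len(n_g), each = 2))
    ions <- (n - 19):n
    cutoff <- stats::runif(1, 0.2, 0.6)
    cn <- coordination_per_group(traj, groups, ions, cutoff)
    oracle_frames <- vapply(seq_len(3), function(f)
      sum(oracle_group_counts(frame_coords(traj, f), groups, ions,
                              box, cutoff)) / n_g, numeric(1))
    expect_equal(attr(cn, "per_frame"), oracle_frames)
  }
})

test_that("a fully bound synthesis gives lipids-per-ion by construction", {
  spec <- membrane_spec(lipids_per_leaflet = 64, ps_per_leaflet = 12,
                        n_frames = 5, noise_sd = 0, n_ca = 24,
                        p_phos = 1, mean_residence = Inf)
  traj <- generate_membrane(spec, seed = 2)$trajectory
  ions <- select_atoms(traj$topology, "CA")
  lp <- lipids_per_adsorbed_ion(traj, ions)
  expect_equal(as.numeric(lp), 128 / 24)
  expect_equal(attr(lp, "mean_adsorbed"), 24)
})

test_that("no contacts yields an infinite ratio with a warning", {
  spec <- membrane_spec(lipids_per_leaflet = 8, n_frames = 2, noise_sd = 0,
                        n_ca = 5, p_phos = 0)
  traj <- generate_membrane(spec, seed = 3)$trajectory
  ions <- select_atoms(traj$topology, "CA")
  expect_warning(lp <- lipids_per_adsorbed_ion(traj, ions), "infinite")
  expect_identical(as.numeric(lp), Inf)
})

test_that("half-bound ions double the lipids-per-ion ratio", {
  spec <- membrane_spec(lipids_per_leaflet = 32, n_frames = 60, dt = 0.5,
                        noise_sd = 0, n_ca = 32, p_phos = 0.5,
                        mean_residence = 1)
  gen <- generate_membrane(spec, seed = 4)
  traj <- gen$trajectory
  ions <- select_atoms(traj$topology, "CA")
  lp <- lipids_per_adsorbed_ion(traj, ions)
  # with p = 0.5 the expected ratio is 2 * n_lipids / n_ions = 4
  se_frac <- gen$truth$se_bound_fraction
  observed_frac <- attr(lp, "mean_adsorbed") / 32
  expect_lt(abs(observed_frac - 0.5), 3 * se_frac)
})

test_that("coordination of adsorbed ions matches construction and the oracle", {
  # each bound ion bridges exactly one phosphate by construction
  spec <- membrane_spec(lipids_per_leaflet = 16, n_frames = 4, noise_sd = 0,
                        n_ca = 8, p_phos = 1, mean_residence = Inf)
  gen <- generate_membrane(spec, seed = 5)
  traj <- gen$trajectory
  top <- traj$topology
  ions <- select_atoms(top, "CA")
  sets <- list(phosphate = group_instances(top, "PHOS_P"),
               carbonyl = group_instances(top, c("CARBONYL_O_SN1",
                                                 "CARBONYL_O_SN2")))
  co <- coordination_of_adsorbed(traj, ions, sets,
                                 c(phosphate = 0.33, carbonyl = 0.33))
  expect_equal(as.numeric(co["phosphate"]), 1)
  # a phosphate-bound ion can also sit within the carbonyl cutoff of the
  # same lipid; the ground truth carries that geometric cross term
  exp_carb <- gen$truth$coordination_of_adsorbed[["carbonyl"]]
  se <- sqrt(exp_carb * (1 - exp_carb) / (8 * 4))
  expect_lt(abs(as.numeric(co["carbonyl"]) - exp_carb), 3.5 * se + 1e-9)
  # randomized system: equality with exhaustive enumeration, every frame
  set.seed(32)
  n <- 90
  box <- c(2.5, 2.5, 2.5)
  rt <- random_trajectory(n, 2, box = box)
  g_a <- split(1:30, rep(1:15, each = 2))
  ions2 <- 61:70
  all_atoms <- unlist(g_a)
  cut <- 0.45
  co2 <- coordination_of_adsorbed(rt, ions2, list(grp = g_a), c(grp = cut),
                                  lipid_sel = all_atoms, contact_cutoff = cut)
  manual <- unlist(lapply(1:2, function(f) {
    pos <- frame_coords(rt, f)
    per_ion <- oracle_group_counts_per_ion(pos, g_a, ions2, box, cut)
    ads <- rowSums(per_ion) > 0
    rowSums(per_ion > 0)[ads]
  }))
  expect_equal(as.numeric(co2["grp"]), mean(manual))
})

test_that("an ion bound to two groups of one lipid counts once per group", {
  top <- topology(c("P", "OC1", "OC2", "CA"), c("POPS", "POPS", "POPS", "CA"),
                  c(1L, 1L, 1L, 2L),
                  group = c("PHOS_P", "COO_PS", "COO_PS", "CA"))
  pos <- rbind(c(1, 1, 1), c(1.3, 1, 1), c(1.3, 1.15, 1), c(1.15, 1.05, 1))
  traj <- md_trajectory(pos, c(4, 4, 4), 0, top)
  sets <- list(phosphate = group_instances(top, "PHOS_P"),
               carboxylate = group_instances(top, "COO_PS"))
  co <- coordination_of_adsorbed(traj, 4L, sets,
                                 c(phosphate = 0.33, carboxylate = 0.33),
                                 lipid_sel = 1:3)
  expect_equal(as.numeric(co["phosphate"]), 1)
  expect_equal(as.numeric(co["carboxylate"]), 1)
})

test_that("hydration counts placed shell waters and respects the cutoffs", {
  spec <- membrane_spec(lipids_per_leaflet = 16, n_frames = 3, noise_sd = 0,
                        shell_waters_carbonyl = 2, shell_waters_phosphate = 3,
                        waters_per_lipid = 4)
  gen <- generate_membrane(spec, seed = 6)
  hyd <- hydration_numbers(gen$trajectory)
  truth <- gen$truth$hydration
  # sigma = 0: deterministic up to cross-shell geometry captured by the truth
  expect_equal(hyd$mean[hyd$group == "carbonyl"], truth[["carbonyl"]],
               tolerance = 0.05)
  expect_equal(hyd$mean[hyd$group == "phosphate"], truth[["phosphate"]],
               tolerance = 0.05)
  # boundary: a water just outside 0.24 nm of a carbonyl O is not counted
  top <- topology(c("OB", "OW", "OW"), c("POPC", "SOL", "SOL"), 1:3,
                  group = c("CARBONYL_O_SN2", "WATER_O", "WATER_O"))
  pos <- rbind(c(1, 1, 1), c(1.25, 1, 1), c(1.2, 1, 1))
  tr <- md_trajectory(pos, c(4, 4, 4), 0, top)
  h <- hydration_numbers(tr)
  expect_equal(h$mean[h$group == "carbonyl"], 1)
  top0 <- topology("OB", "POPC", 1L, group = "CARBONYL_O_SN2")
  tr0 <- md_trajectory(matrix(1, 1, 3), c(4, 4, 4), 0, top0)
  expect_error(hydration_numbers(tr0), "no WATER_O")
})

test_that("hydration equals the brute-force oracle on random water slabs", {
  set.seed(33)
  n_lip <- 6
  top <- topology(
    atom = c(rep(c("P", "OA", "OB"), n_lip), rep("OW", 40)),
    resname = c(rep("POPC", 3 * n_lip), rep("SOL", 40)),
    resid = c(rep(seq_len(n_lip), each = 3), n_lip + seq_len(40)),
    group = c(rep(c("PHOS_P", "CARBONYL_O_SN1", "CARBONYL_O_SN2"), n_lip),
              rep("WATER_O", 40)))
  box <- c(2, 2, 2)
  coords <- array(stats::runif((3 * n_lip + 40) * 3 * 2) * 2,
                  c(3 * n_lip + 40, 3, 2))
  traj <- md_trajectory(coords, box, 0:1, top)
  hyd <- hydration_numbers(traj, cutoffs = c(carbonyl = 0.4, phosphate = 0.5))
  w_idx <- which(top$group == "WATER_O")
  for (g in c("carbonyl", "phosphate")) {
    tags <- if (g == "carbonyl") c("CARBONYL_O_SN1", "CARBONYL_O_SN2") else "PHOS_P"
    cut <- if (g == "carbonyl") 0.4 else 0.5
    groups <- group_instances(top, tags)
    manual <- unlist(lapply(1:2, function(f) {
      pos <- frame_coords(traj, f)
      vapply(groups, function(gi) {
        d <- oracle_pair_distances(pos[gi, , drop = FALSE],
                                   pos[w_idx, , drop = FALSE], box)
        sum(apply(d <= cut, 2, any))
      }, numeric(1))
    }))
    expect_equal(hyd$mean[hyd$group == g], mean(manual))
    expect_equal(hyd$sd[hyd$group == g], stats::sd(manual))
  }
})

test_that("residence intervals follow the stated gap-bridging semantics", {
  rs <- residence_times(c(TRUE, TRUE, TRUE, FALSE, FALSE), dt = 1)
  expect_equal(rs$intervals$length_ns, 3)
  expect_equal(rs$first_desorption_ns, 3)
  rs1 <- residence_times(c(TRUE, TRUE, FALSE, TRUE, TRUE), dt = 1,
                         gap_tolerance = 1)
  expect_equal(rs1$intervals$length_ns, 5)
  rs0 <- residence_times(c(TRUE, TRUE, FALSE, TRUE, TRUE), dt = 1,
                         gap_tolerance = 0)
  expect_equal(sort(rs0$intervals$length_ns), c(2, 2))
})

test_that("the Markov mean residence time is recovered from timelines", {
  spec <- membrane_spec(lipids_per_leaflet = 16, n_frames = 400, dt = 1,
                        noise_sd = 0, n_ca = 50, p_phos = 0.5,
                        mean_residence = 10)
  gen <- generate_membrane(spec, seed = 7)
  tl <- structure(gen$truth$bound_state, class = "contact_timeline",
                  time = gen$trajectory$time)
  rs <- residence_times(tl, dt = 1, drop_censored = TRUE)
  se <- rs$mean_ns / sqrt(rs$n_intervals)
  expect_lt(abs(rs$mean_ns - 10), 3 * se)
})

test_that("binding results are invariant under rigid translation with wrap", {
  spec <- membrane_spec(lipids_per_leaflet = 16, n_frames = 3, noise_sd = 0.02,
                        n_ca = 10, p_phos = 0.6, waters_per_lipid = 2)
  traj <- generate_membrane(spec, seed = 8)$trajectory
  shift <- c(0.9, -0.4, 1.3)
  tr2 <- traj
  for (f in seq_len(n_frames(traj)))
    for (k in 1:3)
      tr2$coords[, k, f] <- (traj$coords[, k, f] + shift[k]) %% traj$box[f, k]
  ions <- select_atoms(traj$topology, "CA")
  g <- group_instances(traj$topology, "PHOS_P")
  c1 <- coordination_per_group(traj, g, ions, 0.33)
  c2 <- coordination_per_group(tr2, g, ions, 0.33)
  expect_equal(as.numeric(c1), as.numeric(c2), tolerance = 1e-12)
  h1 <- hydration_numbers(traj)
  h2 <- hydration_numbers(tr2)
  expect_equal(h1$mean, h2$mean, tolerance = 1e-12)
})

test_that("n(r) at a cutoff agrees with direct coordination counting", {
  set.seed(34)
  n <- 120
  box <- c(3, 3, 3)
  traj <- random_trajectory(n, 4, box = box)
  a_idx <- 1:20
  b_idx <- 21:120
  res <- rdf(traj, a_idx, b_idx, r_max = 1.2, bin_width = 0.01)
  groups <- as.list(a_idx)
  cutoff <- res$r[60] + 0.005   # a bin edge, to match the histogram boundary
  n_at_cut <- res$n[60]
  cn <- coordination_per_group(traj, groups, b_idx, cutoff)
  # n(r) counts all ions per A; with single-atom groups and counts 0/1 they
  # can differ when two B atoms share one A; compare total-count variants
  total <- vapply(seq_len(4), function(f) {
    d <- oracle_pair_distances(frame_coords(traj, f)[a_idx, ],
                               frame_coords(traj, f)[b_idx, ], box)
    sum(d <= cutoff)
  }, numeric(1))
  expect_equal(n_at_cut, mean(total) / length(a_idx), tolerance = 1e-12)
})
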