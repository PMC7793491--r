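test_that("Kabsch superposition inverts exact rigid motions", {
  set.seed(101)
  ref <- matrix(rnorm(150), ncol = 3)

  # identity
  tr <- kabsch_superpose(ref, ref)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_false(tr$degenerate)

  # 90 degrees about z plus a translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mobile <- ref %*% t(Rz) + matrix(rep(c(1, 2, 3), each = 50), ncol = 3)
  tr <- kabsch_superpose(mobile, ref)
  fitted <- apply_transform(mobile, tr)
  expect_lt(sqrt(mean(rowSums((fitted - ref)^2))), 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
})

test_that("fitting never increases RMSD and always yields a proper rotation", {
  set.seed(202)
  for (rep in 1:20) {
    ref <- matrix(rnorm(150), ncol = 3)
    mobile <- ref %*% t(random_rotation()) + rnorm(3) +
      matrix(rnorm(150, sd = 0.4), ncol = 3)
    pre <- sqrt(mean(rowSums((mobile - ref)^2)))
    tr <- kabsch_superpose(mobile, ref)
    post <- sqrt(mean(rowSums((apply_transform(mobile, tr) - ref)^2)))
    expect_lte(post, pre + 1e-12)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  }
})

test_that("collinear coordinates fall back to a flagged translation-only fit", {
  line <- cbind(1:5, 0, 0)
  tr <- kabsch_superpose(line + 2, line)
  expect_true(tr$degenerate)
  expect_equal(tr$rotation, diag(3))
  # translation still recovered
  expect_equal(apply_transform(line + 2, tr), line, ignore_attr = TRUE)
})

test_that("RMSD series matches analytic values on constructed frames", {
  st <- ccct3_structure()
  static <- gaussian_trajectory(st, 0, n_frames = 4, seed = 1)
  expect_equal(rmsd_series(static)$value, rep(0, 4), tolerance = 1e-12)

  # rigid translation by (3,4,0): unfitted RMSD 5, fitted 0
  moved <- static
  moved$frames[[3]] <- sweep(moved$frames[[3]], 2L, c(3, 4, 0), `+`)
  unfit <- rmsd_series(moved, fit_selection = NULL)
  expect_equal(unfit$value[3], 5, tolerance = 1e-12)
  expect_equal(rmsd_series(moved)$value[3], 0, tolerance = 1e-9)

  # two atoms displaced +/-1 along x, no fitting: RMSD = 1
  atoms <- bare_atoms(2)
  f0 <- rbind(c(-2, 0, 0), c(2, 0, 0))
  f1 <- rbind(c(-1, 0, 0), c(1, 0, 0))
  two <- raw_trajectory(atoms, list(f0, f1))
  expect_equal(rmsd_series(two, fit_selection = NULL)$value[2], 1)
})

test_that("fitted RMSD is invariant under rigid motion of every frame", {
  set.seed(303)
  st <- ccct3_structure()
  traj <- gaussian_trajectory(st, 0.7, n_frames = 20, seed = 7)
  base <- rmsd_series(traj)$value

  moved <- traj
  for (i in seq_along(moved$frames)) {
    moved$frames[[i]] <- moved$frames[[i]] %*% t(random_rotation()) +
      matrix(rnorm(3, sd = 5), n_atoms(st), 3, byrow = TRUE)
  }
  expect_equal(rmsd_series(moved)$value, base, tolerance = 1e-6)

  # and fitted <= unfitted frame by frame
  expect_true(all(rmsd_series(moved)$value <=
                    rmsd_series(moved, fit_selection = NULL)$value + 1e-9))
})

test_that("whole-selection MSD is the atom-weighted mix of region MSDs", {
  seq <- ccct3_seq()
  st <- toy_imotif_structure(seq)
  regions <- assign_regions(seq)
  traj <- gaussian_trajectory(st, c(core = 0.3, loop = 1.2), n_frames = 15,
                              regions = regions, seed = 5)
  whole <- select_atoms(st, regions, region = "whole")
  core <- select_atoms(st, regions, region = "core")
  loop <- select_atoms(st, regions, region = "loop")
  # same fit frame for all three measurements
  msd <- function(sel) {
    rmsd_series(traj, selection = sel, fit_selection = whole)$value^2
  }
  mixed <- (length(core) * msd(core) + length(loop) * msd(loop)) / length(whole)
  expect_equal(msd(whole), mixed, tolerance = 1e-10)
})

test_that("time averaging respects the burn-in window", {
  s <- tspc4:::new_traj_series(c(0, 1, 2, 3), c(1, 2, 3, 4), "RMSD")
  expect_equal(time_average_rmsd(s), 2.5)
  expect_equal(time_average_rmsd(s, burn_in = 0.5), 3)
  const <- tspc4:::new_traj_series(0:9, rep(2, 10), "RMSD")
  expect_equal(time_average_rmsd(const), 2)
  expect_error(time_average_rmsd(s, burn_in = 10), "no frames")
})

test_that("RMSF recovers the Gaussian closed form sigma * sqrt(3)", {
  st <- ccct3_structure()
  traj <- gaussian_trajectory(st, 0.5, n_frames = 4000, seed = 9)
  out <- rmsf_by_residue(traj)
  expect_equal(mean(out$rmsf), 0.5 * sqrt(3), tolerance = 0.03)

  static <- gaussian_trajectory(st, 0, n_frames = 5, seed = 1)
  expect_equal(rmsf_by_residue(static)$rmsf, rep(0, 21))
})

test_that("loop residues fluctuate more than core when built that way", {
  seq <- ccct3_seq()
  st <- toy_imotif_structure(seq)
  regions <- assign_regions(seq)
  traj <- gaussian_trajectory(st, c(core = 0.3, loop = 0.9), n_frames = 800,
                              regions = regions, seed = 13)
  out <- rmsf_by_residue(traj)
  core_vals <- out$rmsf[regions[out$resno] == "core"]
  loop_vals <- out$rmsf[startsWith(regions[out$resno], "loop")]
  expect_true(min(loop_vals) > max(core_vals))
})

test_that("radius of gyration matches hand-computed geometries", {
  # single atom
  one <- raw_trajectory(bare_atoms(1), list(matrix(c(1, 2, 3), 1)))
  expect_equal(rg_series(one)$value, 0)
  # two equal masses 2d apart: Rg = d
  d <- 1.7
  two <- raw_trajectory(bare_atoms(2),
                        list(rbind(c(-d, 0, 0), c(d, 0, 0))))
  expect_equal(rg_series(two)$value, d)
  # 8 unit masses at cube corners, edge 2: Rg = sqrt(3)
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  cube <- raw_trajectory(bare_atoms(8), list(corners))
  expect_equal(rg_series(cube)$value, sqrt(3))
  # mass weighting moves Rg toward the heavy atom
  atoms <- bare_atoms(2); atoms$mass <- c(3, 1)
  uneven <- raw_trajectory(atoms, list(rbind(c(0, 0, 0), c(4, 0, 0))))
  expect_equal(rg_series(uneven)$value, sqrt(3 / 4 * 1 + 1 / 4 * 9), tolerance = 1e-12)
})

test_that("RDF of a fixed pair is a sharp peak in the right bin", {
  atoms <- bare_atoms(2)
  traj <- raw_trajectory(atoms, list(rbind(c(0, 0, 0), c(2, 0, 0))))
  prof <- rdf(traj, 1L, 2L, dR = 0.1, max_r = 5)
  hit <- prof$g > 0
  expect_equal(sum(hit), 1L)
  expect_equal(prof$r[hit], 2.05)  # bin [2.0, 2.1)
  expect_equal(attr(prof, "n_distances"), 1L)
})

test_that("RDF conserves counts and the literal normalisation differs as printed", {
  traj <- ideal_gas_trajectory(0.03, 12, n_frames = 3, seed = 21)
  sel <- seq_len(n_atoms(traj))
  dR <- 0.25; max_r <- 5
  shell <- rdf(traj, sel, sel, dR = dR, max_r = max_r, box = 12)
  lit <- rdf(traj, sel, sel, dR = dR, max_r = max_r, box = 12,
             normalization = "literal")
  # same histogram, different per-bin expected counts
  lower <- shell$r - dR / 2
  vol_shell <- (4 * pi / 3) * ((lower + dR)^3 - lower^3)
  vol_lit <- (4 * pi / 3) * (lower + dR)^3 - (4 * pi / 3) * dR^3
  expect_equal(lit$g * vol_lit, shell$g * vol_shell, tolerance = 1e-12)
  # raw distances within range equal the histogram mass
  counts <- shell$g * 3 * length(sel) * 0.03 * vol_shell
  d <- tspc4:::cross_distances(traj$frames[[1]], traj$frames[[1]], 12)
  diag(d) <- NA
  n_in <- sum(vapply(traj$frames, function(f) {
    dd <- tspc4:::cross_distances(f, f, 12); diag(dd) <- NA
    sum(dd < max_r, na.rm = TRUE)
  }, numeric(1)))
  expect_equal(sum(counts), n_in, tolerance = 1e-9)

  expect_error(rdf(traj, sel, integer(0)), "non-empty")
  expect_warning(rdf(raw_trajectory(bare_atoms(2),
                                    list(rbind(c(0, 0, 0), c(50, 0, 0)))),
                     1L, 2L, max_r = 5), "all-zero")
})

test_that("C:C+ distance monitoring classifies maintained and disrupted pairs", {
  seq <- ccct3_seq()
  st <- toy_imotif_structure(seq)
  top <- cc_pair_topology(seq)

  static <- gaussian_trajectory(st, 0, n_frames = 10, seed = 1)
  rep0 <- cc_pair_distances(static, top)
  expect_true(all(rep0$status$status == "maintained"))
  expect_equal(unname(rep0$distances[1, ]), rep(2.8, 6), tolerance = 1e-12)

  drift <- pair_drift_trajectory(st, top, "C2c:C4c", drift_distance = 8,
                                 drift_fraction = 0.6, n_frames = 100)
  rep1 <- cc_pair_distances(drift, top)
  expect_equal(rep1$status$status[rep1$status$label == "C2c:C4c"], "disrupted")
  expect_true(all(rep1$status$status[rep1$status$label != "C2c:C4c"] ==
                    "maintained"))
  expect_equal(rep1$status$fraction_beyond[rep1$status$label == "C2c:C4c"], 0.6)

  # missing N3 atom is a contract violation
  broken <- static
  broken$atoms$name[broken$atoms$resno == top$res_i[1]] <- "C1'"
  expect_error(cc_pair_distances(broken, top), "no unique N3")
})

test_that("a disrupted pair raises the core-region time-averaged RMSD", {
  seq <- ccct3_seq()
  st <- toy_imotif_structure(seq)
  top <- cc_pair_topology(seq)
  regions <- assign_regions(seq)
  core <- select_atoms(st, regions, region = "core")

  control <- pair_drift_trajectory(st, top, "C2c:C4c", drift_fraction = 0,
                                   n_frames = 50)
  disrupted <- pair_drift_trajectory(st, top, "C2c:C4c", drift_distance = 8,
                                     drift_fraction = 0.6, n_frames = 50)
  avg <- function(traj) {
    time_average_rmsd(rmsd_series(traj, selection = core))
  }
  expect_gt(avg(disrupted), avg(control))
})

test_that("loop contact fraction counts contact frames exactly", {
  seq <- ccct3_seq()
  st <- toy_imotif_structure(seq)  # loops ~120 degrees apart, far from contact
  regions <- assign_regions(seq)
  apart <- gaussian_trajectory(st, 0, n_frames = 10, seed = 1)
  expect_equal(loop_contact_fraction(apart, regions), 0)

  i1 <- select_atoms(st, regions, region = "loop1")
  i3 <- select_atoms(st, regions, region = "loop3")
  touching <- apart
  for (i in seq_along(touching$frames)) {
    touching$frames[[i]][i3, ] <- touching$frames[[i]][i1, ]
  }
  expect_equal(loop_contact_fraction(touching, regions), 1)

  partial <- apart
  for (i in 1:4) partial$frames[[i]][i3, ] <- partial$frames[[i]][i1, ]
  expect_equal(loop_contact_fraction(partial, regions), 0.4)

  expect_error(loop_contact_fraction(apart, rep("core", 21)), "no residues")
})

test_that("fitted RMSD agrees with an independent superposition engine", {
  skip_if_not_installed("bio3d")
  st <- ccct3_structure()
  traj <- gaussian_trajectory(st, 0.9, n_frames = 12, seed = 31)
  mine <- rmsd_series(traj)$value
  ref_flat <- as.numeric(t(traj$frames[[1]]))
  xyz_mat <- do.call(rbind, lapply(traj$frames, function(f) as.numeric(t(f))))
  theirs <- bio3d::rmsd(ref_flat, xyz_mat, fit = TRUE)
  # bio3d rounds its RMSD output to 3 decimals
  expect_equal(mine, as.numeric(theirs), tolerance = 1e-3)
})
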