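#' @importFrom stats rnorm runif
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  has <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit(
    if (has) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  )
  set.seed(seed)
  expr
}

#' Build a deterministic pseudo-atom i-motif structure
#'
#' Places one bead per residue (named `N3`, unit mass) in an idealised
#' i-motif geometry: the four cytosine tracts form two intercalated stacks
#' of C:C+ pairs — duplex 1/3 pairs alternate along the stacking axis with
#' duplex 2/4 pairs, the two duplexes rotated 90 degrees about it — with
#' every aligned-register N3-N3 pair distance set to `pair_distance`. Loop
#' residues lie on arcs at `tract_separation` from the axis, at azimuths
#' 120 degrees apart, so loops are well separated unless moved. The geometry
#' is a scaffold for testing region logic and distance monitors, not a
#' physical model.
#'
#' @param seq an `imotif_sequence`.
#' @param rise stacking rise between consecutive pair planes in A
#'   (default 3.1; must be > 0).
#' @param tract_separation loop arc radius from the stack axis in A
#'   (default 8).
#' @param pair_distance N3-N3 distance within each C:C+ pair in A
#'   (default 2.8).
#' @return An `md_structure` with `nchar(seq$sequence)` atoms, in residue
#'   order.
#' @examples
#' st <- toy_imotif_structure(parse_imotif("d[(CCCTTT)3CCC]"))
#' n_atoms(st)  # 21
#' @export
toy_imotif_structure <- function(seq, rise = 3.1, tract_separation = 8,
                                 pair_distance = 2.8) {
  stopifnot(inherits(seq, "imotif_sequence"))
  if (rise <= 0) stop("stacking rise must be positive")
  if (tract_separation <= 0) stop("tract separation must be positive")
  if (pair_distance <= 0) stop("pair distance must be positive")
  n <- nchar(seq$sequence)
  L <- seq$tract_length
  xyz <- matrix(NA_real_, n, 3L)
  half <- pair_distance / 2
  for (i in seq_len(L)) {
    z13 <- (i - 1L) * 2 * rise        # duplex 1/3 pair planes
    z24 <- z13 + rise                 # intercalated duplex 2/4 planes
    xyz[seq$tracts[[1]][1] + i - 1L, ] <- c(+half, 0, z13)
    xyz[seq$tracts[[3]][1] + i - 1L, ] <- c(-half, 0, z13)
    xyz[seq$tracts[[2]][1] + i - 1L, ] <- c(0, +half, z24)
    xyz[seq$tracts[[4]][1] + i - 1L, ] <- c(0, -half, z24)
  }
  for (k in 1:3) {
    sp <- seq$loops[[k]]
    m <- sp[2] - sp[1] + 1L
    z_from <- xyz[sp[1] - 1L, 3]
    z_to <- xyz[sp[2] + 1L, 3]
    theta <- 2 * pi * k / 3
    for (j in seq_len(m)) {
      phi <- theta + (j - (m + 1) / 2) * 0.25
      zj <- z_from + (z_to - z_from) * j / (m + 1)
      xyz[sp[1] + j - 1L, ] <- c(tract_separation * cos(phi),
                                 tract_separation * sin(phi), zj)
    }
  }
  base <- strsplit(seq$sequence, "")[[1]]
  atoms <- data.frame(
    name = "N3",
    resno = seq_len(n),
    resname = paste0("D", base),
    element = "N",
    mass = 1.0,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, xyz)
}

# Resolve a per-residue sigma vector from a scalar or named region spec
# (names among core/loop/loop1/loop2/loop3; "loop" covers all loops).
resolve_sigma <- function(sigma, regions) {
  if (is.null(names(sigma))) {
    stopifnot(length(sigma) == 1L)
    return(rep(sigma, length(regions)))
  }
  out <- rep(NA_real_, length(regions))
  for (nm in names(sigma)) {
    hit <- if (nm == "loop") startsWith(regions, "loop") else regions == nm
    out[hit] <- sigma[[nm]]
  }
  if (anyNA(out)) {
    stop("sigma spec does not cover regions: ",
         paste(unique(regions[is.na(out)]), collapse = ", "))
  }
  out
}

#' Generate a Gaussian-fluctuation trajectory
#'
#' Each frame is the reference structure plus independent Gaussian noise on
#' every coordinate, with a per-region standard deviation. Frames are
#' uncorrelated in time, which keeps the statistics closed-form: the
#' expected unfitted RMSF is `sigma * sqrt(3)` and the expected unfitted
#' per-frame mean-square deviation is the atom-average of `3 * sigma_i^2`.
#' Identical seeds give bit-identical trajectories.
#'
#' @param structure reference `md_structure`.
#' @param sigma per-coordinate displacement sd in A: a single number, or a
#'   named vector over regions (e.g. `c(core = 0.3, loop = 1.5)`), which
#'   requires `regions`.
#' @param n_frames number of frames (>= 2).
#' @param regions per-residue labels from [assign_regions()] (needed only
#'   for region-specific `sigma`).
#' @param frame_interval ps between frames (default 0.5).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @param first_frame_exact emit the unperturbed reference as frame 1
#'   (default `FALSE`), useful when the first frame serves as the RMSD
#'   reference.
#' @return An `md_trajectory`.
#' @export
gaussian_trajectory <- function(structure, sigma, n_frames, regions = NULL,
                                frame_interval = 0.5, seed = NULL,
                                first_frame_exact = FALSE) {
  stopifnot(inherits(structure, "md_structure"), n_frames >= 2L)
  sig_res <- if (is.null(names(sigma))) {
    rep(sigma[[1]], max(structure$atoms$resno))
  } else {
    if (is.null(regions)) stop("region-specific sigma requires a region map")
    resolve_sigma(sigma, regions)
  }
  stopifnot(all(sig_res >= 0))
  sig_atom <- sig_res[structure$atoms$resno]
  nat <- n_atoms(structure)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      if (first_frame_exact && i == 1L) return(structure$xyz)
      structure$xyz + matrix(rnorm(nat * 3L, sd = sig_atom), nat, 3L)
    })
  })
  new_trajectory(structure$atoms, frames, frame_interval)
}

#' Generate trajectories across a temperature set
#'
#' Builds one Gaussian-fluctuation trajectory per temperature, either from
#' an explicit `sigma_schedule` or — when `target_rmsd` is given — with the
#' noise amplitude solved so that each temperature's time-averaged best-fit
#' whole-molecule RMSD (first frame as reference) hits the target.
#'
#' The solve works on fixed noise: the standard-normal draws `Z` for a
#' temperature are generated once from the seed and frames are
#' `reference + sigma * Z`, making the measured average RMSD a smooth,
#' strictly increasing, deterministic function of `sigma` that is bisected
#' against the target (closed-form `target / sqrt(3 (N - 2) / N)` seeds the
#' bracket). Frame 1 is the exact reference in each trajectory.
#'
#' @param structure reference `md_structure`.
#' @param seq the `imotif_sequence` (for region-aware selections).
#' @param temps temperatures in K (default `c(280, 300, 320, 340, 360)`).
#' @param n_frames frames per trajectory (default 400).
#' @param sigma_schedule named numeric vector of per-temperature sigma (A);
#'   ignored when `target_rmsd` is given.
#' @param target_rmsd optional per-temperature target time-averaged RMSD
#'   (A), recycled to `length(temps)`; all values must be `>= 0`.
#' @param heavy_only measure the tuning RMSD on heavy atoms (default `TRUE`).
#' @param seed RNG seed; temperature i uses `seed + i`.
#' @param tol relative tuning tolerance on the target (default 0.005).
#' @return Named list of `md_trajectory` objects (names = temperatures),
#'   with attribute `sigma` giving the per-temperature amplitudes used.
#' @export
temperature_trajectory_set <- function(structure, seq,
                                       temps = c(280, 300, 320, 340, 360),
                                       n_frames = 400L,
                                       sigma_schedule = NULL,
                                       target_rmsd = NULL,
                                       heavy_only = TRUE,
                                       seed = NULL, tol = 0.005) {
  stopifnot(inherits(structure, "md_structure"),
            inherits(seq, "imotif_sequence"),
            length(temps) >= 2L, !is.unsorted(temps, strictly = TRUE))
  regions <- assign_regions(seq)
  sel <- select_atoms(structure, regions, region = "whole",
                      heavy_only = heavy_only)
  nat <- n_atoms(structure)
  if (!is.null(target_rmsd)) {
    target_rmsd <- rep_len(target_rmsd, length(temps))
    if (any(target_rmsd < 0)) stop("target RMSD values must be non-negative")
  } else {
    if (is.null(sigma_schedule)) stop("supply sigma_schedule or target_rmsd")
    sigma_schedule <- rep_len(sigma_schedule, length(temps))
  }
  out <- vector("list", length(temps))
  sigmas <- numeric(length(temps))
  for (i in seq_along(temps)) {
    ti_seed <- if (is.null(seed)) NULL else seed + i
    if (is.null(target_rmsd)) {
      sigmas[i] <- sigma_schedule[i]
      out[[i]] <- gaussian_trajectory(structure, sigmas[i], n_frames,
                                      seed = ti_seed,
                                      first_frame_exact = TRUE)
      next
    }
    target <- target_rmsd[i]
    if (target == 0) {
      sigmas[i] <- 0
      out[[i]] <- gaussian_trajectory(structure, 0, n_frames,
                                      seed = ti_seed,
                                      first_frame_exact = TRUE)
      next
    }
    Z <- with_seed(ti_seed, {
      lapply(seq_len(n_frames - 1L), function(j) matrix(rnorm(nat * 3L), nat, 3L))
    })
    build <- function(s) {
      frames <- c(list(structure$xyz),
                  lapply(Z, function(z) structure$xyz + s * z))
      new_trajectory(structure$atoms, frames, 0.5)
    }
    measure <- function(s) {
      time_average_rmsd(rmsd_series(build(s), selection = sel))
    }
    # closed-form Gaussian expectation brackets the root; expand if needed
    guess <- target / sqrt(3 * (length(sel) - 2) / length(sel))
    lo <- 0; hi <- 2 * guess
    while (measure(hi) < target) hi <- hi * 2
    for (iter in 1:60) {
      mid <- (lo + hi) / 2
      if (measure(mid) < target) lo <- mid else hi <- mid
      if ((hi - lo) < tol * guess) break
    }
    sigmas[i] <- (lo + hi) / 2
    out[[i]] <- build(sigmas[i])
  }
  names(out) <- as.character(temps)
  names(sigmas) <- as.character(temps)
  attr(out, "sigma") <- sigmas
  out
}

#' Generate a synthetic two-state CD melt curve
#'
#' Ellipticity follows a two-state sigmoid between folded and unfolded
#' baselines: `theta(T) = theta_u + (theta_f - theta_u) / (1 + exp((T - tm)
#' / width))` plus optional linear baseline slopes and Gaussian noise. With
#' flat baselines and no noise the first-derivative extremum sits exactly at
#' `tm`. The default ramp (293-353 K at 0.2 K pitch) mirrors a standard
#' 20-80 degrees C melting experiment.
#'
#' @param tm transition midpoint in K; must lie inside `t_range`.
#' @param width transition width parameter in K (> 0; default 3).
#' @param theta_folded,theta_unfolded baseline ellipticities in mdeg
#'   (defaults 6 and 0.5, typical of the 285 nm i-motif band).
#' @param baseline_slopes length-2 mdeg/K slopes of the folded and unfolded
#'   baselines (default `c(0, 0)`).
#' @param noise_sd Gaussian noise sd in mdeg (default 0).
#' @param t_range temperature ramp limits in K (default `c(293, 353)`).
#' @param pitch temperature step in K (default 0.2).
#' @param direction `"heating"` or `"annealing"` (annealing reverses the
#'   ramp).
#' @param seed RNG seed for the noise.
#' @return A `melt_curve`; generator parameters are attached as attribute
#'   `params`.
#' @export
synth_melt_curve <- function(tm, width = 3, theta_folded = 6,
                             theta_unfolded = 0.5,
                             baseline_slopes = c(0, 0), noise_sd = 0,
                             t_range = c(293, 353), pitch = 0.2,
                             direction = c("heating", "annealing"),
                             seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(width > 0, pitch > 0, length(t_range) == 2L,
            t_range[1] < t_range[2])
  if (tm <= t_range[1] || tm >= t_range[2]) {
    stop("tm (", tm, " K) must lie inside the temperature range [",
         t_range[1], ", ", t_range[2], "] K")
  }
  temp <- seq(t_range[1], t_range[2], by = pitch)
  f <- 1 / (1 + exp((temp - tm) / width))   # folded fraction
  t0 <- temp - t_range[1]
  theta <- (theta_folded + baseline_slopes[1] * t0) * f +
    (theta_unfolded + baseline_slopes[2] * t0) * (1 - f)
  if (noise_sd > 0) {
    theta <- theta + with_seed(seed, rnorm(length(theta), sd = noise_sd))
  }
  if (direction == "annealing") {
    temp <- rev(temp); theta <- rev(theta)
  }
  cu <- melt_curve(temp, theta, direction = direction, celsius = "no")
  attr(cu, "params") <- list(tm = tm, width = width,
                             theta_folded = theta_folded,
                             theta_unfolded = theta_unfolded,
                             baseline_slopes = baseline_slopes,
                             noise_sd = noise_sd, pitch = pitch, seed = seed)
  cu
}

#' Generate uniform point-cloud frames (ideal gas)
#'
#' Uniform random points in a periodic cube at a stated number density, the
#' reference fixture for radial-distribution-function normalisation: the RDF
#' of an ideal gas is 1 at all r (use `box` in [rdf()] for minimum-image
#' distances).
#'
#' @param density number density in molecules/A^3 (default 0.03,
#'   approximately water).
#' @param box cubic box edge in A.
#' @param n_frames number of independent frames.
#' @param seed RNG seed.
#' @return An `md_trajectory` of `round(density * box^3)` single-atom
#'   "molecules" per frame, with attribute `box`.
#' @export
ideal_gas_trajectory <- function(density = 0.03, box = 20, n_frames = 10L,
                                 seed = NULL) {
  stopifnot(density > 0, box > 0, n_frames >= 1L)
  n <- round(density * box^3)
  if (n < 2L) {
    stop("density * box^3 must be at least 2 (got ", n, " points)")
  }
  atoms <- data.frame(
    name = "O", resno = seq_len(n), resname = "HOH",
    element = "O", mass = element_mass("O"),
    stringsAsFactors = FALSE
  )
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) matrix(runif(n * 3L, 0, box), n, 3L))
  })
  traj <- new_trajectory(atoms, frames, 0.5)
  attr(traj, "box") <- box
  traj
}

#' Generate a trajectory with one drifting C:C+ pair
#'
#' All atoms stay at their reference positions except the second partner of
#' one chosen pair, which is displaced along the pair axis to
#' `drift_distance` in exactly `round(drift_fraction * n_frames)` frames
#' (the trailing frames, deterministically). The fixture exercises the
#' disruption classifier: with the default rules the chosen pair is reported
#' disrupted precisely when `drift_fraction` exceeds the disruption
#' threshold, while all other pairs stay maintained.
#'
#' @param structure reference `md_structure` (e.g. from
#'   [toy_imotif_structure()]).
#' @param topology a `cc_pair_topology`.
#' @param pair pair label (e.g. `"C2c:C4a"`) or row index in `topology`.
#' @param drift_distance displaced N3-N3 distance in A (default 8).
#' @param drift_fraction fraction of frames displaced, in `[0, 1]`.
#' @param n_frames number of frames (default 100).
#' @return An `md_trajectory`.
#' @export
pair_drift_trajectory <- function(structure, topology, pair,
                                  drift_distance = 8, drift_fraction,
                                  n_frames = 100L) {
  stopifnot(inherits(structure, "md_structure"),
            inherits(topology, "cc_pair_topology"),
            drift_fraction >= 0, drift_fraction <= 1, n_frames >= 2L)
  row <- if (is.character(pair)) match(pair, topology$label) else as.integer(pair)
  if (is.na(row) || row < 1L || row > nrow(topology)) {
    stop("pair not found in topology: ", pair)
  }
  res_i <- topology$res_i[row]; res_j <- topology$res_j[row]
  idx_i <- which(structure$atoms$resno == res_i & structure$atoms$name == "N3")
  idx_j <- which(structure$atoms$resno == res_j & structure$atoms$name == "N3")
  stopifnot(length(idx_i) == 1L, length(idx_j) == 1L)
  axis <- structure$xyz[idx_j, ] - structure$xyz[idx_i, ]
  axis <- axis / sqrt(sum(axis^2))
  drifted <- structure$xyz
  drifted[idx_j, ] <- structure$xyz[idx_i, ] + drift_distance * axis
  k <- round(drift_fraction * n_frames)
  frames <- lapply(seq_len(n_frames), function(i) {
    if (i > n_frames - k) drifted else structure$xyz
  })
  new_trajectory(structure$atoms, frames, 0.5)
}
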