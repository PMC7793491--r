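#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the (optionally
#' weighted) sum of squared deviations between `mobile` and `reference`
#' coordinate sets, via singular value decomposition of the weighted
#' covariance matrix. Degenerate inputs (all points collinear or coincident,
#' where the rotation is under-determined) fall back to a translation-only
#' fit and are flagged.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @param weights optional non-negative per-atom weights.
#' @return A list of class `rigid_transform`: `rotation` (3x3 proper
#'   orthogonal, det = +1), `translation` (length 3), `degenerate` flag.
#'   Apply with [apply_transform()]: `x' = (x - mobile centroid) R + ref centroid`.
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' tr <- kabsch_superpose(ref, ref)
#' max(abs(tr$rotation - diag(3)))  # identity
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference), nrow(mobile) >= 3L)
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  degenerate <- sv$d[2] < max(sv$d[1], 1e-12) * 1e-8
  if (degenerate) {
    R <- diag(3)
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  structure(
    list(rotation = R, translation = cr, center = cm, degenerate = degenerate),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz `n x 3` coordinate matrix.
#' @param transform a `rigid_transform` from [kabsch_superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(sweep(as.matrix(xyz), 2L, transform$center) %*% transform$rotation,
        2L, transform$translation, `+`)
}

coord_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

new_traj_series <- function(times, values, metric, unit = "A") {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  structure(
    data.frame(time_ps = times, value = values),
    metric = metric, unit = unit,
    class = c("traj_series", "data.frame")
  )
}

#' @export
print.traj_series <- function(x, ...) {
  cat(attr(x, "metric"), "series: ", nrow(x), " frames, mean ",
      format(mean(x$value), digits = 4), " ", attr(x, "unit"), "\n", sep = "")
  invisible(x)
}

#' Best-fit RMSD time series
#'
#' Root-mean-square deviation of the selected atoms from a reference frame,
#' after optimal superposition of each frame onto the reference. By default
#' the fit uses the same atoms being measured (per-selection fitting, as in
#' CPPTRAJ's mask behaviour); pass a different `fit_selection` (e.g. the core)
#' to measure one region's motion in another region's frame. The reference
#' defaults to the first frame, so the series starts at 0.
#'
#' @param traj an `md_trajectory`.
#' @param selection integer atom indices to measure (see [select_atoms()]);
#'   defaults to all atoms.
#' @param fit_selection atom indices used for superposition; defaults to
#'   `selection`. `NULL` disables fitting.
#' @param reference frame index (default 1) or an `md_structure` with the
#'   same topology.
#' @param mass_weighted weight the fit by atomic mass (default `FALSE`).
#' @return A `traj_series` data frame with columns `time_ps`, `value` (A).
#' @export
rmsd_series <- function(traj, selection = NULL, fit_selection = selection,
                        reference = 1L, mass_weighted = FALSE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("atom selection is empty")
  ref_xyz <- reference_coords(traj, reference)
  fit_w <- if (mass_weighted) traj$atoms$mass[fit_selection] else NULL
  vals <- vapply(traj$frames, function(f) {
    if (!is.null(fit_selection)) {
      tr <- kabsch_superpose(f[fit_selection, , drop = FALSE],
                             ref_xyz[fit_selection, , drop = FALSE], fit_w)
      f <- apply_transform(f, tr)
    }
    coord_rmsd(f[selection, , drop = FALSE],
               ref_xyz[selection, , drop = FALSE])
  }, numeric(1))
  new_traj_series(frame_times(traj), vals, "RMSD")
}

reference_coords <- function(traj, reference) {
  if (inherits(reference, "md_structure")) {
    if (nrow(reference$xyz) != n_atoms(traj)) {
      stop("reference topology does not match trajectory (",
           nrow(reference$xyz), " vs ", n_atoms(traj), " atoms)")
    }
    reference$xyz
  } else {
    stopifnot(reference >= 1L, reference <= n_frames(traj))
    traj$frames[[reference]]
  }
}

#' Time-average of a trajectory statistic
#'
#' Arithmetic mean of a per-frame series after discarding an initial burn-in
#' window. The default burn-in of 0 ps averages the whole series.
#'
#' @param series a `traj_series` (or data frame with `time_ps`, `value`).
#' @param burn_in ps to discard from the start; frames at `time >= burn_in`
#'   are retained.
#' @return Mean value (full precision; report to 1 decimal for tables).
#' @export
time_average_rmsd <- function(series, burn_in = 0) {
  keep <- series$time_ps >= burn_in
  if (!any(keep)) {
    stop("burn-in of ", burn_in, " ps leaves no frames (series ends at ",
         max(series$time_ps), " ps)")
  }
  mean(series$value[keep])
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF measures each residue's fluctuation about its mean position over the
#' trajectory: frames are (optionally) superposed onto the first frame, the
#' time-mean position of every selected atom is computed, and the per-residue
#' RMSF is the square root of the mean squared displacement from that mean,
#' averaged over the residue's selected atoms. For isotropic Gaussian
#' displacements with per-coordinate standard deviation sigma and no fitting,
#' the expected RMSF is `sigma * sqrt(3)`.
#'
#' @param traj an `md_trajectory` with at least 2 frames.
#' @param selection atom indices to analyse; defaults to all atoms.
#' @param fit_selection atoms used to superpose each frame onto the first
#'   frame; `NULL` (default) analyses raw coordinates without fitting.
#' @return Data frame with columns `resno` and `rmsf` (A).
#' @export
rmsf_by_residue <- function(traj, selection = NULL, fit_selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), n_frames(traj) >= 2L)
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("atom selection is empty")
  frames <- traj$frames
  if (!is.null(fit_selection)) {
    ref <- frames[[1L]]
    frames <- lapply(frames, function(f) {
      apply_transform(f, kabsch_superpose(f[fit_selection, , drop = FALSE],
                                          ref[fit_selection, , drop = FALSE]))
    })
  }
  sel_xyz <- lapply(frames, function(f) f[selection, , drop = FALSE])
  mean_xyz <- Reduce(`+`, sel_xyz) / length(sel_xyz)
  msf <- Reduce(`+`, lapply(sel_xyz, function(f) {
    rowSums((f - mean_xyz)^2)
  })) / length(sel_xyz)
  resno <- traj$atoms$resno[selection]
  agg <- tapply(msf, resno, mean)
  data.frame(resno = as.integer(names(agg)), rmsf = sqrt(unname(agg)))
}

#' Radius of gyration time series
#'
#' Rg describes the overall compactness of the selected atoms:
#' `Rg = sqrt(sum(w_i * |r_i - rbar|^2) / sum(w_i))` with weights `w_i` equal
#' to atomic mass (default) or 1, and `rbar` the weighted centroid.
#'
#' @inheritParams rmsd_series
#' @param mass_weighted use atomic masses as weights (default `TRUE`).
#' @return A `traj_series` with per-frame Rg in A.
#' @export
rg_series <- function(traj, selection = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("atom selection is empty")
  w <- if (mass_weighted) traj$atoms$mass[selection] else rep(1, length(selection))
  w <- w / sum(w)
  vals <- vapply(traj$frames, function(f) {
    x <- f[selection, , drop = FALSE]
    ctr <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2L, ctr)^2)))
  }, numeric(1))
  new_traj_series(frame_times(traj), vals, "Rg")
}

#' Radial distribution function g(r)
#'
#' Histograms reference-to-target atom distances over all frames and
#' normalises each bin by the count expected for a uniform reference density,
#' so an ideal gas gives g(r) = 1. Two normalisations are available:
#' `"shell"` (default) uses the exact spherical-shell volume
#' `(4*pi/3) * ((R + dR)^3 - R^3)` with `R` the bin's lower edge, the
#' physically standard choice; `"literal"` uses
#' `(4*pi/3) * (R + dR)^3 - (4*pi/3) * dR^3`, the CPPTRAJ-style expression
#' sometimes quoted with the bin spacing in the second term, preserved here
#' for comparability.
#'
#' When both atom sets come from a periodic point-cloud fixture, pass the
#' cubic `box` edge to use minimum-image distances (required for the
#' ideal-gas limit; `max_r` should then be at most `box/2`).
#'
#' @param traj an `md_trajectory`.
#' @param reference_atoms,target_atoms integer atom index vectors.
#' @param dR bin width in A (default 0.1).
#' @param max_r histogram range in A (default 10).
#' @param density expected number density in molecules/A^3 (default 0.03,
#'   approximately water at 1.0 g/mL).
#' @param normalization `"shell"` or `"literal"` (see Details).
#' @param box optional cubic box edge (A) for minimum-image distances.
#' @return An `rdf_profile` data frame with columns `r` (bin centres) and
#'   `g`, and attributes `dR`, `density`, `normalization`, `n_distances`.
#' @export
rdf <- function(traj, reference_atoms, target_atoms, dR = 0.1, max_r = 10,
                density = 0.03, normalization = c("shell", "literal"),
                box = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), dR > 0, max_r > dR, density > 0)
  normalization <- match.arg(normalization)
  if (length(reference_atoms) == 0L || length(target_atoms) == 0L) {
    stop("reference and target atom sets must be non-empty")
  }
  breaks <- seq(0, max_r, by = dR)
  if (max(breaks) < max_r) breaks <- c(breaks, max(breaks) + dR)
  nbin <- length(breaks) - 1L
  counts <- numeric(nbin)
  total <- 0L
  for (f in traj$frames) {
    d <- cross_distances(f[reference_atoms, , drop = FALSE],
                         f[target_atoms, , drop = FALSE], box)
    # exclude self-distances where the two sets share atoms
    shared <- intersect(reference_atoms, target_atoms)
    if (length(shared) > 0L) {
      ri <- match(shared, reference_atoms)
      ti <- match(shared, target_atoms)
      d[cbind(ri, ti)] <- NA_real_
    }
    d <- d[!is.na(d)]
    total <- total + length(d)
    d <- d[d < max(breaks)]
    if (length(d) > 0L) {
      h <- tabulate(findInterval(d, breaks, rightmost.closed = FALSE) , nbins = nbin)
      counts <- counts + h
    }
  }
  if (sum(counts) == 0) {
    warning("no distances within [0, max_r]; returning an all-zero profile")
  }
  lower <- breaks[-length(breaks)]
  expected <- switch(normalization,
    shell = density * (4 * pi / 3) * ((lower + dR)^3 - lower^3),
    literal = density * ((4 * pi / 3) * (lower + dR)^3 - (4 * pi / 3) * dR^3)
  )
  g <- counts / (length(traj$frames) * length(reference_atoms) * expected)
  # the literal formula gives the first bin zero expected volume; an empty
  # bin there is reported as 0 rather than 0/0
  g[counts == 0 & expected == 0] <- 0
  structure(
    data.frame(r = lower + dR / 2, g = g),
    dR = dR, density = density, normalization = normalization,
    n_distances = total,
    class = c("rdf_profile", "data.frame")
  )
}

cross_distances <- function(a, b, box = NULL) {
  if (is.null(box)) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    sqrt(pmax(d2, 0))
  } else {
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(a[, k], b[, k], `-`)
      dk <- dk - box * round(dk / box)
      d2 <- d2 + dk^2
    }
    sqrt(d2)
  }
}

#' @export
plot.rdf_profile <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (Å)", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Monitor C:C+ hydrogen-bond distances along a trajectory
#'
#' For every pair in a [cc_pair_topology()], tracks the N3-N3 distance (the
#' hemi-protonated C:C+ hydrogen-bond marker, ~2.8 A in the folded i-motif)
#' over all frames and classifies the pair as `"maintained"` or
#' `"disrupted"`. A pair is disrupted when its distance exceeds `cutoff` in
#' more than `disruption_fraction` of the frames; 3.5 A is the conventional
#' heavy-atom hydrogen-bond limit.
#'
#' @param traj an `md_trajectory` whose paired cytosine residues each contain
#'   an atom named `N3` (in pseudo-atom models the single bead is named N3).
#' @param topology a `cc_pair_topology`.
#' @param cutoff hydrogen-bond distance limit in A (default 3.5).
#' @param disruption_fraction fraction of frames beyond `cutoff` above which
#'   a pair counts as disrupted (default 0.5).
#' @return An object of class `cc_pair_report`: list with `distances`
#'   (frames x pairs matrix, columns named by pair label), `status` data
#'   frame (`label`, `fraction_beyond`, `status`), `cutoff`,
#'   `disruption_fraction`, `times`.
#' @export
cc_pair_distances <- function(traj, topology, cutoff = 3.5,
                              disruption_fraction = 0.5) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(topology, "cc_pair_topology"))
  n3_index <- function(res) {
    idx <- which(traj$atoms$resno == res & traj$atoms$name == "N3")
    if (length(idx) != 1L) {
      stop("residue ", res, " has no unique N3 atom (found ", length(idx), ")")
    }
    idx
  }
  ai <- vapply(topology$res_i, n3_index, integer(1))
  aj <- vapply(topology$res_j, n3_index, integer(1))
  distances <- t(vapply(traj$frames, function(f) {
    sqrt(rowSums((f[ai, , drop = FALSE] - f[aj, , drop = FALSE])^2))
  }, numeric(nrow(topology))))
  if (nrow(topology) == 1L) distances <- matrix(distances, ncol = 1L)
  colnames(distances) <- topology$label
  frac <- colMeans(distances > cutoff)
  status <- data.frame(
    label = topology$label,
    fraction_beyond = unname(frac),
    status = ifelse(frac > disruption_fraction, "disrupted", "maintained"),
    stringsAsFactors = FALSE
  )
  structure(
    list(distances = distances, status = status, cutoff = cutoff,
         disruption_fraction = disruption_fraction, times = frame_times(traj)),
    class = "cc_pair_report"
  )
}

#' @export
print.cc_pair_report <- function(x, ...) {
  cat("C:C+ N3-N3 distance report (cutoff ", x$cutoff, " A, disrupted if > ",
      100 * x$disruption_fraction, "% of frames beyond)\n", sep = "")
  print(x$status, row.names = FALSE)
  invisible(x)
}

#' Fraction of frames with inter-loop contact
#'
#' A frame counts as a contact frame when any heavy-atom distance between the
#' two loops is below `cutoff`. Persistent loop1-loop3 contact is a hallmark
#' of compact, stable short-loop i-motifs.
#'
#' @param traj an `md_trajectory`.
#' @param regions per-residue labels from [assign_regions()].
#' @param loop_a,loop_b loop labels (default `"loop1"`, `"loop3"`).
#' @param cutoff contact distance in A (default 4.0).
#' @return Fraction of frames in contact, in `[0, 1]`.
#' @export
loop_contact_fraction <- function(traj, regions, loop_a = "loop1",
                                  loop_b = "loop3", cutoff = 4.0) {
  for (lab in c(loop_a, loop_b)) {
    if (!lab %in% regions) stop("region map has no residues labelled ", lab)
  }
  ia <- select_atoms(traj, regions, region = loop_a)
  ib <- select_atoms(traj, regions, region = loop_b)
  hits <- vapply(traj$frames, function(f) {
    min(cross_distances(f[ia, , drop = FALSE], f[ib, , drop = FALSE])) < cutoff
  }, logical(1))
  mean(hits)
}
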