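#' @importFrom utils read.csv write.csv
NULL

# Standard atomic masses (amu) for elements common in nucleic acids.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06
)

# Infer the element symbol from a PDB atom name: strip digits/primes and
# take the leading letter ("C5'" -> C, "OP1" -> O, "N3" -> N).
guess_element <- function(name) {
  stripped <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(stripped, 1L, 1L))
  el[el == ""] <- "X"
  el
}

element_mass <- function(element) {
  m <- .element_masses[element]
  m[is.na(m)] <- 1.0  # pseudo-atoms and unknown elements carry unit mass
  unname(m)
}

new_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  stopifnot(
    nrow(atoms) >= 1L,
    ncol(xyz) == 3L,
    nrow(xyz) == nrow(atoms),
    all(is.finite(xyz)),
    all(atoms$resno >= 1L),
    all(atoms$mass > 0)
  )
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

new_trajectory <- function(atoms, frames, frame_interval = 0.5) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(length(frames) >= 1L, frame_interval > 0)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    stopifnot(ncol(f) == 3L, nrow(f) == nrow(atoms), all(is.finite(f)))
    f
  })
  structure(
    list(atoms = atoms, frames = frames, frame_interval = frame_interval),
    class = "md_trajectory"
  )
}

#' Number of frames and atoms
#'
#' @param x an `md_trajectory` or `md_structure`.
#' @return Integer count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "md_trajectory")) length(x$frames) else 1L
}

#' @rdname n_frames
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Frame times in picoseconds
#'
#' Times start at 0 for the first frame and advance by the trajectory's
#' frame interval (ps per saved frame).
#'
#' @param traj an `md_trajectory`.
#' @return Numeric vector of times, length `n_frames(traj)`.
#' @export
frame_times <- function(traj) {
  (seq_len(n_frames(traj)) - 1L) * traj$frame_interval
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", n_atoms(x), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms,",
      x$frame_interval, "ps/frame\n")
  invisible(x)
}

bio3d_to_atoms <- function(pdb) {
  atoms <- data.frame(
    name = trimws(pdb$atom$elety),
    resno = as.integer(pdb$atom$resno),
    resname = trimws(pdb$atom$resid),
    stringsAsFactors = FALSE
  )
  el <- trimws(pdb$atom$elesy)
  missing_el <- is.na(el) | el == ""
  el[missing_el] <- guess_element(atoms$name[missing_el])
  atoms$element <- toupper(el)
  atoms$mass <- element_mass(atoms$element)
  atoms
}

#' Read a structure from a PDB or XYZ file
#'
#' PDB files are read with bio3d; XYZ files with a minimal reader. For a
#' multi-model file only the first model is returned (use [read_trajectory()]
#' for all frames). Coordinates are in Angstrom. Elements missing from PDB
#' columns are inferred from atom names.
#'
#' @param path file path; format detected from the `.pdb`/`.xyz` extension.
#' @return An `md_structure` (atom table plus an `n x 3` coordinate matrix).
#' @export
read_structure <- function(path) {
  traj <- read_trajectory(path)
  new_structure(traj$atoms, traj$frames[[1]])
}

#' Read a trajectory from a multi-model PDB or multi-frame XYZ file
#'
#' Frames are returned in file order; every frame must contain the same
#' number of atoms as the first (checked, error otherwise).
#'
#' @param path file path (`.pdb` with MODEL/ENDMDL records, or `.xyz` with
#'   repeated frame blocks).
#' @param frame_interval time between saved frames in ps (metadata only;
#'   defaults to 0.5 ps, a common trajectory save pitch).
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, frame_interval = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    parsed <- read_xyz_frames(path)
    atoms <- parsed$atoms
  } else {
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
      error = function(e) stop("cannot parse PDB file ", path, ": ",
                               conditionMessage(e))
    )
    if (nrow(pdb$atom) == 0L) stop("no atoms found in ", path)
    atoms <- bio3d_to_atoms(pdb)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    parsed <- list(frames = lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    }))
  }
  new_trajectory(atoms, parsed$frames, frame_interval)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop("no atoms found in ", path)
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + nat > length(lines)) stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    if (any(lengths(toks) < 4L)) stop("malformed XYZ atom record near line ", i)
    el <- toupper(vapply(toks, `[[`, "", 1L))
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(coords))) stop("non-numeric XYZ coordinates near line ", i)
    if (is.null(atoms)) {
      atoms <- data.frame(
        name = el, resno = seq_along(el), resname = el,
        element = el, mass = element_mass(el),
        stringsAsFactors = FALSE
      )
    } else if (nat != nrow(atoms)) {
      stop("inconsistent atom count across XYZ frames (", nat, " vs ",
           nrow(atoms), ")")
    }
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + nat
  }
  list(atoms = atoms, frames = frames)
}

atoms_to_bio3d <- function(atoms, xyz_frames) {
  n <- nrow(atoms)
  at <- data.frame(
    type = rep("ATOM", n),
    eleno = seq_len(n),
    elety = atoms$name,
    alt = "",
    resid = atoms$resname,
    chain = "A",
    resno = atoms$resno,
    insert = "",
    x = xyz_frames[[1]][, 1], y = xyz_frames[[1]][, 2], z = xyz_frames[[1]][, 3],
    o = 1, b = 0, segid = "",
    elesy = atoms$element, charge = "",
    stringsAsFactors = FALSE
  )
  xyz <- do.call(rbind, lapply(xyz_frames, function(f) as.numeric(t(f))))
  p <- list(atom = at, xyz = bio3d::as.xyz(xyz), calpha = rep(FALSE, n))
  class(p) <- "pdb"
  p
}

#' Write a structure or trajectory to PDB or XYZ
#'
#' Multi-frame objects are written as multi-model PDB (MODEL/ENDMDL records,
#' via bio3d) or concatenated XYZ frame blocks. PDB coordinates keep the
#' format's 3-decimal precision.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param path output path; format from the `.pdb`/`.xyz` extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  frames <- if (inherits(x, "md_trajectory")) x$frames else list(x$xyz)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in frames) {
      writeLines(as.character(nrow(f)), con)
      writeLines("generated by tspc4", con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                         x$atoms$element, f[, 1], f[, 2], f[, 3]), con)
    }
  } else {
    bio3d::write.pdb(atoms_to_bio3d(x$atoms, frames), file = path)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_structure <- write_trajectory

#' Select atoms by region, element and name
#'
#' Resolves a deterministic, ordered list of atom indices for a topology,
#' filtered by i-motif region, hydrogen exclusion and an optional atom-name
#' whitelist. Region labels come from [assign_regions()] and are matched via
#' each atom's residue number. The `"whole"` region is the union of core and
#' all loops; `"loop"` is the union of the three loops.
#'
#' @param x an `md_structure` or `md_trajectory` (or a bare atom data frame).
#' @param regions per-residue label vector from [assign_regions()]; may be
#'   `NULL` when `region = "whole"`.
#' @param region one of `"whole"`, `"core"`, `"loop"`, `"loop1"`, `"loop2"`,
#'   `"loop3"`.
#' @param heavy_only drop hydrogens (default `TRUE`).
#' @param names optional atom-name whitelist (e.g. `"N3"`).
#' @return Increasing integer vector of atom indices; error if empty.
#' @export
select_atoms <- function(x, regions = NULL,
                         region = c("whole", "core", "loop",
                                    "loop1", "loop2", "loop3"),
                         heavy_only = TRUE, names = NULL) {
  region <- match.arg(region)
  atoms <- if (is.data.frame(x)) x else x$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (region != "whole" || !is.null(regions)) {
    if (is.null(regions)) stop("a region map is required for region = '",
                               region, "'")
    if (max(atoms$resno) > length(regions)) {
      stop("region map covers ", length(regions),
           " residues but topology has residue ", max(atoms$resno))
    }
    lab <- regions[atoms$resno]
    keep <- switch(region,
      whole = !is.na(lab),
      core  = lab == "core",
      loop  = startsWith(lab, "loop"),
      lab == region
    )
  }
  if (heavy_only) keep <- keep & atoms$element != "H"
  if (!is.null(names)) keep <- keep & atoms$name %in% names
  idx <- which(keep)
  if (length(idx) == 0L) stop("atom selection is empty")
  idx
}
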