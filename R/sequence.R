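#' Parse an i-motif sequence
#'
#' Accepts either the compact repeat notation used for model i-motifs,
#' e.g. `"d[(CCCTTT)3CCC]"`, or a plain A/C/G/T string. The expanded sequence
#' is scanned for exactly four equal-length cytosine tracts (maximal runs of
#' two or more consecutive C) separated by three loops; tracts and loops must
#' tile the sequence, i.e. it starts with tract 1 and ends with tract 4.
#'
#' The leading `"d"` (deoxy) and the brackets of the repeat notation are
#' optional; subscript repeat counts are written as plain digits.
#'
#' @param text repeat notation or plain sequence string.
#' @param name optional label for the sequence (defaults to the input text).
#' @return An object of class `imotif_sequence`: a list with elements
#'   `name`, `notation`, `sequence`, `tracts` (list of four `c(start, end)`
#'   spans, 1-based inclusive), `loops` (list of three spans, 5'->3') and
#'   `tract_length`.
#' @examples
#' seq <- parse_imotif("d[(CCCTAA)3CCC]", name = "CCCTA2")
#' seq$sequence   # "CCCTAACCCTAACCCTAACCC"
#' @seealso [assign_regions()], [cc_pair_topology()]
#' @export
parse_imotif <- function(text, name = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- gsub("\\s", "", text)
  expanded <- expand_repeat_notation(raw)
  seq <- toupper(expanded)
  if (!grepl("^[ACGT]+$", seq)) {
    stop("sequence contains characters other than A/C/G/T: ", text)
  }
  spans <- locate_tracts(seq)
  structure(
    list(
      name = if (is.null(name)) raw else name,
      notation = raw,
      sequence = seq,
      tracts = spans$tracts,
      loops = spans$loops,
      tract_length = spans$tracts[[1]][2] - spans$tracts[[1]][1] + 1L
    ),
    class = "imotif_sequence"
  )
}

#' Read an i-motif sequence from a FASTA file
#'
#' Reads the first record of a FASTA file and parses it with
#' [parse_imotif()]; the record header becomes the sequence name.
#'
#' @param path path to a FASTA file.
#' @return An `imotif_sequence` object.
#' @export
read_imotif_fasta <- function(path) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("reading FASTA requires the 'seqinr' package")
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no sequences found in ", path)
  parse_imotif(as.character(recs[[1]]), name = names(recs)[1])
}

# Expand d[(<unit>)n<tail>] notation; plain sequences pass through.
expand_repeat_notation <- function(raw) {
  m <- regmatches(
    raw,
    regexec("^d?\\[?\\(([ACGTacgt]+)\\)([0-9]+)([ACGTacgt]*)\\]?$", raw)
  )[[1]]
  if (length(m) == 0L) {
    if (grepl("^d\\[", raw) || grepl("\\(", raw)) {
      stop("malformed repeat notation: ", raw)
    }
    return(raw)
  }
  n <- as.integer(m[3])
  if (n < 1L) stop("repeat count must be >= 1 in: ", raw)
  paste0(strrep(m[2], n), m[4])
}

# Tracts are maximal runs of >= 2 consecutive C; exactly four equal-length
# runs are required, beginning and ending the sequence.
locate_tracts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  r <- rle(chars == "C")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_tract <- r$values & r$lengths >= 2L
  idx <- which(is_tract)
  if (length(idx) != 4L) {
    stop(
      "expected exactly four C-tracts (runs of >= 2 C), found ",
      length(idx), " in: ", seq
    )
  }
  lens <- r$lengths[idx]
  if (length(unique(lens)) != 1L) {
    stop(
      "C-tracts have unequal lengths (",
      paste(lens, collapse = ", "), ") in: ", seq
    )
  }
  if (starts[idx[1]] != 1L || ends[idx[4]] != length(chars)) {
    stop("sequence must begin with tract 1 and end with tract 4: ", seq)
  }
  tracts <- lapply(idx, function(i) c(starts[i], ends[i]))
  loops <- lapply(1:3, function(k) {
    c(ends[idx[k]] + 1L, starts[idx[k + 1L]] - 1L)
  })
  bad <- vapply(loops, function(sp) sp[2] < sp[1], logical(1))
  if (any(bad)) stop("empty loop between tracts in: ", seq)
  list(tracts = tracts, loops = loops)
}

#' @export
print.imotif_sequence <- function(x, ...) {
  cat("i-motif sequence:", x$name, "\n")
  cat("  ", x$sequence, " (", nchar(x$sequence), " nt)\n", sep = "")
  cat("  tracts: ",
      paste(vapply(x$tracts, function(s) paste0(s[1], "-", s[2]), ""),
            collapse = ", "),
      "  (length ", x$tract_length, ")\n", sep = "")
  loopseq <- vapply(x$loops, function(s) substr(x$sequence, s[1], s[2]), "")
  cat("  loops:  ", paste(sprintf("loop%d=%s", 1:3, loopseq), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assign core/loop region labels to each residue
#'
#' Labels every residue of an i-motif sequence as `"core"` (member of one of
#' the four cytosine tracts) or `"loop1"`, `"loop2"`, `"loop3"` (the three
#' connecting segments, numbered 5'->3').
#'
#' @param seq an `imotif_sequence` from [parse_imotif()].
#' @return Character vector of per-residue labels, length `nchar(seq$sequence)`.
#' @export
assign_regions <- function(seq) {
  stopifnot(inherits(seq, "imotif_sequence"))
  n <- nchar(seq$sequence)
  labels <- rep(NA_character_, n)
  for (sp in seq$tracts) labels[sp[1]:sp[2]] <- "core"
  for (k in 1:3) {
    sp <- seq$loops[[k]]
    labels[sp[1]:sp[2]] <- paste0("loop", k)
  }
  stopifnot(!anyNA(labels))
  labels
}

#' Build the C:C+ base-pair topology of an i-motif
#'
#' The i-motif core is two parallel-stranded duplexes (tracts 1+3 and
#' tracts 2+4) intercalated in an antiparallel fashion and held together by
#' hemi-protonated C:C+ pairs. Cytosines are addressed by tract number (1-4)
#' and a within-tract position letter (a, b, c, ... 5'->3'), so `"C2c:C4a"`
#' pairs the third cytosine of tract 2 with the first of tract 4.
#'
#' Two pairing registers are provided. In the `"aligned"` register the i-th
#' cytosine of tract 1 pairs the i-th of tract 3 (and likewise 2/4). The
#' `"shifted"` register offsets each duplex by one position cyclically, which
#' produces cross-register names such as `"C2c:C4a"`. The experimentally
#' realised register depends on the intercalation topology of the particular
#' i-motif; both conventions are exposed and neither is asserted as canonical.
#'
#' @param seq an `imotif_sequence`.
#' @param register pairing convention, `"aligned"` (default) or `"shifted"`.
#' @return An object of class `cc_pair_topology`: a data frame with one row
#'   per pair (columns `tract_i`, `pos_i`, `res_i`, `tract_j`, `pos_j`,
#'   `res_j`, `label`) and attribute `register`. There are always
#'   `2 * tract_length` pairs.
#' @examples
#' top <- cc_pair_topology(parse_imotif("d[(CCCTTT)3CCC]"))
#' top$label
#' @export
cc_pair_topology <- function(seq, register = c("aligned", "shifted")) {
  stopifnot(inherits(seq, "imotif_sequence"))
  register <- match.arg(register)
  L <- seq$tract_length
  pos_j <- switch(register,
    aligned = seq_len(L),
    shifted = (seq_len(L) %% L) + 1L
  )
  rows <- list()
  for (duplex in list(c(1L, 3L), c(2L, 4L))) {
    ti <- duplex[1]; tj <- duplex[2]
    for (i in seq_len(L)) {
      j <- pos_j[i]
      rows[[length(rows) + 1L]] <- data.frame(
        tract_i = ti, pos_i = i,
        res_i = seq$tracts[[ti]][1] + i - 1L,
        tract_j = tj, pos_j = j,
        res_j = seq$tracts[[tj]][1] + j - 1L,
        label = paste0("C", ti, letters[i], ":C", tj, letters[j]),
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, rows)
  stopifnot(
    nrow(pairs) == 2L * L,
    !anyDuplicated(pairs$res_i),
    !anyDuplicated(pairs$res_j)
  )
  structure(pairs, register = register,
            class = c("cc_pair_topology", "data.frame"))
}

#' @export
print.cc_pair_topology <- function(x, ...) {
  cat("C:C+ pair topology (", attr(x, "register"), " register, ",
      nrow(x), " pairs)\n", sep = "")
  cat(" ", paste(x$label, collapse = "  "), "\n")
  invisible(x)
}
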