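# Shared fixtures, built in code at test time.

ccct3_seq <- function() parse_imotif("d[(CCCTTT)3CCC]", name = "CCCT3")
cccta2_seq <- function() parse_imotif("d[(CCCTAA)3CCC]", name = "CCCTA2")

ccct3_structure <- function(...) toy_imotif_structure(ccct3_seq(), ...)

# bare trajectory from a list of coordinate matrices and an atom table
raw_trajectory <- function(atoms, frames, frame_interval = 0.5) {
  tspc4:::new_trajectory(atoms, frames, frame_interval)
}

# n pseudo-atoms, one residue each, unit mass
bare_atoms <- function(n, name = "X", element = "C", mass = 1) {
  data.frame(name = name, resno = seq_len(n), resname = "UNK",
             element = element, mass = mass, stringsAsFactors = FALSE)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
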