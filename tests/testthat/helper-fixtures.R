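# Shared fixtures, built in code at test time.

# a minimal hand-written three-atom PDB text
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "HETATM    3  F   F   A   2       8.000   6.000  -6.000  1.00  0.00           F",
    "END"
  ), path)
  path
}

# proper rotation matrix (det = +1) from a seeded random QR factorization
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# two-frame toy trajectory with planted P-F separations
toy_two_frame_traj <- function(sep = c(2, 6)) {
  atoms <- tibble::tibble(
    serial = 1:2, name = c("P", "F"), element = c("P", "F"),
    resname = c("OPS", "F"), resseq = c(198L, 900L), chain = "A",
    x = 0, y = 0, z = 0, charge = NA_real_
  )
  coords <- array(0, c(length(sep), 2, 3))
  for (i in seq_along(sep)) coords[i, 2, 3] <- sep[i]
  new_trajectory(atoms, coords, seq_along(sep) * 100 - 100)
}

table5 <- function() read_adduct_table(fluorelease_example("bche_am1_charges"))
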