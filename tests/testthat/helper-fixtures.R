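# Shared fixtures, all generated in code.

helix10 <- function(include_hydrogens = TRUE) {
  build_peptide(strrep("A", 10), c(-57, -47),
                include_hydrogens = include_hydrogens)
}

# Apply a random rigid-body motion (rotation + translation) to a structure.
rigid_motion <- function(structure, seed = 1) {
  set.seed(seed)
  # random rotation from QR of a Gaussian matrix, det forced to +1
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- rnorm(3, 0, 20)
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t_vec[1]
  a$y <- xyz[, 2] + t_vec[2]
  a$z <- xyz[, 3] + t_vec[3]
  pepshift:::new_protein_structure(a)
}

# Minimal hand-written PDB text: one glycine, three atoms.
gly_pdb_text <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
}

default_params_cached <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- default_params()
    p
  }
})
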