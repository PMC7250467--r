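# Synthetic structure builders: ideal peptides with exactly specified
# backbone dihedrals, helical assemblies replicated from a unit, and
# minimal probe scenes with analytically known descriptor values.  These
# are first-class generators (not test stubs): every geometric descriptor
# can be validated against exact ground truth without external data.

# Ideal covalent geometry (Angstroms / degrees), Engh-Huber-style values.
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180)

# Place atom d bonded to c with the given bond length, angle at c (between
# b and d) and dihedral a-b-c-d (NeRF construction).
place_atom <- function(a, b, c3, bond, angle, dihedral) {
  bc <- vec_unit(c3 - b)
  n <- vec_unit(vec_cross(b - a, bc))
  m <- vec_cross(n, bc)
  ang <- angle / DEG; dih <- dihedral / DEG
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Side-chain templates.  Each entry places one atom from three reference
# atoms already present in the residue; dihedrals are either numeric or
# "chiK"/"chiK+180" resolved from the residue's chi angles.  Rings are
# closed by exact polygon angles (hexagon 120, pentagon 108), so they come
# out planar by construction.  Non-aromatic, non-anisotropy side chains are
# reduced to their heavy-atom skeleton; fixtures need exactness, not
# rotamer realism.
SIDE_TEMPLATES <- list(
  ALA = list(),
  SER = list(list("OG", "O", c("N", "CA", "CB"), 1.42, 110.5, "chi1")),
  CYS = list(list("SG", "S", c("N", "CA", "CB"), 1.81, 113.8, "chi1")),
  THR = list(list("OG1", "O", c("N", "CA", "CB"), 1.43, 109.6, "chi1"),
             list("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, "chi1+120")),
  VAL = list(list("CG1", "C", c("N", "CA", "CB"), 1.52, 110.5, "chi1"),
             list("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, "chi1+120")),
  ILE = list(list("CG1", "C", c("N", "CA", "CB"), 1.53, 110.4, "chi1"),
             list("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, "chi1+120"),
             list("CD1", "C", c("CA", "CB", "CG1"), 1.52, 113.8, "chi2")),
  LEU = list(list("CG", "C", c("N", "CA", "CB"), 1.53, 116.3, "chi1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.52, 110.7, "chi2"),
             list("CD2", "C", c("CA", "CB", "CG"), 1.52, 110.7, "chi2+120")),
  MET = list(list("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
             list("SD", "S", c("CA", "CB", "CG"), 1.80, 112.7, "chi2"),
             list("CE", "C", c("CB", "CG", "SD"), 1.79, 100.9, "chi3")),
  LYS = list(list("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
             list("CE", "C", c("CB", "CG", "CD"), 1.52, 111.3, "chi3"),
             list("NZ", "N", c("CG", "CD", "CE"), 1.49, 111.9, "chi4")),
  PRO = list(list("CG", "C", c("N", "CA", "CB"), 1.50, 104.5, 30),
             list("CD", "C", c("CA", "CB", "CG"), 1.51, 106.1, -35)),
  ASN = list(list("CG", "C", c("N", "CA", "CB"), 1.52, 112.6, "chi1"),
             list("OD1", "O", c("CA", "CB", "CG"), 1.23, 120.8, "chi2"),
             list("ND2", "N", c("CA", "CB", "CG"), 1.33, 116.4, "chi2+180")),
  ASP = list(list("CG", "C", c("N", "CA", "CB"), 1.52, 112.6, "chi1"),
             list("OD1", "O", c("CA", "CB", "CG"), 1.25, 118.5, "chi2"),
             list("OD2", "O", c("CA", "CB", "CG"), 1.25, 118.5, "chi2+180")),
  GLN = list(list("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.52, 112.6, "chi2"),
             list("OE1", "O", c("CB", "CG", "CD"), 1.23, 120.8, "chi3"),
             list("NE2", "N", c("CB", "CG", "CD"), 1.33, 116.4, "chi3+180")),
  GLU = list(list("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.52, 112.6, "chi2"),
             list("OE1", "O", c("CB", "CG", "CD"), 1.25, 118.5, "chi3"),
             list("OE2", "O", c("CB", "CG", "CD"), 1.25, 118.5, "chi3+180")),
  ARG = list(list("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
             list("NE", "N", c("CB", "CG", "CD"), 1.46, 112.0, "chi3"),
             list("CZ", "C", c("CG", "CD", "NE"), 1.33, 124.2, "chi4"),
             list("NH1", "N", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
             list("NH2", "N", c("CD", "NE", "CZ"), 1.33, 120.0, 180)),
  HIS = list(list("CG", "C", c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
             list("ND1", "N", c("CA", "CB", "CG"), 1.37, 126.0, "chi2"),
             list("CE1", "C", c("CB", "CG", "ND1"), 1.37, 108.0, 180),
             list("NE2", "N", c("CG", "ND1", "CE1"), 1.37, 108.0, 0),
             list("CD2", "C", c("ND1", "CE1", "NE2"), 1.37, 108.0, 0)),
  PHE = list(list("CG", "C", c("N", "CA", "CB"), 1.51, 114.0, "chi1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.39, 120.0, "chi2"),
             list("CE1", "C", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
             list("CZ", "C", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             list("CE2", "C", c("CD1", "CE1", "CZ"), 1.39, 120.0, 0),
             list("CD2", "C", c("CE1", "CZ", "CE2"), 1.39, 120.0, 0)),
  TYR = list(list("CG", "C", c("N", "CA", "CB"), 1.51, 114.0, "chi1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.39, 120.0, "chi2"),
             list("CE1", "C", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
             list("CZ", "C", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             list("CE2", "C", c("CD1", "CE1", "CZ"), 1.39, 120.0, 0),
             list("CD2", "C", c("CE1", "CZ", "CE2"), 1.39, 120.0, 0),
             list("OH", "O", c("CD1", "CE1", "CZ"), 1.36, 120.0, 180)),
  TRP = list(list("CG", "C", c("N", "CA", "CB"), 1.50, 113.6, "chi1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.37, 126.9, "chi2"),
             list("NE1", "N", c("CB", "CG", "CD1"), 1.37, 108.0, 180),
             list("CE2", "C", c("CG", "CD1", "NE1"), 1.37, 108.0, 0),
             list("CD2", "C", c("CD1", "NE1", "CE2"), 1.37, 108.0, 0),
             list("CZ2", "C", c("CG", "CD2", "CE2"), 1.40, 120.0, 180),
             list("CH2", "C", c("CD2", "CE2", "CZ2"), 1.40, 120.0, 0),
             list("CZ3", "C", c("CE2", "CZ2", "CH2"), 1.40, 120.0, 0),
             list("CE3", "C", c("CZ2", "CH2", "CZ3"), 1.40, 120.0, 0)))

default_chis <- function(res_name) {
  chi2 <- if (res_name %in% c("PHE", "TYR", "HIS", "TRP")) 90 else 180
  c(chi1 = 180, chi2 = chi2, chi3 = 180, chi4 = 180)
}

resolve_dihedral <- function(spec, chis) {
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^(chi[1-4])([+-][0-9.]+)?$", spec))[[1]]
  val <- chis[[m[2]]]
  if (m[3] != "") val <- val + as.numeric(m[3])
  val
}

#' Build an ideal peptide with prescribed backbone dihedrals
#'
#' Constructs a single-chain peptide with ideal covalent geometry; phi and
#' psi are set exactly to the requested values (omega fixed at 180), so the
#' geometry module recovers them to numerical precision.  Aromatic side
#' chains are built as exact planar polygons.  Backbone amide (HN, absent
#' at the N-terminus and on proline) and alpha protons are added when
#' `include_hydrogens` is `TRUE`; side-chain protons are not modelled.
#'
#' @param sequence One-letter amino-acid string (e.g. `"AAFAY"`).
#' @param phi_psi Numeric matrix (n x 2) of per-residue (phi, psi) degrees,
#'   or a length-2 vector recycled to all residues.
#' @param include_hydrogens Add HN and HA protons.
#' @param chain_id Chain label.
#' @param jitter Standard deviation (Angstroms) of optional Gaussian
#'   coordinate noise, applied after construction; default off.
#' @param seed RNG seed used when `jitter > 0`.
#' @return A `protein_structure` with attribute `ground_truth`
#'   (`list(sequence, phi_psi, n_atoms)`).
#' @export
build_peptide <- function(sequence, phi_psi = c(-57, -47),
                          include_hydrogens = TRUE, chain_id = "A",
                          jitter = 0, seed = NULL) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) == 0L) stop("sequence must be non-empty", call. = FALSE)
  bad <- setdiff(letters1, names(AA3))
  if (length(bad) > 0)
    stop(sprintf("unknown residue letter(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  n <- length(letters1)
  if (is.null(dim(phi_psi))) phi_psi <- matrix(phi_psi, n, 2, byrow = TRUE)
  if (nrow(phi_psi) != n || ncol(phi_psi) != 2)
    stop("phi_psi must be an n x 2 matrix", call. = FALSE)

  g <- BB_GEOM
  rows <- list()
  emit <- function(res_i, res_name, name, element, pos) {
    rows[[length(rows) + 1L]] <<- list(res_i = res_i, res_name = res_name,
                                       name = name, element = element,
                                       pos = pos)
  }
  prev <- NULL  # list(N, CA, C) of previous residue
  for (i in seq_len(n)) {
    rname <- AA3[[letters1[i]]]
    phi <- phi_psi[i, 1]; psi <- phi_psi[i, 2]
    if (is.null(prev)) {
      N <- c(0, 0, 0)
      CA <- c(g$n_ca, 0, 0)
      th <- g$ang_n_ca_c / DEG
      C <- CA + g$ca_c * c(-cos(th), sin(th), 0)
    } else {
      N <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n,
                      phi_psi[i - 1, 2])
      CA <- place_atom(prev$CA, prev$C, N, g$n_ca, g$ang_c_n_ca, g$omega)
      C <- place_atom(prev$C, N, CA, g$ca_c, g$ang_n_ca_c, phi)
    }
    O <- place_atom(N, CA, C, g$c_o, g$ang_ca_c_o, psi + 180)
    emit(i, rname, "N", "N", N)
    emit(i, rname, "CA", "C", CA)
    emit(i, rname, "C", "C", C)
    emit(i, rname, "O", "O", O)

    local_pos <- list(N = N, CA = CA, C = C, O = O)
    if (rname != "GLY") {
      # CB at tetrahedral geometry; chirality branch picked so the residue
      # is the L-enantiomer (positive triple product of N, C, CB about CA)
      CB <- place_atom(C, N, CA, 1.521, 110.4, 122.55)
      s <- sum(vec_cross(N - CA, C - CA) * (CB - CA))
      if (s < 0) CB <- place_atom(C, N, CA, 1.521, 110.4, -122.55)
      emit(i, rname, "CB", "C", CB)
      local_pos$CB <- CB
      chis <- default_chis(rname)
      for (tpl in SIDE_TEMPLATES[[rname]]) {
        refs <- lapply(tpl[[3]], function(nm) local_pos[[nm]])
        pos <- place_atom(refs[[1]], refs[[2]], refs[[3]], tpl[[4]], tpl[[5]],
                          resolve_dihedral(tpl[[6]], chis))
        emit(i, rname, tpl[[1]], tpl[[2]], pos)
        local_pos[[tpl[[1]]]] <- pos
      }
    }
    if (include_hydrogens) {
      if (i > 1L && rname != "PRO") {
        HN <- N - 1.01 * vec_unit(vec_unit(CA - N) + vec_unit(prev$C - N))
        emit(i, rname, "H", "H", HN)
      }
      if (rname == "GLY") {
        u1 <- vec_unit(N - CA); u2 <- vec_unit(C - CA)
        b <- -vec_unit(u1 + u2); pz <- vec_unit(vec_cross(u1, u2))
        w <- 54.75 / DEG
        emit(i, rname, "HA2", "H",
             CA + 1.09 * vec_unit(b * cos(w) + pz * sin(w)))
        emit(i, rname, "HA3", "H",
             CA + 1.09 * vec_unit(b * cos(w) - pz * sin(w)))
      } else {
        dir <- -(vec_unit(N - CA) + vec_unit(C - CA) +
                   vec_unit(local_pos$CB - CA))
        emit(i, rname, "HA", "H", CA + 1.09 * vec_unit(dir))
      }
    }
    prev <- list(N = N, CA = CA, C = C)
  }

  atoms <- data.frame(
    serial = seq_along(rows),
    name = vapply(rows, `[[`, "", "name"),
    element = vapply(rows, `[[`, "", "element"),
    res_name = vapply(rows, `[[`, "", "res_name"),
    res_seq = vapply(rows, `[[`, 0L, "res_i"),
    chain_id = chain_id, insert = " ",
    x = vapply(rows, function(r) r$pos[1], 0),
    y = vapply(rows, function(r) r$pos[2], 0),
    z = vapply(rows, function(r) r$pos[3], 0),
    occupancy = 1, alt_loc = " ", het = FALSE,
    stringsAsFactors = FALSE)
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
  }
  st <- new_protein_structure(atoms)
  attr(st, "ground_truth") <- list(sequence = sequence, phi_psi = phi_psi,
                                   n_atoms = nrow(atoms))
  st
}

CHAIN_LABELS <- c(LETTERS, letters, 0:9)

#' Replicate a unit structure into a helical assembly
#'
#' Copy k (k = 0..n-1) is rotated by `k * twist` degrees about the z axis
#' and translated by `k * rise` Angstroms along it; chains are re-labelled
#' uniquely per copy.
#'
#' @param unit A `protein_structure`.
#' @param n_copies Number of copies (>= 1).
#' @param rise Axial rise per copy, Angstroms.
#' @param twist Rotation per copy, degrees.
#' @return A `protein_structure` with `n_copies * unit$n_atoms` atoms.
#' @export
build_assembly <- function(unit, n_copies, rise = 10, twist = 30) {
  if (n_copies < 1L) stop("n_copies must be >= 1", call. = FALSE)
  u_chains <- unique(unit$atoms$chain_id)
  need <- n_copies * length(u_chains)
  if (need > length(CHAIN_LABELS)) {
    warning("more than 62 chain labels needed; switching to two-character labels",
            call. = FALSE)
    labels <- as.vector(outer(CHAIN_LABELS, CHAIN_LABELS, paste0))[seq_len(need)]
  } else labels <- CHAIN_LABELS[seq_len(need)]

  xyz <- as.matrix(unit$atoms[, c("x", "y", "z")])
  pieces <- vector("list", n_copies)
  for (k in seq_len(n_copies) - 1L) {
    th <- k * twist / DEG
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    p <- unit$atoms
    new_xyz <- xyz %*% t(R)
    p$x <- new_xyz[, 1]; p$y <- new_xyz[, 2]; p$z <- new_xyz[, 3] + k * rise
    p$chain_id <- labels[k * length(u_chains) + match(p$chain_id, u_chains)]
    pieces[[k + 1L]] <- p
  }
  atoms <- do.call(rbind, pieces)
  atoms$serial <- seq_len(nrow(atoms))
  new_protein_structure(atoms)
}

#' Minimal probe scenes with analytic ground truth
#'
#' Builds one of three minimal geometries at exactly the requested
#' parameters, together with the analytically expected descriptor value:
#' \describe{
#'   \item{`ring_axial`}{A regular hexagonal ring (radius `radius`) in the
#'     z = 0 plane plus a probe atom at `height` on the ring axis; ground
#'     truth is the closed-form axial Haigh-Mallion value for I = B = 1.}
#'   \item{`hbond_collinear`}{A collinear N-H...O=C' arrangement with
#'     N...O distance `r`; ground truth `1/r`.}
#'   \item{`ani_axial`}{A planar three-atom group with centroid at the
#'     origin plus a probe at distance `r` and angle `theta` degrees from
#'     the plane normal; ground truth `delta_chi (1 - 3 cos^2 theta)/(3 r^3)`.}
#' }
#'
#' @param kind `"ring_axial"`, `"hbond_collinear"` or `"ani_axial"`.
#' @param height,radius Ring-scene geometry (Angstroms).
#' @param r Donor-acceptor distance / probe distance (Angstroms).
#' @param theta Probe angle from the group normal (degrees).
#' @param delta_chi Anisotropy constant used for the ground truth.
#' @return List with `structure`, `ground_truth`, `probe_index`, and the
#'   scene-specific index sets (`ring`, `donor`/`acceptor`, `group`).
#' @export
build_probe_scene <- function(kind = c("ring_axial", "hbond_collinear",
                                       "ani_axial"),
                              height = 3, radius = 1.39, r = 2.9,
                              theta = 0, delta_chi = 1) {
  kind <- match.arg(kind)
  mk <- function(names, elements, res_names, res_seqs, coords) {
    data.frame(serial = seq_along(names), name = names, element = elements,
               res_name = res_names, res_seq = res_seqs, chain_id = "A",
               insert = " ", x = coords[, 1], y = coords[, 2],
               z = coords[, 3], occupancy = 1, alt_loc = " ", het = FALSE,
               stringsAsFactors = FALSE)
  }
  if (kind == "ring_axial") {
    ang <- (0:5) * 60 / DEG
    ring_xyz <- cbind(radius * cos(ang), radius * sin(ang), 0)
    coords <- rbind(ring_xyz, c(0, 0, height))
    atoms <- mk(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "HA"),
                c(rep("C", 6), "H"),
                c(rep("PHE", 6), "ALA"), c(rep(1L, 6), 2L), coords)
    s_tri <- sqrt(3) / 4 * radius^2
    rv <- sqrt(radius^2 + height^2)
    gt <- 6 * s_tri * 2 / rv^3
    list(structure = new_protein_structure(atoms), ground_truth = gt,
         probe_index = 7L,
         ring = list(kind = "PHE", idx = 1:6, res_index = 1L))
  } else if (kind == "hbond_collinear") {
    coords <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(r, 0, 0), c(r + 1.23, 0, 0))
    atoms <- mk(c("N", "H", "O", "C"), c("N", "H", "O", "C"),
                c("ALA", "ALA", "GLY", "GLY"), c(1L, 1L, 2L, 2L), coords)
    list(structure = new_protein_structure(atoms), ground_truth = 1 / r,
         probe_index = 2L, donor = c(1L, 2L), acceptor = c(3L, 4L))
  } else {
    grp <- rbind(c(1.2, 0, 0), c(-0.6, 0.9, 0), c(-0.6, -0.9, 0))
    probe <- r * c(sin(theta / DEG), 0, cos(theta / DEG))
    atoms <- mk(c("O", "C", "N", "H"), c("O", "C", "N", "H"),
                c("ALA", "ALA", "ALA", "GLY"), c(1L, 1L, 1L, 2L),
                rbind(grp, probe))
    gt <- delta_chi * (1 - 3 * cos(theta / DEG)^2) / (3 * r^3)
    list(structure = new_protein_structure(atoms), ground_truth = gt,
         probe_index = 4L, group = c(1L, 2L, 3L))
  }
}

#' Seeded synthetic validation set
#'
#' Generates peptides emulating the study conditions of the dual-path
#' validation harness: mixed helix/sheet secondary structure (alternating
#' blocks with mild angular jitter), at least 10 percent aromatic residues,
#' hydrogens included.
#'
#' @param n_structures Number of structures.
#' @param n_residues Residues per structure (>= 50 for the validation
#'   conditions).
#' @param seed RNG seed.
#' @param aromatic_frac Fraction of aromatic residues (drawn from F/Y/H/W).
#' @return List of `protein_structure` objects.
#' @export
build_validation_set <- function(n_structures = 20, n_residues = 56,
                                 seed = 1, aromatic_frac = 0.14) {
  set.seed(seed)
  out <- vector("list", n_structures)
  non_arom <- c("A", "L", "S", "T", "V", "I", "K", "E", "D", "N", "Q", "R",
                "G", "M")
  arom <- c("F", "Y", "H", "W")
  for (s in seq_len(n_structures)) {
    seq_l <- sample(non_arom, n_residues, replace = TRUE)
    n_arom <- ceiling(aromatic_frac * n_residues)
    pos <- sample(n_residues, n_arom)
    seq_l[pos] <- sample(arom, n_arom, replace = TRUE)
    # alternating helix / sheet blocks
    phi_psi <- matrix(NA_real_, n_residues, 2)
    i <- 1L; helix <- TRUE
    while (i <= n_residues) {
      len <- min(sample(6:12, 1), n_residues - i + 1L)
      base <- if (helix) c(-57, -47) else c(-139, 135)
      idx <- i:(i + len - 1L)
      phi_psi[idx, 1] <- base[1] + stats::rnorm(len, 0, 6)
      phi_psi[idx, 2] <- base[2] + stats::rnorm(len, 0, 6)
      i <- i + len; helix <- !helix
    }
    out[[s]] <- build_peptide(paste(seq_l, collapse = ""), phi_psi,
                              include_hydrogens = TRUE)
  }
  out
}
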