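# The five descriptor families, each computed by two execution paths:
#   * a per-call reference path (one query at a time, plain loops), and
#   * a batched path (one pass over all queries, vectorized, with a
#     spatial cell list for neighbour search).
# Both paths share the same elementwise arithmetic kernels, so with ordered
# accumulation the batched results reproduce the reference results bitwise;
# the "unordered" accumulation mode reverses each query's summation order to
# emulate the non-deterministic reductions of a parallel target, which
# perturbs results only at floating-point rounding level.

#' Default geometric cutoffs
#'
#' All cutoffs are configuration, not constants; these defaults follow
#' standard structural-biology heuristics (contact shell 8 A with a minimum
#' sequence separation of 2 residues, N...O hydrogen-bond ceiling 3.5 A with
#' N-H-O at least 120 degrees, anisotropy shell 12 A, ring-current shell 8 A
#' from the ring centroid).
#'
#' @return Named list of cutoffs.
#' @export
default_cutoffs <- function() {
  list(contact_radius = 8.0, contact_min_seq_sep = 2L,
       hbond_max_da_dist = 3.5, hbond_min_nho_angle = 120,
       ani_max_dist = 12.0, ring_max_dist = 8.0)
}

# ---- spatial cell list -----------------------------------------------------

# Hash atoms into cubic cells of edge `cell` (>= the search cutoff) so that
# all atoms within the cutoff of a point live in its 27 neighbouring cells.
make_cell_list <- function(x, y, z, cell, ids = seq_along(x)) {
  ix <- floor(x / cell); iy <- floor(y / cell); iz <- floor(z / cell)
  key <- paste(ix, iy, iz, sep = ",")
  env <- list2env(split(ids, key), hash = TRUE, parent = emptyenv())
  list(env = env, cell = cell)
}

# Candidate ids in the 27 cells around a point, ascending.
cell_neighbors <- function(cl, px, py, pz) {
  ix <- floor(px / cl$cell); iy <- floor(py / cl$cell); iz <- floor(pz / cl$cell)
  off <- -1:1
  keys <- as.vector(outer(outer(ix + off, iy + off, paste, sep = ","),
                          iz + off, paste, sep = ","))
  got <- mget(keys, envir = cl$env, ifnotfound = list(NULL))
  ids <- unlist(got, use.names = FALSE)
  if (is.null(ids)) integer() else sort(ids)
}

# ---- shared elementwise kernels -------------------------------------------

# Linear switching term of the contact descriptor; vector-capable.
contact_term <- function(r, radius) {
  ifelse(r < radius, 1 - r / radius, 0)
}

# Axially symmetric (McConnell point-dipole) anisotropy term; vector-capable
# over proton coordinates.  theta is the angle between the proton->centroid
# vector and the group-plane normal; cos^2 makes the normal sign irrelevant.
ani_kernel <- function(px, py, pz, centroid, normal, delta_chi, max_dist) {
  vx <- centroid[1] - px; vy <- centroid[2] - py; vz <- centroid[3] - pz
  r <- sqrt(vx * vx + vy * vy + vz * vz)
  ct <- (vx * normal[1] + vy * normal[2] + vz * normal[3]) / r
  val <- delta_chi * (1 - 3 * ct * ct) / (3 * r^3)
  ifelse(r > max_dist, 0, val)
}

# Haigh-Mallion ring-current term; vector-capable over query coordinates.
# For each ring bond (i,j), S_ij is the signed area of the triangle formed
# by the query's in-plane projection and projected ring atoms i and j; the
# ring frame's winding convention fixes the sign.
ring_kernel <- function(px, py, pz, frame, ring_xyz, intensity, scale,
                        max_dist) {
  cx <- frame$centroid[1]; cy <- frame$centroid[2]; cz <- frame$centroid[3]
  vx <- px - cx; vy <- py - cy; vz <- pz - cz
  cdist <- sqrt(vx * vx + vy * vy + vz * vz)
  e1 <- frame$basis[, 1]; e2 <- frame$basis[, 2]
  qx2 <- vx * e1[1] + vy * e1[2] + vz * e1[3]
  qy2 <- vx * e2[1] + vy * e2[2] + vz * e2[3]
  n <- nrow(ring_xyz)
  inv_r3 <- vector("list", n)
  for (i in seq_len(n)) {
    dx <- px - ring_xyz[i, 1]; dy <- py - ring_xyz[i, 2]; dz <- pz - ring_xyz[i, 3]
    ri <- sqrt(dx * dx + dy * dy + dz * dz)
    inv_r3[[i]] <- 1 / ri^3
  }
  acc <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    sij <- 0.5 * ((frame$coords2d[i, 1] - qx2) * (frame$coords2d[j, 2] - qy2) -
                  (frame$coords2d[j, 1] - qx2) * (frame$coords2d[i, 2] - qy2))
    acc <- acc + sij * (inv_r3[[i]] + inv_r3[[j]])
  }
  ifelse(cdist > max_dist, 0, intensity * scale * acc)
}

# Hydrogen-bond pair geometry.  Returns c(value, r_no, valid); value is
# (1/r_NO) * cos(180 - NHO) * cos(180 - HOC') when r_NO and the N-H-O angle
# pass the cutoffs, else 0.
hbond_pair <- function(npos, hpos, opos, cpos, cutoffs) {
  dx <- opos - npos
  r_no <- sqrt(sum(dx * dx))
  if (r_no > cutoffs$hbond_max_da_dist) return(c(0, r_no, 0))
  ang_nho <- tryCatch(vec_angle(npos, hpos, opos), error = function(e) NA_real_)
  ang_hoc <- tryCatch(vec_angle(hpos, opos, cpos), error = function(e) NA_real_)
  if (is.na(ang_nho) || is.na(ang_hoc)) {
    warning("degenerate hydrogen-bond geometry; contribution set to 0",
            call. = FALSE)
    return(c(0, r_no, 0))
  }
  if (ang_nho < cutoffs$hbond_min_nho_angle) return(c(0, r_no, 0))
  val <- (1 / r_no) * cos((180 - ang_nho) / DEG) * cos((180 - ang_hoc) / DEG)
  c(val, r_no, 1)
}

# Frame of a planar three-atom group (A, center, B): centroid and unit
# normal of the plane through the three atoms.
group_frame <- function(a, center, b) {
  n <- vec_cross(a - center, b - center)
  nn <- vec_norm(n)
  if (nn < 1e-10)
    stop("degenerate geometry: collinear anisotropy group", call. = FALSE)
  list(centroid = (a + center + b) / 3, normal = n / nn)
}

# Sequence-separation mask: TRUE when atom j may contribute to a contact on
# a query in residue `qres`.  Different chains always count.
seq_sep_ok <- function(q_chain, q_ord, a_chain, a_ord, min_sep) {
  a_chain != q_chain | abs(a_ord - q_ord) >= min_sep
}

# ---- per-call reference path ----------------------------------------------

#' Contact descriptor of one query atom (reference path)
#'
#' Sum over heavy atoms at sequence separation >= `contact_min_seq_sep`
#' (atoms on other chains always count) of the linear switching term
#' `1 - r / contact_radius` for `r < contact_radius`.
#'
#' @param structure A `protein_structure`.
#' @param selection Its `selection_set`.
#' @param cutoffs Geometric cutoffs, see [default_cutoffs()].
#' @param query_index Atom index of the query nucleus.
#' @return Dimensionless contact value.
#' @export
get_contact <- function(structure, selection, cutoffs, query_index) {
  a <- structure$atoms
  res <- structure$residues
  qres <- a$res_index[query_index]
  dx <- a$x - a$x[query_index]
  dy <- a$y - a$y[query_index]
  dz <- a$z - a$z[query_index]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  ok <- a$element != "H" &
    seq_sep_ok(res$chain_id[qres], res$res_seq[qres],
               res$chain_id[a$res_index], res$res_seq[a$res_index],
               cutoffs$contact_min_seq_sep)
  terms <- contact_term(r, cutoffs$contact_radius)
  terms[!ok] <- 0
  sum(terms)
}

#' Hydrogen-bond descriptor of one donor against one acceptor (reference path)
#'
#' @param structure,selection,cutoffs As in [get_contact()].
#' @param donor_pair Integer pair (N index, H index).
#' @param acceptor_pair Integer pair (O index, C' index).
#' @return The geometric H-bond value (0 when the pair fails the distance or
#'   angle cutoff).
#' @export
gethbond <- function(structure, selection, cutoffs, donor_pair, acceptor_pair) {
  a <- structure$atoms
  p <- function(i) c(a$x[i], a$y[i], a$z[i])
  hbond_pair(p(donor_pair[1]), p(donor_pair[2]),
             p(acceptor_pair[1]), p(acceptor_pair[2]), cutoffs)[1]
}

#' Magnetic-anisotropy descriptor of one proton against one group (reference path)
#'
#' Axially symmetric model: `delta_chi * (1 - 3 cos^2 theta) / (3 r^3)` with
#' `r` the proton-to-group-centroid distance and `theta` the angle between
#' the proton->centroid vector and the group-plane normal.  Zero beyond
#' `ani_max_dist`.
#'
#' @param structure,selection,cutoffs As in [get_contact()].
#' @param query_proton Atom index of the proton.
#' @param group_triple Integer triple (A, center, B) of the group atoms.
#' @param group_kind One of `"backbone"`, `"OCN"`, `"OCO"`, `"NCN"` (used
#'   only for reporting; the constant is passed via `delta_chi`).
#' @param delta_chi Anisotropy constant of the group kind.
#' @return Anisotropy contribution (ppm-scaled).
#' @export
getani <- function(structure, selection, cutoffs, query_proton, group_triple,
                   group_kind = "backbone", delta_chi = 1) {
  a <- structure$atoms
  p <- function(i) c(a$x[i], a$y[i], a$z[i])
  fr <- group_frame(p(group_triple[1]), p(group_triple[2]), p(group_triple[3]))
  r <- vec_distance(p(query_proton), fr$centroid)
  if (r < 0.5)
    warning("steric clash: proton within 0.5 A of anisotropy group centroid",
            call. = FALSE)
  as.numeric(ani_kernel(a$x[query_proton], a$y[query_proton],
                        a$z[query_proton], fr$centroid, fr$normal, delta_chi,
                        cutoffs$ani_max_dist))
}

#' Ring-current descriptor of one query atom against one ring (reference path)
#'
#' Haigh-Mallion form `I * B * sum_bonds S_ij (1/r_i^3 + 1/r_j^3)`; `S_ij`
#' is the signed in-plane triangle area spanned by the query's projection
#' and ring atoms i, j.  Zero beyond `ring_max_dist` from the centroid.  The
#' ring plane is re-fitted on every call; the batched path fits it once per
#' ring (the two give identical values).
#'
#' @param structure,selection,cutoffs As in [get_contact()].
#' @param query_index Atom index of the query nucleus (not a ring member).
#' @param ring A ring entry from the selection (`list(kind, idx, res_index)`).
#' @param intensity Ring intensity factor I for the ring kind.
#' @param scale Global ring-current scale B.
#' @return Ring-current contribution (ppm-scaled).
#' @export
getring <- function(structure, selection, cutoffs, query_index, ring,
                    intensity = 1, scale = 1) {
  a <- structure$atoms
  ring_xyz <- as.matrix(a[ring$idx, c("x", "y", "z")])
  fr <- tryCatch(ring_frame(ring_xyz), error = function(e) NULL)
  if (is.null(fr)) {
    warning("degenerate ring plane; ring contribution set to 0", call. = FALSE)
    return(0)
  }
  as.numeric(ring_kernel(a$x[query_index], a$y[query_index], a$z[query_index],
                         fr, ring_xyz, intensity, scale,
                         cutoffs$ring_max_dist))
}

#' Backbone phi/psi dihedrals of one residue
#'
#' `phi = dihedral(C'(i-1), N, CA, C')`, `psi = dihedral(N, CA, C', N(i+1))`.
#' Either angle is `NA` (flagged absent) at a chain terminus or when a
#' required backbone atom is missing; absence is not an error.
#'
#' @param structure A `protein_structure`.
#' @param residue Residue index (row of `structure$residues`).
#' @param selection Optional pre-built selection (built on demand otherwise).
#' @return Named numeric vector `c(phi = , psi = )` in degrees.
#' @export
get_dihedral_descriptor <- function(structure, residue, selection = NULL) {
  if (is.null(selection)) selection <- get_select(structure)
  bb <- selection$backbone
  res <- structure$residues
  a <- structure$atoms
  p <- function(i) c(a$x[i], a$y[i], a$z[i])
  n_res <- nrow(res)
  phi <- NA_real_; psi <- NA_real_
  i <- residue
  if (!anyNA(bb[i, c("N", "CA", "C")])) {
    if (i > 1L && res$chain_id[i - 1L] == res$chain_id[i] &&
        !is.na(bb[i - 1L, "C"]))
      phi <- vec_dihedral(p(bb[i - 1L, "C"]), p(bb[i, "N"]),
                          p(bb[i, "CA"]), p(bb[i, "C"]))
    if (i < n_res && res$chain_id[i + 1L] == res$chain_id[i] &&
        !is.na(bb[i + 1L, "N"]))
      psi <- vec_dihedral(p(bb[i, "N"]), p(bb[i, "CA"]),
                          p(bb[i, "C"]), p(bb[i + 1L, "N"]))
  }
  c(phi = phi, psi = psi)
}

# Global ordered group list for the anisotropy descriptor: backbone amide
# groups first (selection order), then side-chain groups.  The fixed order
# defines the reference summation order.
ani_group_list <- function(structure, selection) {
  a <- structure$atoms
  res_of <- a$res_index
  groups <- list()
  am <- selection$amide_groups
  for (k in seq_len(nrow(am)))
    groups[[length(groups) + 1L]] <-
      list(idx = am[k, c("o", "c", "n")], kind = "backbone",
           res_members = unique(res_of[am[k, c("o", "c", "n")]]))
  for (g in selection$sidechain_groups)
    groups[[length(groups) + 1L]] <-
      list(idx = g$idx, kind = g$kind, res_members = unique(res_of[g$idx]))
  groups
}

# Best-acceptor H-bond value per donor (reference path): scan acceptors in
# ascending order, keep the geometrically valid one with maximal 1/r_NO
# (ties resolved toward the lower acceptor index by the scan order).
hbond_best_reference <- function(structure, selection, cutoffs) {
  a <- structure$atoms
  res <- structure$residues
  don <- selection$donors
  acc <- selection$acceptors
  out <- numeric(nrow(don))
  if (nrow(don) == 0L || nrow(acc) == 0L) return(out)
  p <- function(i) c(a$x[i], a$y[i], a$z[i])
  for (d in seq_len(nrow(don))) {
    dres <- don[d, "res"]
    best_r <- Inf; best_val <- 0
    for (k in seq_len(nrow(acc))) {
      ares <- acc[k, "res"]
      if (ares == dres) next
      if (res$chain_id[ares] == res$chain_id[dres] && ares == dres - 1L) next
      hv <- hbond_pair(p(don[d, "n"]), p(don[d, "h"]),
                       p(acc[k, "o"]), p(acc[k, "c"]), cutoffs)
      if (hv[3] == 1 && hv[2] < best_r) {
        best_r <- hv[2]; best_val <- hv[1]
      }
    }
    out[d] <- best_val
  }
  out
}

# ---- batched path ----------------------------------------------------------

#' Contact descriptor for all query nuclei in one batched pass
#'
#' Equivalent to mapping [get_contact()] over every query: queries are
#' binned into a cell list and processed cell by cell against the heavy
#' atoms of the 27 surrounding cells.  With `accumulation = "ordered"` each
#' query's contributions are summed in ascending atom index, reproducing the
#' reference path exactly; `"unordered"` reverses the summation order,
#' emulating a parallel reduction.
#'
#' @param structure,selection,cutoffs As in [get_contact()].
#' @param accumulation `"ordered"` or `"unordered"`.
#' @return Numeric vector, one contact value per query atom, in the order of
#'   `unlist(selection$query_nuclei)`.
#' @export
batch_get_contact <- function(structure, selection, cutoffs,
                              accumulation = "ordered") {
  a <- structure$atoms
  res <- structure$residues
  qidx <- unlist(selection$query_nuclei, use.names = FALSE)
  nq <- length(qidx)
  if (nq == 0L) return(numeric())
  heavy <- which(a$element != "H")
  cl <- make_cell_list(a$x[heavy], a$y[heavy], a$z[heavy],
                       cutoffs$contact_radius, ids = heavy)
  out <- numeric(nq)
  qcell <- paste(floor(a$x[qidx] / cl$cell), floor(a$y[qidx] / cl$cell),
                 floor(a$z[qidx] / cl$cell), sep = ",")
  rev_sum <- accumulation == "unordered"
  for (grp in split(seq_len(nq), qcell)) {
    q1 <- qidx[grp[1]]
    cand <- cell_neighbors(cl, a$x[q1], a$y[q1], a$z[q1])
    if (length(cand) == 0L) next
    cx <- a$x[cand]; cy <- a$y[cand]; cz <- a$z[cand]
    c_chain <- res$chain_id[a$res_index[cand]]
    c_ord <- res$res_seq[a$res_index[cand]]
    for (g in grp) {
      qi <- qidx[g]
      qr <- a$res_index[qi]
      dx <- cx - a$x[qi]; dy <- cy - a$y[qi]; dz <- cz - a$z[qi]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      ok <- seq_sep_ok(res$chain_id[qr], res$res_seq[qr],
                       c_chain, c_ord, cutoffs$contact_min_seq_sep)
      terms <- contact_term(r, cutoffs$contact_radius)
      terms[!ok] <- 0
      out[g] <- if (rev_sum) sum(rev(terms)) else sum(terms)
    }
  }
  out
}

# Batched best-acceptor H-bond values per donor, via a cell list over
# acceptor O atoms.  The per-pair kernel and winner rule are shared with the
# reference path, so results are identical (selection by maximum, so the
# accumulation mode plays no role here).
batch_gethbond <- function(structure, selection, cutoffs,
                           accumulation = "ordered") {
  a <- structure$atoms
  res <- structure$residues
  don <- selection$donors
  acc <- selection$acceptors
  out <- numeric(nrow(don))
  if (nrow(don) == 0L || nrow(acc) == 0L) return(out)
  cl <- make_cell_list(a$x[acc[, "o"]], a$y[acc[, "o"]], a$z[acc[, "o"]],
                       cutoffs$hbond_max_da_dist, ids = seq_len(nrow(acc)))
  p <- function(i) c(a$x[i], a$y[i], a$z[i])
  for (d in seq_len(nrow(don))) {
    dres <- don[d, "res"]
    np <- p(don[d, "n"]); hp <- p(don[d, "h"])
    best_r <- Inf; best_val <- 0
    for (k in cell_neighbors(cl, np[1], np[2], np[3])) {
      ares <- acc[k, "res"]
      if (ares == dres) next
      if (res$chain_id[ares] == res$chain_id[dres] && ares == dres - 1L) next
      hv <- hbond_pair(np, hp, p(acc[k, "o"]), p(acc[k, "c"]), cutoffs)
      if (hv[3] == 1 && hv[2] < best_r) {
        best_r <- hv[2]; best_val <- hv[1]
      }
    }
    out[d] <- best_val
  }
  out
}

# Batched anisotropy for all query protons: iterate groups (ascending for
# ordered accumulation, descending for unordered) and scatter each group's
# kernel values onto the protons within range.  Per-proton accumulation
# order is therefore ascending group order, matching the reference scan.
batch_getani <- function(structure, selection, cutoffs, delta_chi,
                         proton_idx, accumulation = "ordered") {
  a <- structure$atoms
  np <- length(proton_idx)
  out <- numeric(np)
  if (np == 0L) return(out)
  groups <- ani_group_list(structure, selection)
  if (length(groups) == 0L) return(out)
  px <- a$x[proton_idx]; py <- a$y[proton_idx]; pz <- a$z[proton_idx]
  pres <- a$res_index[proton_idx]
  cl <- make_cell_list(px, py, pz, cutoffs$ani_max_dist)
  ord <- seq_along(groups)
  if (accumulation == "unordered") ord <- rev(ord)
  p <- function(i) c(a$x[i], a$y[i], a$z[i])
  for (gi in ord) {
    g <- groups[[gi]]
    fr <- group_frame(p(g$idx[1]), p(g$idx[2]), p(g$idx[3]))
    cand <- cell_neighbors(cl, fr$centroid[1], fr$centroid[2], fr$centroid[3])
    if (length(cand) == 0L) next
    cand <- cand[!(pres[cand] %in% g$res_members)]
    if (length(cand) == 0L) next
    val <- ani_kernel(px[cand], py[cand], pz[cand], fr$centroid, fr$normal,
                      delta_chi[[g$kind]], cutoffs$ani_max_dist)
    out[cand] <- out[cand] + val
  }
  out
}

# Batched ring currents for all query atoms: iterate rings (ascending order
# for ordered accumulation), fit each ring frame once, and scatter kernel
# values onto the queries within range.  Ring members never receive their
# own ring's contribution.
batch_getring <- function(structure, selection, cutoffs, ring_I, ring_B,
                          query_idx, accumulation = "ordered") {
  a <- structure$atoms
  nq <- length(query_idx)
  out <- numeric(nq)
  rings <- selection$rings
  if (nq == 0L || length(rings) == 0L) return(out)
  qx <- a$x[query_idx]; qy <- a$y[query_idx]; qz <- a$z[query_idx]
  cl <- make_cell_list(qx, qy, qz, cutoffs$ring_max_dist)
  ord <- seq_along(rings)
  if (accumulation == "unordered") ord <- rev(ord)
  for (ri in ord) {
    ring <- rings[[ri]]
    ring_xyz <- as.matrix(a[ring$idx, c("x", "y", "z")])
    fr <- tryCatch(ring_frame(ring_xyz), error = function(e) NULL)
    if (is.null(fr)) {
      warning("degenerate ring plane; ring contribution set to 0",
              call. = FALSE)
      next
    }
    cand <- cell_neighbors(cl, fr$centroid[1], fr$centroid[2], fr$centroid[3])
    if (length(cand) == 0L) next
    cand <- cand[!(query_idx[cand] %in% ring$idx)]
    if (length(cand) == 0L) next
    val <- ring_kernel(qx[cand], qy[cand], qz[cand], fr, ring_xyz,
                       ring_I[[ring$kind]], ring_B, cutoffs$ring_max_dist)
    out[cand] <- out[cand] + val
  }
  out
}

# ---- descriptor assembly ---------------------------------------------------

#' Compute all descriptor families for every query nucleus
#'
#' @param structure A `protein_structure`.
#' @param selection Its (optionally proton-filtered) `selection_set`.
#' @param params A `parameter_set` (supplies cutoffs, anisotropy constants
#'   and ring intensities).
#' @param mode `"reference"` (per-call loops), `"batched"` (vectorized, one
#'   pass, ordered accumulation) or `"batched-unordered"` (reversed
#'   accumulation order, emulating a parallel reduction).
#' @return Data frame with one row per (query atom, nucleus class):
#'   identification columns plus `contact`, `hbond`, `ani`, `ring`, `phi`,
#'   `psi`.  The hydrogen-bond value of a residue's donor is attached to all
#'   of that residue's query nuclei; anisotropy applies to proton queries
#'   only.
#' @export
compute_descriptors <- function(structure, selection, params,
                                mode = c("reference", "batched",
                                         "batched-unordered")) {
  mode <- match.arg(mode)
  cutoffs <- params$cutoffs
  a <- structure$atoms
  res <- structure$residues
  q <- selection$query_nuclei
  qidx <- unlist(q, use.names = FALSE)
  qnuc <- rep(names(q), lengths(q))
  qres <- unlist(selection$query_res, use.names = FALSE)
  nq <- length(qidx)
  n_res <- nrow(res)

  is_proton <- qnuc %in% c("HN", "HA")
  accumulation <- if (mode == "batched-unordered") "unordered" else "ordered"

  if (mode == "reference") {
    contact <- vapply(qidx, function(i)
      get_contact(structure, selection, cutoffs, i), numeric(1))

    don_val <- hbond_best_reference(structure, selection, cutoffs)

    groups <- ani_group_list(structure, selection)
    ani <- numeric(nq)
    pq <- which(is_proton)
    for (k in pq) {
      acc <- 0
      for (g in groups) {
        if (qres[k] %in% g$res_members) next
        acc <- acc + getani(structure, selection, cutoffs, qidx[k], g$idx,
                            g$kind, params$delta_chi[[g$kind]])
      }
      ani[k] <- acc
    }

    ringv <- numeric(nq)
    for (k in seq_len(nq)) {
      acc <- 0
      for (ring in selection$rings) {
        if (qidx[k] %in% ring$idx) next
        acc <- acc + getring(structure, selection, cutoffs, qidx[k], ring,
                             params$ring_intensity[[ring$kind]],
                             params$ring_scale)
      }
      ringv[k] <- acc
    }

    phi_res <- rep(NA_real_, n_res); psi_res <- rep(NA_real_, n_res)
    for (i in seq_len(n_res)) {
      if (!(res$res_name[i] %in% STANDARD_AA)) next
      d <- get_dihedral_descriptor(structure, i, selection)
      phi_res[i] <- d["phi"]; psi_res[i] <- d["psi"]
    }
  } else {
    contact <- batch_get_contact(structure, selection, cutoffs, accumulation)
    don_val <- batch_gethbond(structure, selection, cutoffs, accumulation)
    ani <- numeric(nq)
    pq <- which(is_proton)
    ani[pq] <- batch_getani(structure, selection, cutoffs, params$delta_chi,
                            qidx[pq], accumulation)
    ringv <- batch_getring(structure, selection, cutoffs,
                           params$ring_intensity, params$ring_scale,
                           qidx, accumulation)
    phi_res <- rep(NA_real_, n_res); psi_res <- rep(NA_real_, n_res)
    for (i in which(res$res_name %in% STANDARD_AA)) {
      d <- get_dihedral_descriptor(structure, i, selection)
      phi_res[i] <- d["phi"]; psi_res[i] <- d["psi"]
    }
  }

  hb_res <- numeric(n_res)
  if (nrow(selection$donors) > 0L)
    hb_res[selection$donors[, "res"]] <- don_val

  data.frame(
    atom = qidx, nucleus = qnuc, res_index = qres,
    chain = res$chain_id[qres], res_seq = res$res_seq[qres],
    res_name = res$res_name[qres],
    contact = contact, hbond = hb_res[qres], ani = ani, ring = ringv,
    phi = phi_res[qres], psi = psi_res[qres],
    stringsAsFactors = FALSE)
}
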