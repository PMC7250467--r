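# Descriptor families: analytic cases, brute-force oracles, batched-path
# equivalence, rigid-motion invariance, r^-3 decay.

co <- default_cutoffs()

test_that("contact switching term behaves at the midpoint and in isolation", {
  # two residues far apart -> no contact at all
  iso <- build_peptide("AA", c(-57, -47), include_hydrogens = FALSE)
  a <- iso$atoms
  a$x[a$res_seq == 2] <- a$x[a$res_seq == 2] + 100
  far <- pepshift:::new_protein_structure(a)
  sel <- get_select(far)
  expect_equal(get_contact(far, sel, co, sel$query_nuclei$CA[1]), 0)

  # single neighbour at exactly half the contact radius, seq-sep satisfied
  probe <- data.frame(
    serial = 1:2, name = c("CA", "CA"), element = c("C", "C"),
    res_name = c("ALA", "ALA"), res_seq = c(1L, 5L), chain_id = "A",
    insert = " ", x = c(0, co$contact_radius / 2), y = 0, z = 0,
    occupancy = 1, alt_loc = " ", het = FALSE, stringsAsFactors = FALSE)
  st <- pepshift:::new_protein_structure(probe)
  sel2 <- get_select(st)
  expect_equal(get_contact(st, sel2, co, 1L), 0.5)
})

test_that("contact equals an all-pairs brute-force oracle on a random cluster", {
  set.seed(31)
  n <- 50
  atoms <- data.frame(
    serial = 1:n, name = "CA", element = "C", res_name = "ALA",
    res_seq = 1:n, chain_id = "A", insert = " ",
    x = runif(n, 0, 18), y = runif(n, 0, 18), z = runif(n, 0, 18),
    occupancy = 1, alt_loc = " ", het = FALSE, stringsAsFactors = FALSE)
  st <- pepshift:::new_protein_structure(atoms)
  sel <- get_select(st)
  oracle <- function(q) {
    acc <- 0
    for (j in 1:n) {
      if (abs(j - q) < co$contact_min_seq_sep) next
      r <- sqrt(sum((atoms[q, c("x", "y", "z")] - atoms[j, c("x", "y", "z")])^2))
      if (r < co$contact_radius) acc <- acc + (1 - r / co$contact_radius)
    }
    acc
  }
  for (q in c(1, 17, 50))
    expect_equal(get_contact(st, sel, co, q), oracle(q), tolerance = 1e-12)
  # batched path agrees element-wise with the per-call map
  ref <- vapply(unlist(sel$query_nuclei, use.names = FALSE), function(i)
    get_contact(st, sel, co, i), numeric(1))
  expect_equal(batch_get_contact(st, sel, co), ref, tolerance = 0)
  expect_equal(batch_get_contact(st, sel, co, "unordered"), ref,
               tolerance = 1e-10)
})

test_that("hydrogen-bond geometry: collinear value, cutoff, angle gate", {
  sc <- build_probe_scene("hbond_collinear", r = 2.9)
  v <- gethbond(sc$structure, NULL, co, sc$donor, sc$acceptor)
  expect_equal(v, 1 / 2.9, tolerance = 1e-12)

  sc_far <- build_probe_scene("hbond_collinear", r = 4.2)
  expect_equal(gethbond(sc_far$structure, NULL, co, sc_far$donor,
                        sc_far$acceptor), 0)
})

test_that("helix H-bond ladder matches an exhaustive donor x acceptor oracle", {
  hel <- build_peptide(strrep("A", 12), c(-57, -47))
  sel <- get_select(hel)
  res <- hel$residues
  oracle <- numeric(nrow(sel$donors))
  for (d in seq_len(nrow(sel$donors))) {
    best_r <- Inf; best <- 0
    for (k in seq_len(nrow(sel$acceptors))) {
      dres <- sel$donors[d, "res"]; ares <- sel$acceptors[k, "res"]
      if (ares == dres || (res$chain_id[ares] == res$chain_id[dres] &&
                           ares == dres - 1L)) next
      v <- gethbond(hel, sel, co, sel$donors[d, c("n", "h")],
                    sel$acceptors[k, c("o", "c")])
      p <- function(i) c(hel$atoms$x[i], hel$atoms$y[i], hel$atoms$z[i])
      r_no <- vec_distance(p(sel$donors[d, "n"]), p(sel$acceptors[k, "o"]))
      if (v != 0 && r_no < best_r) { best_r <- r_no; best <- v }
    }
    oracle[d] <- best
  }
  got <- pepshift:::batch_gethbond(hel, sel, co)
  expect_equal(got, oracle, tolerance = 1e-12)
  # the alpha-helical ladder is i -> i-4: interior donors are bonded
  expect_true(all(got[sel$donors[, "res"] >= 5] > 0))
  expect_true(all(got[sel$donors[, "res"] < 5] == 0))
})

test_that("anisotropy: axial value, magic-angle zero, r^-3 decay, oracle", {
  sc <- build_probe_scene("ani_axial", r = 2, theta = 0, delta_chi = 1)
  v <- getani(sc$structure, NULL, co, sc$probe_index, sc$group,
              delta_chi = 1)
  expect_equal(v, -1 / 12, tolerance = 1e-12)

  magic <- acos(sqrt(1 / 3)) * 180 / pi
  scm <- build_probe_scene("ani_axial", r = 2, theta = magic)
  expect_equal(getani(scm$structure, NULL, co, scm$probe_index, scm$group,
                      delta_chi = 1), 0, tolerance = 1e-12)

  # doubling the axial distance divides the value by exactly 8
  sc2 <- build_probe_scene("ani_axial", r = 4, theta = 0)
  v2 <- getani(sc2$structure, NULL, co, sc2$probe_index, sc2$group,
               delta_chi = 1)
  expect_equal(v / v2, 8, tolerance = 1e-9)

  # random proton positions against a direct formula evaluation
  set.seed(5)
  for (k in 1:20) {
    pos <- rnorm(3, 0, 3)
    a <- sc$structure$atoms
    a[4, c("x", "y", "z")] <- pos
    st <- pepshift:::new_protein_structure(a)
    got <- getani(st, NULL, co, 4L, 1:3, delta_chi = -12.9)
    centroid <- unname(colMeans(as.matrix(a[1:3, c("x", "y", "z")])))
    r <- sqrt(sum((pos - centroid)^2))
    # plane of the group is z = 0, normal (0,0,1)
    ct <- (centroid[3] - pos[3]) / r
    oracle <- if (r > co$ani_max_dist) 0 else
      -12.9 * (1 - 3 * ct^2) / (3 * r^3)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("ring current: axial closed form, sign flip in plane, cutoff, decay", {
  sc <- build_probe_scene("ring_axial", height = 3)
  v <- getring(sc$structure, NULL, co, sc$probe_index, sc$ring, 1, 1)
  expect_equal(v, sc$ground_truth, tolerance = 1e-9)
  expect_gt(v, 0)

  # numeric oracle: direct Haigh-Mallion evaluation over the hexagon
  ringc <- as.matrix(sc$structure$atoms[1:6, c("x", "y", "z")])
  q <- c(0, 0, 3)
  s_sum <- 0
  for (i in 1:6) {
    j <- if (i == 6) 1 else i + 1
    s_ij <- 0.5 * ((ringc[i, 1] - q[1]) * (ringc[j, 2] - q[2]) -
                   (ringc[j, 1] - q[1]) * (ringc[i, 2] - q[2]))
    ri <- sqrt(sum((q - ringc[i, ])^2)); rj <- sqrt(sum((q - ringc[j, ])^2))
    s_sum <- s_sum + s_ij * (1 / ri^3 + 1 / rj^3)
  }
  expect_equal(v, s_sum, tolerance = 1e-9)

  # in-plane query far outside the ring: deshielding region, opposite sign
  a <- sc$structure$atoms
  a[7, c("x", "y", "z")] <- c(4.5, 0, 0)
  st_in <- pepshift:::new_protein_structure(a)
  v_in <- getring(st_in, NULL, co, 7L, sc$ring, 1, 1)
  expect_lt(v_in * v, 0)

  # beyond the centroid cutoff -> exactly zero
  a[7, c("x", "y", "z")] <- c(0, 0, co$ring_max_dist + 0.5)
  st_far <- pepshift:::new_protein_structure(a)
  expect_equal(getring(st_far, NULL, co, 7L, sc$ring, 1, 1), 0)

  # r^-3 decay on doubling the query-to-vertex distance
  r1 <- sqrt(1.39^2 + 3^2)
  h2 <- sqrt((2 * r1)^2 - 1.39^2)
  sc2 <- build_probe_scene("ring_axial", height = h2)
  v2 <- getring(sc2$structure, NULL, co, sc2$probe_index, sc2$ring, 1, 1)
  expect_equal(v / v2, 8, tolerance = 1e-9)
})

test_that("phi/psi are recovered exactly and termini are flagged absent", {
  st <- build_peptide(strrep("A", 8), c(-57, -47))
  sel <- get_select(st)
  for (i in 2:7) {
    d <- get_dihedral_descriptor(st, i, sel)
    expect_equal(unname(d["phi"]), -57, tolerance = 1e-6)
    expect_equal(unname(d["psi"]), -47, tolerance = 1e-6)
  }
  expect_true(is.na(get_dihedral_descriptor(st, 1, sel)["phi"]))
  expect_true(is.na(get_dihedral_descriptor(st, 8, sel)["psi"]))
})

test_that("descriptors are invariant under rigid-body motion", {
  st <- build_peptide("AFAWANA", c(-57, -47))
  sel <- clear_protons(get_select(st), st)
  p <- default_params_cached()
  d0 <- compute_descriptors(st, sel, p, "batched")
  for (seed in 1:3) {
    stm <- rigid_motion(st, seed)
    selm <- clear_protons(get_select(stm), stm)
    dm <- compute_descriptors(stm, selm, p, "batched")
    for (colm in c("contact", "hbond", "ani", "ring"))
      expect_equal(dm[[colm]], d0[[colm]], tolerance = 1e-9)
    expect_equal(dm$phi, d0$phi, tolerance = 1e-6)
    expect_equal(dm$psi, d0$psi, tolerance = 1e-6)
  }
})

test_that("batched path reproduces the per-call path on mixed structures", {
  set.seed(13)
  sts <- build_validation_set(2, 30, seed = 99)
  p <- default_params_cached()
  for (st in sts) {
    sel <- clear_protons(get_select(st), st)
    dr <- compute_descriptors(st, sel, p, "reference")
    db <- compute_descriptors(st, sel, p, "batched")
    du <- compute_descriptors(st, sel, p, "batched-unordered")
    for (colm in c("contact", "hbond", "ani", "ring")) {
      expect_equal(db[[colm]], dr[[colm]], tolerance = 0)
      expect_equal(du[[colm]], dr[[colm]], tolerance = 1e-10)
    }
  }
})

test_that("hydrogen-free structures zero the proton families but still predict", {
  dry <- build_peptide("AFAEANA", c(-139, 135), include_hydrogens = FALSE)
  sel <- clear_protons(get_select(dry), dry)
  p <- default_params_cached()
  d <- compute_descriptors(dry, sel, p, "batched")
  expect_true(all(d$hbond == 0))
  expect_true(all(d$ani == 0))
  tab <- predict_shifts(dry, sel, p, "batched")
  expect_true(all(tab$nucleus %in% c("CA", "CB", "C", "N")))
  expect_gt(nrow(tab), 0)
  expect_true(all(is.finite(tab$shift_ppm)))
})

test_that("empty query sets yield empty batched results", {
  sc <- build_probe_scene("hbond_collinear")
  sel <- get_select(sc$structure)
  sel$query_nuclei <- lapply(sel$query_nuclei, function(x) integer())
  expect_length(batch_get_contact(sc$structure, sel, co), 0L)
})
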