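# Geometric kernels: exact cases, brute-force oracles, rigid-motion
# invariance.

test_that("distance matches hand cases and a sum-of-squares oracle", {
  expect_identical(vec_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_identical(vec_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(42)
  for (k in 1:100) {
    a <- rnorm(3, 0, 10); b <- rnorm(3, 0, 10)
    oracle <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
    expect_equal(vec_distance(a, b), oracle, tolerance = 1e-12)
    expect_equal(vec_distance(b, a), vec_distance(a, b))
  }
})

test_that("angle matches exact cases and the arccos oracle", {
  expect_equal(vec_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vec_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_error(vec_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
  set.seed(7)
  for (k in 1:50) {
    a <- rnorm(3); v <- rnorm(3); c3 <- rnorm(3)
    u1 <- a - v; u2 <- c3 - v
    oracle <- acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
    expect_equal(vec_angle(a, v, c3), oracle, tolerance = 1e-9)
  }
})

test_that("dihedral follows the IUPAC convention and its antisymmetry", {
  # planar cis and trans butane-like arrangements
  expect_equal(vec_dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)), 0)
  expect_equal(abs(vec_dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                                c(2, -1, 0))), 180)
  expect_error(vec_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
  set.seed(9)
  for (k in 1:50) {
    p <- replicate(4, rnorm(3), simplify = FALSE)
    d <- tryCatch(vec_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                  error = function(e) NA)
    if (is.na(d)) next
    # IUPAC torsion: unchanged by traversal reversal, negated by mirror
    # reflection (an improper operation flips chirality)
    expect_equal(vec_dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d,
                 tolerance = 1e-9)
    m <- lapply(p, function(v) c(v[1], v[2], -v[3]))
    expect_equal(vec_dihedral(m[[1]], m[[2]], m[[3]], m[[4]]), -d,
                 tolerance = 1e-9)
    expect_true(d > -180 && d <= 180)
  }
  # atan2-of-cross-products oracle
  set.seed(10)
  for (k in 1:30) {
    p <- replicate(4, rnorm(3), simplify = FALSE)
    b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    oracle <- atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) *
      180 / pi
    expect_equal(vec_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("ring_frame recovers plane, centroid and winding", {
  ang <- (0:5) * pi / 3
  hex <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  fr <- ring_frame(hex)
  expect_equal(fr$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(fr$normal), c(0, 0, 1), tolerance = 1e-12)
  # counter-clockwise winding seen from +normal
  expect_equal(fr$normal[3], 1)
  # translation equivariance
  fr2 <- ring_frame(sweep(hex, 2, c(5, 5, 5), "+"))
  expect_equal(fr2$centroid, c(5, 5, 5), tolerance = 1e-12)
  expect_equal(fr2$normal, fr$normal, tolerance = 1e-12)
  # in-plane coordinates are centred
  expect_equal(colMeans(fr$coords2d), c(0, 0), tolerance = 1e-9)
  expect_equal(sqrt(sum(fr$normal^2)), 1, tolerance = 1e-9)
  expect_error(ring_frame(cbind(1:5, 1:5, 1:5)), "collinear|5 or 6")
})

test_that("ring_frame normal matches an SVD plane fit for puckered rings", {
  set.seed(3)
  for (k in 1:20) {
    ang <- (0:5) * pi / 3
    ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), rnorm(6, 0, 0.05))
    fr <- ring_frame(ring)
    centred <- sweep(ring, 2, colMeans(ring))
    n_oracle <- svd(centred)$v[, 3]
    # sign-insensitive comparison against the oracle
    expect_equal(abs(sum(fr$normal * n_oracle)), 1, tolerance = 1e-9)
  }
})

test_that("kernels are invariant under rigid-body motion", {
  set.seed(21)
  for (k in 1:10) {
    pts <- replicate(4, rnorm(3, 0, 5), simplify = FALSE)
    qr_ <- qr(matrix(rnorm(9), 3, 3)); R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tv <- rnorm(3, 0, 10)
    mv <- lapply(pts, function(p) as.numeric(R %*% p + tv))
    expect_equal(vec_distance(mv[[1]], mv[[2]]),
                 vec_distance(pts[[1]], pts[[2]]), tolerance = 1e-9)
    expect_equal(vec_angle(mv[[1]], mv[[2]], mv[[3]]),
                 vec_angle(pts[[1]], pts[[2]], pts[[3]]), tolerance = 1e-9)
    expect_equal(vec_dihedral(mv[[1]], mv[[2]], mv[[3]], mv[[4]]),
                 vec_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                 tolerance = 1e-9)
  }
})
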