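test_that("self-superposition gives identity rotation and zero rmsd", {
  set.seed(7)
  pts <- matrix(rnorm(30), 10, 3)
  tr <- kabsch_superpose(pts, pts)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_lt(tr$rmsd, 1e-12)
  expect_lt(max(abs(apply_transform(tr, pts) - pts)), 1e-9)
})

test_that("a known rigid motion is recovered exactly", {
  set.seed(11)
  pts <- matrix(rnorm(45), 15, 3)
  R <- rotation_about_axis(c(1, -2, 0.5), 30)
  moved <- sweep(pts %*% t(R), 2, c(3, -1, 2), `+`)
  tr <- kabsch_superpose(pts, moved)
  expect_lt(tr$rmsd, 1e-9)
  expect_lt(max(abs(apply_transform(tr, pts) - moved)), 1e-9)
  # inverse transform undoes it
  inv <- invert_transform(tr)
  expect_lt(max(abs(apply_transform(inv, moved) - pts)), 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd equals the direct pairwise-distance oracle", {
  set.seed(13)
  a <- matrix(rnorm(36), 12, 3)
  b <- a + matrix(rnorm(36, 0, 0.3), 12, 3)   # noisy copy, no exact fit
  tr <- kabsch_superpose(a, b)
  expect_equal(tr$rmsd, oracle_rmsd(apply_transform(tr, a), b),
               tolerance = 1e-12)
})

test_that("kabsch is invariant to pair order and common rigid motion", {
  set.seed(17)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, 0, 0.2), 10, 3)
  r0 <- kabsch_superpose(a, b)$rmsd
  ord <- sample(10)
  expect_equal(kabsch_superpose(a[ord, ], b[ord, ])$rmsd, r0,
               tolerance = 1e-12)
  R <- rotation_about_axis(c(0, 1, 1), 77)
  t0 <- c(-4, 2, 9)
  a2 <- sweep(a %*% t(R), 2, t0, `+`)
  b2 <- sweep(b %*% t(R), 2, t0, `+`)
  expect_equal(kabsch_superpose(a2, b2)$rmsd, r0, tolerance = 1e-9)
})

test_that("degenerate point sets are refused", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "at least 3")
})

test_that("dihedral angles agree with an independent implementation", {
  library(bio3d)
  set.seed(19)
  for (k in 1:25) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    ours <- tryCatch(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                     error = function(e) NA)
    if (is.na(ours)) next
    ref <- bio3d::torsion.xyz(as.numeric(t(pts)))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("dihedral of collinear atoms is an error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("place_atom realizes requested internal coordinates", {
  a <- c(0, 0, 0); b <- c(1.5, 0, 0); c <- c(2.1, 1.4, 0)
  for (tor in c(-120, -60, 0, 45, 180)) {
    d <- place_atom(a, b, c, 1.52, 111, tor)
    expect_equal(sqrt(sum((d - c)^2)), 1.52, tolerance = 1e-9)
    expect_equal(dihedral_angle(a, b, c, d), tor, tolerance = 1e-9)
    v1 <- b - c; v2 <- d - c
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(ang, 111, tolerance = 1e-9)
  }
})
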