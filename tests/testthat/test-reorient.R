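test_that("fit_plane reproduces simple planes and passes through its points", {
  pl <- fit_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$offset, 0)

  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(rnorm(9, sd = 30), 3, 3)
    pl <- fit_plane(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
    resid <- abs(pts %*% pl$normal - pl$offset)
    expect_lt(max(resid), 1e-9)
    # SVD oracle: least-squares plane of 3 points has the same normal
    ctr <- sweep(pts, 2, colMeans(pts))
    sv <- svd(ctr)
    n_svd <- sv$v[, 3]
    expect_equal(abs(sum(n_svd * pl$normal)), 1, tolerance = 1e-9)
  }
})

test_that("fit_plane rejects collinear points", {
  expect_error(fit_plane(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), "collinear")
})

test_that("rigid transforms are validated, composed and inverted", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "reflection")
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")

  set.seed(5)
  t1 <- random_rigid(); t2 <- random_rigid()
  expect_equal(det(t1$rotation), 1, tolerance = 1e-12)
  comp <- compose_transform(t1, t2)
  x <- c(3, -4, 7)
  direct <- as.numeric(t1$rotation %*% (t2$rotation %*% x + t2$translation)) +
    t1$translation
  via <- as.numeric(comp$rotation %*% x) + comp$translation
  expect_equal(via, direct, tolerance = 1e-10)

  inv <- invert_transform(t1)
  roundtrip <- compose_transform(inv, t1)
  expect_equal(roundtrip$rotation, diag(3), tolerance = 1e-10)
  expect_equal(roundtrip$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("reorientation of the canonical template is the identity", {
  tpl <- landmark_template()
  tr <- compute_reorientation(tpl)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("reorientation recovers canonical coordinates after any pose", {
  tpl <- landmark_template()
  set.seed(21)
  for (i in 1:25) {
    pose <- random_rigid(max_rot_deg = 60, max_trans = 40)
    posed <- apply_transform(tpl, pose, frame = "raw")
    back <- apply_transform(posed, compute_reorientation(posed))
    expect_lt(max(abs(back$coords - tpl$coords)), 1e-6)
  }
})

test_that("reorientation aligns the Frankfort and midsagittal planes", {
  tpl <- landmark_template()
  set.seed(31)
  pose <- random_rigid(max_rot_deg = 45, max_trans = 30)
  posed <- apply_transform(tpl, pose, frame = "raw")
  tr <- compute_reorientation(posed)
  re <- apply_transform(posed, tr)
  z_fh <- re$coords[c("rPo", "rOr", "lOr"), "z"]
  expect_lt(max(abs(z_fh - z_fh[1])), 1e-9)
  expect_lt(max(abs(re$coords[c("Na", "ANS", "MGNM"), "y"])), 1e-6)
  expect_lt(attr(tr, "midsagittal_residual_mm"), 1e-6)
  # origin at Sella, +X anterior
  expect_equal(unname(re$coords["S", ]), c(0, 0, 0), tolerance = 1e-9)
  expect_gt(re$coords["Na", "x"], re$coords["MGNM", "x"])
})

test_that("near-parallel reference planes are rejected", {
  # all six defining landmarks in one horizontal plane
  lms <- tiny_landmarks(list(
    rPo = c(0, -5, 0), rOr = c(6, -3, 0), lOr = c(6, 3, 0),
    Na = c(8, 0, 0), ANS = c(9, 1, 0), MGNM = c(-4, 0, 0),
    S = c(0, 0, 0)))
  expect_error(compute_reorientation(lms), "parallel")
})

test_that("apply_transform is exact, invertible and isometric on landmarks", {
  tpl <- landmark_template()
  ident <- rigid_transform()
  expect_equal(apply_transform(tpl, ident)$coords, tpl$coords)

  set.seed(41)
  for (i in 1:10) {
    t1 <- random_rigid()
    moved <- apply_transform(tpl, t1, frame = "raw")
    back <- apply_transform(moved, invert_transform(t1))
    expect_lt(max(abs(back$coords - tpl$coords)), 1e-9)
    # isometry: all pairwise distances preserved
    d0 <- dist(tpl$coords); d1 <- dist(moved$coords)
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("grid transform preserves binary masks under lattice translations", {
  g <- generate_airway_grid(pi * 9 * 20, pi * 9, z_sup = 20, z_inf = 0,
                            voxel = 0.5, aspect = 1, center = c(0, 0))
  shift <- rigid_transform(diag(3), c(2 * 0.5, -3 * 0.5, 0.5))
  moved <- apply_transform(g, shift)
  expect_s3_class(moved, "voxel_grid")
  expect_equal(sum(moved$mask), sum(g$mask))
  expect_equal(airway_volume(moved), airway_volume(g))
})

test_that("transform JSON serialization round-trips", {
  set.seed(3)
  t1 <- random_rigid()
  f <- tempfile(fileext = ".json")
  write_transform_json(t1, f)
  t2 <- read_transform_json(f)
  expect_equal(t2$rotation, t1$rotation, tolerance = 1e-12)
  expect_equal(t2$translation, t1$translation, tolerance = 1e-12)
})
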