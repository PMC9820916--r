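test_that("bounding planes follow the palatal and C3 landmarks", {
  lms <- tiny_landmarks(list(PNS = c(20, 0, 20), ANS = c(70, 0, 20),
                             C3 = c(-10, 0, -40)), frame = "reoriented")
  zb <- bounding_planes(lms)
  expect_equal(unname(zb), c(20, -40))

  lms2 <- tiny_landmarks(list(PNS = c(20, 0, 21), ANS = c(70, 0, 19),
                              C3 = c(-10, 0, -40)), frame = "reoriented")
  expect_equal(unname(bounding_planes(lms2)["z_sup"]), 20)

  lms3 <- tiny_landmarks(list(PNS = c(20, 0, 25), ANS = c(70, 0, 15),
                              C3 = c(-10, 0, -40)), frame = "reoriented")
  expect_warning(bounding_planes(lms3), "palatal")

  bad <- tiny_landmarks(list(PNS = c(20, 0, -50), ANS = c(70, 0, -50),
                             C3 = c(-10, 0, -40)), frame = "reoriented")
  expect_error(suppressWarnings(bounding_planes(bad)), "above")

  span <- diff(rev(unname(bounding_planes(landmark_template()))))
  expect_gt(span, 40); expect_lt(span, 90)
})

test_that("cropping between planes keeps centers inclusively and is idempotent", {
  g <- generate_airway_grid(pi * 4 * 40, pi * 4, z_sup = 40, z_inf = 0,
                            voxel = 0.5, aspect = 1, center = c(0, 0))
  full <- crop_between_planes(g, 40, 0)
  half <- crop_between_planes(g, 20, 0)
  ratio <- sum(half$mask) / sum(full$mask)
  expect_equal(ratio, 0.5, tolerance = 0.5 / 40)  # within one slice

  expect_error(crop_between_planes(g, 500, 400), "intersect")
  again <- crop_between_planes(half, 20, 0)
  expect_identical(again$mask, half$mask)
})

test_that("airway volume is the exact voxel count times voxel cubed", {
  mask <- array(FALSE, c(12, 12, 12))
  mask[2:11, 2:11, 2:11] <- TRUE
  g <- voxel_grid(mask, voxel = 0.3)
  expect_equal(airway_volume(g), 1000 * 0.027)
  expect_equal(airway_volume(voxel_grid(array(FALSE, c(4, 4, 4)), 0.3)), 0)
})

test_that("cylinder phantom volume and CSAmin are accurate at 0.3 mm", {
  vol <- pi * 9 * 30; csa <- pi * 9
  g <- generate_airway_grid(vol, csa, z_sup = 30, z_inf = 0, voxel = 0.3,
                            aspect = 1, center = c(0, 0))
  gc <- crop_between_planes(g, 30, 0)
  expect_lt(abs(airway_volume(gc) - vol) / vol, 0.02)
  cs <- csa_min(gc)
  expect_lt(abs(cs$CSAmin - csa) / csa, 0.02)
  # constant tube: all slices share the minimal area; extents ~ diameter
  areas <- apply(gc$mask, 3, sum) * 0.09
  areas <- areas[areas > 0]
  expect_lt(diff(range(areas)), 0.09 * 3)
  expect_equal(cs$Ap, 6, tolerance = 0.3)
  expect_equal(cs$Lat, 6, tolerance = 0.3)
})

test_that("hourglass phantom: minimal slice at the waist, 3% accuracy", {
  vol <- 60 * (100 + 250) / 2   # cosine profile: mean area 175
  g <- generate_airway_grid(vol, 100, z_sup = 30, z_inf = -30, voxel = 0.3,
                            aspect = 0.5, center = c(2, 0))
  gc <- crop_between_planes(g, 30, -30)
  cs <- csa_min(gc)
  expect_lt(abs(cs$CSAmin - 100) / 100, 0.03)
  expect_lt(abs(airway_volume(gc) - vol) / vol, 0.03)
  expect_lt(abs(cs$slice_z), 1)          # waist at mid-height
  expect_gt(cs$slice_z, -30); expect_lt(cs$slice_z, 30)
})

test_that("elliptical waist extents recover the semi-axes within one voxel", {
  csa <- pi * 8 * 4
  g <- generate_airway_grid(60 * (csa + 200) / 2, csa, 30, -30, 0.3,
                            aspect = 0.5, center = c(0, 0))  # ax 8, ay 4
  cs <- csa_min(crop_between_planes(g, 30, -30))
  expect_equal(cs$Ap, 16, tolerance = 0.3)
  expect_equal(cs$Lat, 8, tolerance = 0.3)
})

test_that("CSAmin ties break toward the most inferior slice", {
  mask <- array(FALSE, c(5, 5, 4))
  mask[2:3, 2:3, 1] <- TRUE      # area 4 (inferior)
  mask[1:4, 1:4, 2] <- TRUE      # area 16
  mask[2:3, 2:3, 3] <- TRUE      # area 4 (tie with slice 1)
  g <- voxel_grid(mask, voxel = 1, origin = c(0, 0, 0))
  expect_equal(csa_min(g)$slice_z, 0)
})

test_that("volume is monotone in the air set and bounded by CSAmin", {
  g <- generate_airway_grid(60 * 175, 100, 30, -30, 0.6, aspect = 0.5)
  gc <- crop_between_planes(g, 30, -30)
  bigger <- gc
  bigger$mask[1, 1, 5] <- TRUE
  expect_gte(airway_volume(bigger), airway_volume(gc))
  # CSAmin <= mean slice area = Vol / height
  expect_lte(csa_min(gc)$CSAmin, airway_volume(gc) / 60 + 1e-9)
})

test_that("discretization error shrinks when the voxel halves", {
  vol <- 60 * (100 + 250) / 2
  verr <- cerr <- numeric(0)
  for (v in c(1.2, 0.6, 0.3)) {
    g <- generate_airway_grid(vol, 100, 30, -30, v, aspect = 0.5,
                              center = c(2, 0))
    gc <- crop_between_planes(g, 30, -30)
    verr <- c(verr, abs(airway_volume(gc) - vol) / vol)
    cerr <- c(cerr, abs(csa_min(gc)$CSAmin - 100) / 100)
  }
  expect_true(all(diff(verr) < 0))
  expect_true(all(diff(cerr) < 0))
})

test_that("largest 26-connected component drops stray voxels", {
  g <- generate_airway_grid(pi * 9 * 20, pi * 9, 20, 0, 0.5, aspect = 1,
                            center = c(0, 0))
  noisy <- g
  noisy$mask[1, 1, 1] <- TRUE            # isolated corner voxel
  noisy$mask[2, 1, dim(noisy$mask)[3]] <- TRUE
  clean <- largest_component(noisy)
  expect_equal(sum(clean$mask), sum(g$mask))
  expect_false(clean$mask[1, 1, 1])
})

test_that("airway_metrics combines cropping, filtering and extraction", {
  tpl <- landmark_template()
  zb <- bounding_planes(tpl)
  g <- generate_airway_grid(14460, 206, zb["z_sup"], zb["z_inf"], 0.6)
  am <- airway_metrics(g, tpl)
  expect_equal(unname(am["Vol"]), 14460, tolerance = 0.01)
  expect_equal(unname(am["CSAmin"]), 206, tolerance = 0.03)
  expect_gt(am[["Ap"]], 0); expect_gt(am[["Lat"]], am[["Ap"]])
})

test_that("incompatible volume/CSAmin targets are rejected", {
  expect_error(generate_airway_grid(1000, 100, 30, 0, 0.5), "incompatible")
  expect_error(generate_airway_grid(-5, 100, 30, 0, 0.5), "targets")
  expect_error(generate_airway_grid(6000, 100, 0, 30, 0.5), "z_sup")
})

test_that("NIfTI grid IO round-trips mask, spacing and origin", {
  g <- generate_airway_grid(pi * 4 * 10, pi * 4, 10, 0, 0.5, aspect = 1)
  f <- tempfile(fileext = ".nii.gz")
  write_grid_nifti(g, f)
  g2 <- read_grid_nifti(f)
  expect_identical(g2$mask, g$mask)
  expect_equal(g2$voxel, g$voxel, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-4)
})
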