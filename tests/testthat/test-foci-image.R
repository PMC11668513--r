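# 3D segmentation, foci counting, colocalization and the rotation null.

test_that("blur preserves flat fields and spreads peaks", {
  flat <- array(3, dim = c(8, 8, 4))
  expect_equal(gaussian_blur_3d(flat, 1.5), flat)
  # a spike far from every border spreads but conserves total intensity
  spike <- array(0, dim = c(21, 21, 13))
  spike[11, 11, 7] <- 100
  b <- gaussian_blur_3d(spike, 1)
  expect_lt(max(b), 100)
  expect_equal(sum(b), 100, tolerance = 1e-6)
  expect_equal(which.max(b), which.max(spike))
})

test_that("connected-component labeling uses 26-connectivity", {
  m <- array(FALSE, dim = c(6, 6, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE # diagonal in all three axes: same component
  m[5, 5, 3] <- TRUE # far away: second component
  lab <- label_components_3d(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_false(lab[5, 5, 3] == lab[1, 1, 1])
  expect_equal(max(label_components_3d(array(FALSE, dim = c(4, 4, 2)))), 0L)
})

test_that("nucleus segmentation recovers planted ellipsoids", {
  st <- generate_image_stack(n_foci = 0, seed = 51)
  seg <- segment_nuclei(st$dapi)
  expect_equal(max(seg), 1L)
  truth <- st$nuclei_mask == 1
  jac <- sum(seg == 1 & truth) / sum(seg == 1 | truth)
  expect_gte(jac, 0.9)

  two <- generate_image_stack(dims = c(128L, 64L, 24L), n_nuclei = 2,
                              n_foci = 0, seed = 52)
  seg2 <- segment_nuclei(two$dapi)
  expect_equal(max(seg2), 2L)

  expect_warning(z <- segment_nuclei(array(0, dim = c(8, 8, 4))), "zero nuclei")
  expect_equal(max(z), 0L)
})

test_that("foci counting honors the mask and the 10-voxel filter", {
  st <- generate_image_stack(n_foci = 3, seed = 53)
  fc <- count_foci(st$target, st$nuclei_mask == 1)
  expect_equal(fc$count, 3L)
  expect_true(all(fc$sizes >= 10))

  # a bright 8-voxel (2x2x2) object is always removed by the size filter
  v <- array(0, dim = c(24, 24, 12))
  mask <- array(TRUE, dim = dim(v))
  v[11:12, 11:12, 5:6] <- 100
  fc8 <- count_foci(v, mask, sigma = 0, min_voxels = 10, threshold = 50)
  expect_equal(fc8$count, 0L)
  # the same object passes a 8-voxel filter
  expect_equal(count_foci(v, mask, sigma = 0, min_voxels = 8, threshold = 50)$count, 1L)

  # a focus outside the mask is never counted
  st2 <- generate_image_stack(n_foci = 1, seed = 54)
  outside_mask <- st2$nuclei_mask == 1
  outside_mask[st2$foci$x + (-6:6), , ] <- FALSE
  expect_equal(count_foci(st2$target, outside_mask)$count, 0L)

  expect_error(count_foci(v, array(FALSE, dim = dim(v))), "empty")
})

test_that("foci count is invariant under global intensity scaling", {
  st <- generate_image_stack(n_foci = 7, seed = 55)
  m <- st$nuclei_mask == 1
  expect_equal(count_foci(st$target * 13.7, m)$count,
               count_foci(st$target, m)$count)
})

test_that("colocalization identities hold exactly", {
  withr::local_seed(56)
  ch <- array(runif(16 * 16 * 8, 1, 10), dim = c(16, 16, 8))
  cc <- coloc_coefficients(ch, ch)
  expect_equal(cc$pearson, 1)
  expect_equal(cc$spearman, 1)
  expect_equal(cc$manders_m1, 1)
  expect_equal(cc$manders_m2, 1)

  anti <- coloc_coefficients(ch, max(ch) - ch)
  expect_equal(anti$pearson, -1)

  expect_warning(flat <- coloc_coefficients(ch, array(5, dim = dim(ch))), "constant")
  expect_true(is.na(flat$pearson))

  # Pearson equals the textbook covariance form
  ch2 <- array(runif(length(ch)), dim = dim(ch))
  x <- as.vector(ch); y <- as.vector(ch2)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(coloc_coefficients(ch, ch2)$pearson, manual, tolerance = 1e-12)

  # independent noise decorrelates
  big1 <- array(runif(50 * 50 * 40), dim = c(50, 50, 40))
  big2 <- array(runif(50 * 50 * 40), dim = c(50, 50, 40))
  expect_lt(abs(coloc_coefficients(big1, big2)$pearson), 0.02)

  expect_error(coloc_coefficients(ch, ch, mask = array(FALSE, dim = dim(ch))),
               "at least 10")
})

test_that("rotation null is deterministic and respects symmetry", {
  # centred radially symmetric blob: coefficients unchanged by rotation
  d <- c(21, 21, 9)
  ctr <- (d + 1) / 2
  blob <- array(0, dim = d)
  for (z in 1:d[3]) {
    for (x in 1:d[1]) for (y in 1:d[2]) {
      blob[x, y, z] <- exp(-((x - ctr[1])^2 + (y - ctr[2])^2) / 18)
    }
  }
  mask <- array(TRUE, dim = d)
  withr::local_seed(57)
  ch1 <- blob + array(runif(prod(d), 0, 1e-3), dim = d)
  plain <- coloc_coefficients(ch1, blob, mask)
  for (ang in c(90, 180, 270)) {
    rot <- rotation_null(ch1, blob, mask, angle = ang)
    expect_equal(rot$pearson, plain$pearson, tolerance = 0.02)
    expect_identical(rot, rotation_null(ch1, blob, mask, angle = ang))
  }

  # planted co-located foci decorrelate under rotation
  st <- generate_image_stack(n_foci = 6, coloc_fraction = 1, seed = 58)
  m <- st$nuclei_mask == 1
  real <- coloc_coefficients(st$target, st$channel2, m)
  null <- rotation_null(st$target, st$channel2, m, angle = 90)
  expect_gt(real$pearson, null$pearson + 0.3)

  expect_error(rotation_null(ch1, blob, array(FALSE, dim = d), 90), "fewer than 10")
})

test_that("region means normalize against the control reference", {
  v <- array(10, dim = c(10, 10, 5))
  sp <- array(FALSE, dim = dim(v)); sp[1:3, 1:3, ] <- TRUE
  np <- array(FALSE, dim = dim(v)); np[6:9, 6:9, ] <- TRUE
  r <- region_mean_intensity(v, list(Sp = sp, Np = np), reference = 10)
  expect_equal(unname(r), c(1, 1))

  v[sp] <- 30
  r2 <- region_mean_intensity(v, list(Sp = sp, Np = np), reference = 10)
  expect_equal(unname(r2["Sp"] / r2["Np"]), 3)

  r3 <- region_mean_intensity(v, list(E = array(FALSE, dim = dim(v))), 10)
  expect_true(is.na(r3))
})

test_that("volumes survive a 16-bit TIFF round trip", {
  st <- generate_image_stack(dims = c(48L, 48L, 16L), n_foci = 2, seed = 59)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(st$target, f, scale = max(st$target))
  v <- read_volume_tiff(f, scale = max(st$target))
  expect_equal(dim(v), dim(st$target))
  expect_lt(max(abs(v - st$target)) / max(st$target), 1e-4)
})
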