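test_that("the density ratio is exact voxel counting", {
  breast <- array(FALSE, c(10, 10, 10)); breast[1:10, 1:10, 1] <- TRUE  # 100 voxels
  dense <- array(FALSE, c(10, 10, 10)); dense[1:10, 1, 1] <- TRUE      # 10 voxels
  expect_identical(compute_density(list(breast = breast, dense = dense)), 0.1)
  expect_identical(compute_density(list(breast = breast, dense = breast)), 1)
  expect_identical(compute_density(list(breast = breast,
                                        dense = array(FALSE, c(10, 10, 10)))), 0)
})

test_that("degenerate mask pairs are rejected", {
  e <- array(FALSE, c(4, 4, 4))
  f <- array(TRUE, c(4, 4, 4))
  expect_error(compute_density(list(breast = e, dense = e)), "Empty breast")
  d <- array(FALSE, c(4, 4, 4)); d[1, 1, 1] <- TRUE
  b <- f; b[1, 1, 1] <- FALSE
  expect_error(compute_density(list(breast = b, dense = d)), "outside")
  expect_error(mask_pair(b, d), "outside")
})

test_that("ground-truth density equals the generator's counted ratio to machine precision", {
  for (i in 1:10) {
    td <- runif(1, 0.02, 0.5)
    ph <- generate_phantom(phantom_spec(grid_shape = c(36, 36, 36),
                                        target_density = td, seed = 7000 + i))
    counted <- sum(ph$truth$dense) / sum(ph$truth$breast)
    expect_equal(compute_density(ph$truth), counted, tolerance = 1e-15)
  }
})

test_that("laterality splitting returns the two ellipsoids intact", {
  ph <- tiny_phantom(0.1, seed = 31, shape = c(48, 48, 48), half = "bilateral")
  sides <- split_laterality(ph$truth$breast)
  expect_equal(sum(sides$left) + sum(sides$right), sum(ph$truth$breast))
  expect_false(any(sides$left & sides$right))
  # left side sits at larger x (patient left in LPS)
  xs <- slice.index(ph$truth$breast, 1)
  expect_gt(mean(xs[sides$left]), mean(xs[sides$right]))
})

test_that("a single-sided phantom leaves the other side empty", {
  ph <- tiny_phantom(0.1, seed = 32, shape = c(48, 48, 48), half = "left")
  sides <- split_laterality(ph$truth$breast)
  expect_equal(sum(sides$right), 0)
  expect_identical(sides$left, ph$truth$breast)
})

test_that("mirror-flipping the mask swaps the side assignments", {
  ph <- tiny_phantom(0.1, seed = 33, shape = c(48, 48, 48), half = "bilateral")
  m <- ph$truth$breast
  flipped <- m[dim(m)[1]:1, , ]
  s1 <- split_laterality(m)
  s2 <- split_laterality(flipped)
  expect_identical(s2$left, s1$right[dim(m)[1]:1, , ])
  expect_identical(s2$right, s1$left[dim(m)[1]:1, , ])
  expect_error(split_laterality(array(FALSE, c(4, 4, 4))), "Empty")
})

test_that("a connected midline mask is split at the mid-coronal plane", {
  m <- array(FALSE, c(10, 6, 6))
  m[2:9, 2:5, 2:5] <- TRUE   # one component across the midline
  s <- split_laterality(m)
  expect_equal(sum(s$left) + sum(s$right), sum(m))
  expect_true(all(which(s$left, arr.ind = TRUE)[, 1] > 5))
  expect_true(all(which(s$right, arr.ind = TRUE)[, 1] <= 5))
})

test_that("the contralateral rule reports the normal breast only", {
  res <- tibble::tibble(exam_id = "e1", side = c("left", "right"),
                        breast_voxels = c(1000, 900), dense_voxels = c(100, 135),
                        density = c(0.10, 0.15))
  out <- select_reported_density(res, cancer_laterality = "left")
  expect_equal(out$side, "right")
  expect_equal(out$density, 0.15)
  out2 <- select_reported_density(res, cancer_laterality = "right")
  expect_equal(out2$side, "left")
  expect_error(select_reported_density(res[res$side == "right", ],
                                       cancer_laterality = "right"),
               "Contralateral")
})

test_that("screening exams report both sides plus their mean", {
  res <- tibble::tibble(exam_id = "e1", side = c("left", "right"),
                        breast_voxels = c(1000, 1000), dense_voxels = c(100, 140),
                        density = c(0.10, 0.14))
  out <- select_reported_density(res, cancer_laterality = "none")
  expect_equal(nrow(out), 3)
  expect_equal(out$density[out$side == "exam"], 0.12)
  out_max <- select_reported_density(res, "none", screening_rule = "max")
  expect_equal(out_max$density[out_max$side == "exam"], 0.14)
})

test_that("per-side densities from a bilateral phantom match the target on both sides", {
  ph <- tiny_phantom(0.18, seed = 55, shape = c(48, 48, 48))
  rows <- density_by_side(ph$truth, exam_id = "p")
  expect_equal(nrow(rows), 2)
  expect_true(all(abs(rows$density - 0.18) <= 0.02))
})
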