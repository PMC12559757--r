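test_that("a patch equal to the volume yields the single origin start", {
  g <- build_patch_grid(c(96, 96, 96), c(96, 96, 96), c(8, 8, 3))
  expect_equal(nrow(g$starts), 1L)
  expect_equal(as.vector(g$starts[1, ]), c(0, 0, 0))
})

test_that("two steps of a 96 patch cover a 191 axis", {
  g <- build_patch_grid(c(191, 96, 96), c(96, 96, 96), c(2, 1, 1))
  xs <- sort(unique(g$starts[, 1]))
  expect_equal(xs, c(0, 95))
  covered <- rep(FALSE, 191)
  for (s in xs) covered[(s + 1):(s + 96)] <- TRUE
  expect_true(all(covered))
})

test_that("default grid geometry on a 256x256x96 volume matches uniform rounding", {
  g <- build_patch_grid(c(256, 256, 96), c(96, 96, 96), c(8, 8, 3))
  xs <- sort(unique(g$starts[, 1]))
  expect_equal(xs, round(seq(0, 160, length.out = 8)))
  expect_equal(sort(unique(g$starts[, 3])), 0)
})

test_that("random grids fully cover their volumes (brute-force check)", {
  set.seed(42)
  for (i in 1:25) {
    shape <- sample(20:80, 3, replace = TRUE)
    patch <- pmin(shape, sample(8:40, 3, replace = TRUE))
    steps <- pmax(ceiling((shape - patch) / patch) + 1, sample(1:4, 3, TRUE))
    g <- build_patch_grid(shape, patch, steps)
    cov <- array(FALSE, shape)
    for (r in seq_len(nrow(g$starts))) {
      s <- g$starts[r, ]
      cov[(s[1] + 1):(s[1] + patch[1]), (s[2] + 1):(s[2] + patch[2]),
          (s[3] + 1):(s[3] + patch[3])] <- TRUE
    }
    expect_true(all(cov))
  }
})

test_that("too few steps for the volume is a coverage error", {
  expect_error(build_patch_grid(c(300, 96, 96), c(96, 96, 96), c(2, 1, 1)),
               "covered")
  expect_error(build_patch_grid(c(64, 64, 64), c(96, 96, 96)), "Patch exceeds")
})

test_that("fusing identical constant predictions returns the constant", {
  g <- build_patch_grid(c(30, 30, 30), c(16, 16, 16), c(3, 3, 3))
  preds <- lapply(seq_len(nrow(g$starts)), function(i) {
    list(start = g$starts[i, ], block = array(0.7, c(16, 16, 16)))
  })
  f <- fuse_patches(preds, c(30, 30, 30))
  expect_true(all(abs(f$probs - 0.7) < 1e-15))
  expect_true(all(f$counts >= 1))
})

test_that("a voxel covered by 0.2 and 0.4 fuses to their mean", {
  preds <- list(list(start = c(0, 0, 0), block = array(0.2, c(4, 4, 4))),
                list(start = c(2, 0, 0), block = array(0.4, c(4, 4, 4))))
  f <- fuse_patches(preds, c(6, 4, 4))
  expect_equal(f$probs[3, 1, 1], 0.3)
  expect_equal(f$counts[3, 1, 1], 2L)
  expect_equal(f$probs[1, 1, 1], 0.2)
})

test_that("fusion matches a brute-force accumulate-and-divide oracle", {
  set.seed(7)
  for (rep in 1:5) {
    shape <- c(14, 12, 10)
    preds <- lapply(1:12, function(i) {
      ps <- sample(3:6, 3, replace = TRUE)
      st <- vapply(1:3, function(a) sample(0:(shape[a] - ps[a]), 1), numeric(1))
      list(start = st, block = array(runif(prod(ps)), ps))
    })
    # guarantee coverage with one full-volume block
    preds[[13]] <- list(start = c(0, 0, 0), block = array(runif(prod(shape)), shape))
    f <- fuse_patches(preds, shape)
    acc <- array(0, shape); cnt <- array(0, shape)
    for (p in preds) {
      for (i in seq_len(dim(p$block)[1])) for (j in seq_len(dim(p$block)[2]))
        for (k in seq_len(dim(p$block)[3])) {
          acc[p$start[1] + i, p$start[2] + j, p$start[3] + k] <-
            acc[p$start[1] + i, p$start[2] + j, p$start[3] + k] + p$block[i, j, k]
          cnt[p$start[1] + i, p$start[2] + j, p$start[3] + k] <-
            cnt[p$start[1] + i, p$start[2] + j, p$start[3] + k] + 1
        }
    }
    expect_lt(max(abs(f$probs - acc / cnt)), 1e-7)
    expect_identical(as.vector(f$counts), as.integer(acc * 0 + cnt))
  }
})

test_that("an uncovered voxel is an error naming its index", {
  preds <- list(list(start = c(0, 0, 0), block = array(1, c(2, 4, 4))))
  expect_error(fuse_patches(preds, c(4, 4, 4)), "\\(3, 1, 1\\)")
})

test_that("patch-wise application of a deterministic cutoff equals global application", {
  ph <- tiny_phantom(0.2, seed = 17, noise = 4, shape = c(40, 40, 40))
  v <- ph$volume$intensities
  model <- fixed_cutoff_model(150)
  mask <- segment_volume(model, v, patch_size = c(16, 16, 16), steps = c(4, 4, 4))
  expect_identical(mask, v > 150)
})

test_that("constant-1 mock gives a full mask; threshold 1 with probs < 1 gives none", {
  m1 <- structure(list(), class = "const_model")
  assign("predict_patch.const_model",
         function(model, patch, ...) array(1, dim(patch)), envir = globalenv())
  on.exit(rm("predict_patch.const_model", envir = globalenv()), add = TRUE)
  v <- array(rnorm(8^3), c(8, 8, 8))
  expect_true(all(segment_volume(m1, v, patch_size = c(8, 8, 8), steps = c(1, 1, 1))))

  m2 <- fixed_cutoff_model(Inf)   # all probabilities 0 < 1
  expect_false(any(segment_volume(m2, v, threshold = 1.0,
                                  patch_size = c(8, 8, 8), steps = c(1, 1, 1))))
})

test_that("volumes smaller than the patch are padded and cropped back", {
  v <- array(runif(10 * 12 * 8), c(10, 12, 8))
  mask <- segment_volume(fixed_cutoff_model(0.5), v, patch_size = c(16, 16, 16))
  expect_identical(dim(mask), dim(v))
  expect_identical(mask, v > 0.5)
})
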