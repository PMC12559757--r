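test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(1)
  cfg <- segmenter_config(base_channels = 2, depth = 2, patch_size = c(8, 8, 8))
  params <- mridense:::vnet_init_params(cfg)
  x <- array(rnorm(512), c(8, 8, 8, 1))
  t_ <- array(rbinom(512, 1, 0.3), c(8, 8, 8, 1))
  lossfn <- function(p) {
    mridense:::dice_loss_grad(mridense:::vnet_forward(p, x, cfg$depth), t_)$loss
  }
  fwd <- mridense:::vnet_forward(params, x, cfg$depth, cache = TRUE)
  lg <- mridense:::dice_loss_grad(fwd$prob, t_)
  gr <- mridense:::vnet_backward(params, fwd, lg$glogit, cfg$depth)
  set.seed(2)
  for (nm in names(params)) {
    i <- sample(length(params[[nm]]), 1)
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + 1e-6
    p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - 1e-6
    num <- (lossfn(p2) - lossfn(p3)) / 2e-6
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("dice + cross-entropy loss gradient is also exact", {
  set.seed(3)
  prob_logit <- array(rnorm(64), c(4, 4, 4, 1))
  t_ <- array(rbinom(64, 1, 0.4), c(4, 4, 4, 1))
  f <- function(lg) {
    p <- 1 / (1 + exp(-lg))
    mridense:::dice_loss_grad(p, t_, with_ce = TRUE)$loss
  }
  p <- 1 / (1 + exp(-prob_logit))
  g <- mridense:::dice_loss_grad(p, t_, with_ce = TRUE)$glogit
  i <- 17
  l2 <- prob_logit; l2[i] <- l2[i] + 1e-6
  l3 <- prob_logit; l3[i] <- l3[i] - 1e-6
  expect_equal(g[i], (f(l2) - f(l3)) / 2e-6, tolerance = 1e-5)
})

test_that("a fixed seed reproduces the loss trajectory exactly", {
  ph <- tiny_phantom(0.2, seed = 61, shape = c(32, 32, 32))
  pair <- list(list(volume = zscore_normalize(ph$volume), mask = ph$truth$dense))
  cfg <- segmenter_config(base_channels = 2, depth = 2, lr = 0.02, epochs = 5,
                          patch_size = c(16, 16, 16), seed = 123)
  m1 <- train_segmenter(pair, cfg, "dense")
  m2 <- train_segmenter(pair, cfg, "dense")
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("training loss decreases in moving average and beats the empty predictor", {
  ph <- tiny_phantom(0.2, seed = 62, shape = c(32, 32, 32))
  pair <- list(list(volume = zscore_normalize(ph$volume), mask = ph$truth$dense))
  cfg <- segmenter_config(base_channels = 4, depth = 2, lr = 0.03, epochs = 40,
                          loss = "dice+ce", patch_size = c(16, 16, 16), seed = 5)
  m <- train_segmenter(pair, cfg, "dense")
  h <- m$history
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
  mask <- segment_volume(m, pair[[1]]$volume, threshold = 0.5,
                         patch_size = c(16, 16, 16), steps = c(3, 3, 3))
  dsc <- dice_coefficient(mask, ph$truth$dense)
  # empty-mask predictor scores 0 on a non-empty truth
  expect_gte(dsc, 0.5)
})

test_that("training inputs are validated", {
  ph <- tiny_phantom(0.2, seed = 63, shape = c(32, 32, 32))
  raw_pair <- list(list(volume = ph$volume, mask = ph$truth$dense))
  cfg <- segmenter_config(base_channels = 2, depth = 2, epochs = 1,
                          patch_size = c(16, 16, 16), seed = 1)
  expect_warning(train_segmenter(raw_pair, cfg, "dense"), "normalized")
  bad <- list(list(volume = zscore_normalize(ph$volume),
                   mask = ph$truth$dense[1:16, 1:16, 1:16]))
  expect_error(train_segmenter(bad, cfg, "dense"), "differ")
  expect_error(segmenter_config(depth = 1), ">= 2")
  expect_error(segmenter_config(depth = 3, patch_size = c(18, 16, 16)),
               "divisible")
})

test_that("patch-size mismatch at inference is an error", {
  ph <- tiny_phantom(0.2, seed = 64, shape = c(32, 32, 32))
  pair <- list(list(volume = zscore_normalize(ph$volume), mask = ph$truth$dense))
  cfg <- segmenter_config(base_channels = 2, depth = 3, lr = 0.02, epochs = 1,
                          patch_size = c(16, 16, 16), seed = 1)
  m <- train_segmenter(pair, cfg, "dense")
  expect_error(predict_patch(m, array(0, c(10, 10, 10))), "divisible")
  p <- predict_patch(m, array(0, c(16, 16, 16)))
  expect_identical(dim(p), c(16L, 16L, 16L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("checkpoints round-trip through save/load", {
  ph <- tiny_phantom(0.2, seed = 65, shape = c(32, 32, 32))
  pair <- list(list(volume = zscore_normalize(ph$volume), mask = ph$truth$dense))
  m <- train_segmenter(pair, segmenter_config(base_channels = 2, epochs = 1,
                                              patch_size = c(16, 16, 16)), "dense")
  f <- withr::local_tempfile(fileext = ".rds")
  save_segmenter(m, f)
  m2 <- load_segmenter(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg, m$cfg)
})
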