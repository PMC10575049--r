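test_that("one epoch on a ten-sample set produces complete bookkeeping", {
  rg <- sampling_ranges()
  tr <- generate_dataset(10, rg, seed = 1, augment = FALSE)
  va <- generate_dataset(4, rg, seed = 2)
  m <- build_ynet(ynet_spec(depth = 3, base_channels = 2), 1)
  fit <- train_ynet(m, tr, va, training_config(epochs = 1, batch_size = 4,
                                               seed = 3))
  expect_s3_class(fit, "ynet_fit")
  expect_equal(nrow(fit$history), 1)
  loss_cols <- c(paste0("train_", c("L1", "L2", "L3", "L4")),
                 paste0("val_", c("L1", "L2", "L3", "L4")))
  expect_true(all(loss_cols %in% names(fit$history)))
  expect_true(all(is.finite(unlist(fit$history[1, loss_cols]))))
  expect_equal(fit$best_epoch, 1L)

  # broom-style accessors
  td <- tidy(fit)
  expect_true(all(c("epoch", "split", "term", "loss") %in% names(td)))
  expect_equal(nrow(td), 10)       # 5 terms x 2 splits x 1 epoch
  expect_equal(nrow(glance(fit)), 1)
})

test_that("training is reproducible for a fixed seed", {
  rg <- sampling_ranges()
  tr <- generate_dataset(12, rg, seed = 5, augment = FALSE)
  m <- build_ynet(ynet_spec(depth = 3, base_channels = 2), 2)
  cfg <- training_config(epochs = 2, batch_size = 6, seed = 11)
  f1 <- train_ynet(m, tr, config = cfg)
  f2 <- train_ynet(m, tr, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$final$params, f2$final$params)
})

test_that("empty datasets and divergence are rejected loudly", {
  rg <- sampling_ranges()
  tr <- generate_dataset(4, rg, seed = 1, augment = FALSE)
  m <- build_ynet(ynet_spec(depth = 3, base_channels = 2), 1)
  ds0 <- tr; ds0$samples <- list()
  expect_error(train_ynet(m, ds0), "empty")
  # absurd learning rate blows the loss up to non-finite within epochs
  expect_error(
    train_ynet(m, tr, config = training_config(epochs = 30, batch_size = 4,
                                               learning_rate = 1e6,
                                               seed = 1)),
    "epoch"
  )
})

test_that("cutoff localization with non-maximum suppression is deterministic", {
  p <- matrix(0.01, 10, 10)
  p[5, 7] <- 0.9
  got <- localize(p, cutoff = 0.5, min_separation = 2)
  expect_equal(nrow(got), 1)
  expect_equal(got$x, 6L)   # 0-based column
  expect_equal(got$y, 4L)

  expect_equal(nrow(localize(matrix(0.3, 8, 8), cutoff = 0.5)), 0)

  # adjacent pixels: the weaker one is suppressed within min_separation 2
  p2 <- matrix(0.01, 10, 10)
  p2[5, 7] <- 0.9; p2[5, 8] <- 0.8
  got2 <- localize(p2, cutoff = 0.5, min_separation = 2)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$prob, 0.9)
  # but survives outside the suppression radius
  p2[5, 7 + 3] <- 0.8
  expect_equal(nrow(localize(p2, cutoff = 0.5, min_separation = 2)), 2)
})

test_that("the diffraction radius follows the Abbe criterion", {
  cfg <- optical_config()
  expect_equal(diffraction_radius(cfg), 633 / (2 * 1.49), tolerance = 1e-12)
  expect_equal(diffraction_radius(cfg), 212.4, tolerance = 1e-3)
  expect_equal(diffraction_radius(cfg) / 93, 2.284, tolerance = 1e-3)
  cfg2 <- optical_config(numerical_aperture = 2 * 1.49)
  expect_equal(diffraction_radius(cfg2), diffraction_radius(cfg) / 2)
})

test_that("greedy matching scores the documented example fractions", {
  r <- 2.284 * 93   # diffraction radius in nm at 93 nm pixels
  exact <- localization_accuracy(
    list(tibble::tibble(x = 10, y = 20)),
    list(tibble::tibble(x = 10, y = 20)), r, 93)
  expect_equal(exact$accuracy, 1.0)

  miss <- localization_accuracy(
    list(tibble::tibble(x = 13, y = 20)),
    list(tibble::tibble(x = 10, y = 20)), r, 93)
  expect_equal(miss$accuracy, 0.0)

  # four truths at pixel distances {0, 1, 2, 5}
  preds <- list(tibble::tibble(x = c(10, 31, 52, 75), y = 10))
  trs <- list(tibble::tibble(x = c(10, 30, 50, 70), y = 10))
  got <- localization_accuracy(preds, trs, r, 93)
  expect_equal(got$accuracy, 0.75)
  expect_equal(sum(got$results$within_limit), 3)
})

test_that("accuracy is monotone non-decreasing in the matching radius", {
  set.seed(13)
  preds <- lapply(1:20, function(i) tibble::tibble(x = runif(1, 0, 80),
                                                   y = runif(1, 0, 80)))
  trs <- lapply(1:20, function(i) tibble::tibble(x = runif(1, 0, 80),
                                                 y = runif(1, 0, 80)))
  accs <- vapply(c(50, 100, 200, 400, 800, 1e6), function(r) {
    localization_accuracy(preds, trs, r, 93)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[length(accs)], 1.0)
})

test_that("localizing oracle probability maps recovers the encoded pixels", {
  ds <- generate_dataset(15, sampling_ranges(), seed = 17)
  for (s in ds$samples) {
    pmap <- s$prob * 0.98 + 0.01   # targets as near-certain probabilities
    det <- localize(pmap, cutoff = 0.5, min_separation = 2)
    expect_equal(nrow(det), nrow(s$pixels))
    expect_setequal(paste(det$x, det$y), paste(s$pixels$x, s$pixels$y))
  }
})

test_that("evaluation scores an oracle head perfectly and a mute head at zero", {
  ds <- generate_dataset(6, sampling_ranges(), seed = 23)
  m <- build_ynet(ynet_spec(depth = 3, base_channels = 2), 1)

  # mute localizer: zero weights, strongly negative location bias
  mute <- m
  mute$params <- lapply(m$params, function(p) p * 0)
  attr(mute$params, "depth") <- m$spec$depth
  mute$params$out_b <- matrix(c(-40, 0, 0), 1, 3)
  ev0 <- evaluate_ynet(mute, ds)
  expect_equal(nrow(ev0$results), 6)
  expect_equal(ev0$accuracy, 0)
  expect_equal(ev0$false_positive_rate, 0)
  expect_true(all(is.na(ev0$results$distance)))

  # oracle outputs injected directly into the metric path
  preds <- lapply(ds$samples, function(s) s$pixels[, c("x", "y")])
  truths <- lapply(ds$samples, function(s) s$pixels)
  r <- diffraction_radius(ds$samples[[1]]$config)
  acc <- localization_accuracy(preds, truths, r,
                               vapply(ds$samples,
                                      function(s) s$config$pixel_size,
                                      numeric(1)))
  expect_equal(acc$accuracy, 1.0)
  expect_equal(acc$false_positive_rate, 0)
})
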