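test_that("binary cross-entropy matches hand-computed values", {
  y <- matrix(c(1L, 0L), 1, 2)
  expect_lt(bce_loss(matrix(c(1, 0), 1, 2), y), 1.2e-7)     # clipped perfection
  expect_equal(bce_loss(matrix(0.5, 1, 2), y), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(matrix(c(0.9, 0.2), 1, 2), y),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), y), "differ")
})

training_fixture <- function(n = 14, seed = 77) {
  cfg <- tiny_synth_config(seed = seed, n = 48L)
  d <- generate_dataset(n, cfg)
  unlist(lapply(d, function(e)
    lapply(ccs_sample_pair(e$image, e$mask, crop_size = 16L, id = e$id),
           function(cr) list(image = cr$image, mask = cr$mask))),
    recursive = FALSE)
}

test_that("training reduces the loss and respects the early-stopping contract", {
  pairs <- training_fixture()
  cfg <- train_config(max_epochs = 12L, early_stop_patience = 3L, seed = 2)
  fit <- model_fit(unet_tiny(seed = 1), pairs, cfg)
  expect_lt(tail(fit$curves$train_loss, 1), fit$curves$train_loss[1])
  expect_true(all(is.finite(fit$curves$train_loss)))
  expect_true(all(is.finite(fit$curves$val_loss)))
  expect_lte(fit$epochs_run, cfg$max_epochs)
  if (fit$epochs_run < cfg$max_epochs)
    expect_equal(fit$epochs_run, fit$best_epoch + cfg$early_stop_patience)
  # the restored best checkpoint scores its recorded validation loss
  expect_equal(min(fit$curves$val_loss),
               fit$curves$val_loss[fit$best_epoch])
})

test_that("training is bit-reproducible under a fixed seed", {
  pairs <- training_fixture(n = 8)
  cfg <- train_config(max_epochs = 4L, early_stop_patience = 2L, seed = 9)
  f1 <- model_fit(unet_tiny(seed = 4), pairs, cfg)
  f2 <- model_fit(unet_tiny(seed = 4), pairs, cfg)
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("mixed-shape training sets are batched without error", {
  cfg <- tiny_synth_config(seed = 31, n = 48L)
  d <- generate_dataset(4, cfg)
  frames <- lapply(d, function(e) list(image = e$image$pixels, mask = e$mask))
  crops <- training_fixture(n = 6, seed = 31)
  fit <- model_fit(unet_tiny(seed = 2), c(frames, crops),
                   train_config(max_epochs = 2L, early_stop_patience = 2L, seed = 3))
  expect_equal(fit$epochs_run, 2L)
})

test_that("empty training sets are rejected", {
  expect_error(model_fit(unet_tiny(seed = 1), list(), train_config()),
               "no training pairs")
})
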