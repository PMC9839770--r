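test_that("flips are exact involutions and rotate-by-zero is the identity", {
  set.seed(8)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- random_mask(32, 32, 0.2)
  spec <- augmentation_spec()
  for (tr in c("hflip", "vflip")) {
    once <- transform_pair(img, msk, tr, spec)
    twice <- transform_pair(once$image, once$mask, tr, spec)
    expect_identical(twice$image, img)
    expect_identical(twice$mask, msk)
    expect_equal(sum(once$mask), sum(msk))     # flips preserve area exactly
  }
  zero <- transform_pair(img, msk, "rotate", augmentation_spec(rotation_deg = 0))
  expect_equal(zero$image, img)
  expect_identical(zero$mask, msk)
  noshear <- transform_pair(img, msk, "shear", augmentation_spec(shear_factor = 0))
  expect_identical(noshear$mask, msk)
})

test_that("vflip sends the top row to the bottom row", {
  h <- 12
  msk <- matrix(0L, h, 9); msk[1, ] <- 1L
  out <- transform_pair(matrix(0, h, 9), msk, "vflip")
  expect_equal(which(rowSums(out$mask) > 0), h)
})

test_that("augment_pair emits the enabled transforms in order with binary masks", {
  set.seed(15)
  img <- matrix(runif(24 * 24), 24, 24)
  msk <- matrix(0L, 24, 24); msk[9:15, 10:16] <- 1L
  out <- augment_pair(img, msk)
  expect_length(out, 5)
  expect_identical(out[[1]]$image, img)
  expect_identical(out[[1]]$mask, msk)
  expect_equal(vapply(out, function(p) p$transform, ""),
               c("identity", "hflip", "vflip", "rotate", "shear"))
  for (p in out) {
    expect_true(all(p$mask %in% c(0L, 1L)))
    expect_equal(dim(p$mask), dim(msk))
  }
  # resampling keeps foreground area within 25% for the warped transforms
  areas <- vapply(out, function(p) sum(p$mask), 0L)
  expect_true(all(abs(areas - sum(msk)) / sum(msk) <= 0.25))

  zero <- augment_pair(img, matrix(0L, 24, 24))
  expect_true(all(vapply(zero, function(p) sum(p$mask), 0L) == 0L))
})

test_that("dataset expansion factor equals the number of enabled transforms", {
  set.seed(30)
  mk <- function(n) lapply(seq_len(n), function(i)
    list(image = matrix(runif(64), 8, 8), mask = random_mask(8, 8), id = paste0("p", i)))
  expect_length(augment_dataset(mk(127)), 635)
  expect_length(augment_dataset(list()), 0)
  two <- augmentation_spec(transforms = c("identity", "hflip"))
  out <- augment_dataset(mk(10), two)
  expect_length(out, 20)
  expect_equal(unique(vapply(out, function(p) p$transform, "")),
               c("identity", "hflip"))
  expect_equal(vapply(out[1:2], function(p) p$id, ""), c("p1", "p1"))
})

test_that("unknown transforms are rejected", {
  expect_error(augmentation_spec(transforms = c("identity", "zoom")), "zoom")
  expect_error(transform_pair(matrix(0, 4, 4), matrix(0L, 4, 4), "rotate",
                              augmentation_spec(transforms = "identity")),
               "not enabled")
})
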