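test_that("direct conv kernels match the im2col expansion", {
  set.seed(61)
  H <- 13; W <- 9; C <- 4; F <- 5
  X <- matrix(rnorm(H * W * C), H * W, C)
  Wm <- matrix(rnorm(9 * C * F), 9 * C, F)
  b <- rnorm(F)
  Z <- ccseg:::im2col3(X, H, W) %*% Wm + rep(b, each = H * W)
  A <- ccseg:::conv3_fwd(X, Wm, b, H, W, TRUE)
  expect_equal(A, pmax(Z, 0), tolerance = 1e-13)

  dA <- matrix(rnorm(H * W * F), H * W, F)
  bw <- ccseg:::conv3_bwd(X, A, dA, Wm, H, W, TRUE)
  dZ <- dA * (Z > 0)
  expect_equal(bw$dW, crossprod(ccseg:::im2col3(X, H, W), dZ), tolerance = 1e-12)
  expect_equal(as.numeric(bw$db), colSums(dZ), tolerance = 1e-12)
  expect_equal(bw$dX, ccseg:::col2im3(dZ %*% t(Wm), H, W, C), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny net", {
  set.seed(62)
  model <- unet_tiny(channels = c(2L, 3L, 4L), seed = 5)
  img <- matrix(runif(64), 8, 8)
  msk <- matrix(0L, 8, 8); msk[3:5, 4:6] <- 1L
  lg <- ccseg:::unet_loss_grad(model, img, msk)
  h <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    picks <- sample(length(p), min(4, length(p)))
    for (i in picks) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + h
      up <- ccseg:::unet_loss_grad(m2, img, msk)$loss
      m2$params[[nm]][i] <- p[i] - h
      dn <- ccseg:::unet_loss_grad(m2, img, msk)$loss
      expect_equal(lg$grads[[nm]][i], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("the fused C++ pass reproduces the R reference layer stack", {
  set.seed(63)
  model <- unet_tiny(seed = 11)
  for (dims in list(c(32, 32), c(44, 52))) {   # exact and padded shapes
    img <- matrix(runif(prod(dims)), dims[1], dims[2])
    msk <- matrix(as.integer(runif(prod(dims)) < 0.05), dims[1], dims[2])
    fast <- ccseg:::unet_loss_grad(model, img, msk)
    ref <- ccseg:::unet_loss_grad_ref(model, img, msk)
    expect_equal(fast$loss, ref$loss, tolerance = 1e-12)
    for (nm in names(ref$grads))
      expect_equal(fast$grads[[nm]], ref$grads[[nm]], tolerance = 1e-11,
                   ignore_attr = TRUE)
    expect_equal(predict_probs(model, img),
                 ccseg:::unet_forward(model, img)$prob, tolerance = 1e-12)
  }
})

test_that("predictions are probabilities of the input shape, deterministically", {
  model <- unet_tiny(seed = 3)
  img <- matrix(runif(30 * 41), 30, 41)
  p <- predict_probs(model, img)
  expect_equal(dim(p), c(30, 41))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_probs(model, img))
  m <- predict_mask(model, img, threshold = 0)
  expect_true(all(m == 1L))
})

test_that("weight initialisation is seed-reproducible", {
  expect_identical(unet_tiny(seed = 7)$params, unet_tiny(seed = 7)$params)
  expect_false(identical(unet_tiny(seed = 7)$params, unet_tiny(seed = 8)$params))
})

test_that("checkpoints round-trip through save and load", {
  model <- unet_tiny(seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_s3_class(back, "unet_tiny")
  img <- matrix(runif(64), 8, 8)
  expect_identical(predict_probs(back, img), predict_probs(model, img))
})
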