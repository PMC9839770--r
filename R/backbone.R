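# Built-in segmentation backbone: a small fully convolutional
# encoder-decoder (3 max-pool stages, nearest-neighbour upsampling, skip
# connections, sigmoid output) sized to train in seconds-to-minutes on one
# CPU core.  Activations are (H*W) x C matrices; convolutions are GEMMs on
# an im2col expansion (see src/convops.cpp).  Any model implementing the
# predict_probs()/model_fit()/save_checkpoint() generics can replace it in
# the pipeline.

#' Segmentation model contract
#'
#' A segmentation model maps a grayscale image (intensity matrix on \[0, 1\])
#' to a same-shaped matrix of per-pixel foreground probabilities.  Any object
#' with methods for \code{predict_probs} and \code{model_fit} can serve as a
#' teacher or student backbone in the self-training pipeline.
#'
#' @param model A model object.
#' @param image A \code{\link{radiograph}} or intensity matrix.
#' @return \code{predict_probs}: numeric matrix of probabilities in
#'   \[0, 1\], same shape as the input.
#' @export
predict_probs <- function(model, image) UseMethod("predict_probs")

#' @rdname predict_probs
#' @param pairs Training pairs: list of \code{list(image, mask)}.
#' @param config A \code{\link{train_config}}.
#' @export
model_fit <- function(model, pairs, config) UseMethod("model_fit")

#' Binarise a model's probability map into a mask
#'
#' @inheritParams predict_probs
#' @param threshold Probability cut (default 0.5).
#' @return Integer 0/1 mask.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  p <- predict_probs(model, image)
  matrix(as.integer(p >= threshold), nrow(p), ncol(p))
}

#' Create the built-in tiny encoder-decoder backbone
#'
#' Three encoder stages (3x3 conv + ReLU + 2x2 max-pool), a bottleneck conv,
#' and three decoder stages (2x nearest upsample, skip concatenation, then a
#' 3x3 conv + ReLU at the two coarse levels and a 1x1 fusion at full
#' resolution), finished by a 1x1 conv and sigmoid.  Inputs of any size are
#' handled by internal zero-padding to a multiple of 8.  Weights use He
#' initialisation under the given seed.
#'
#' @param channels Integer vector of length 3: channel widths of the three
#'   encoder stages (the bottleneck reuses the third).
#' @param seed Seed for weight initialisation.
#' @return An object of class \code{unet_tiny}.
#' @export
unet_tiny <- function(channels = c(8L, 16L, 32L), seed = 1L) {
  stopifnot(length(channels) == 3L, all(channels >= 1L))
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(draw_seed(seed, 0L))
  he <- function(fan_in, nout) matrix(rnorm(fan_in * nout, 0, sqrt(2 / fan_in)),
                                      fan_in, nout)
  params <- list(
    W1 = he(9 * 1, c1),       b1 = numeric(c1),
    W2 = he(9 * c1, c2),      b2 = numeric(c2),
    W3 = he(9 * c2, c3),      b3 = numeric(c3),
    W4 = he(9 * c3, c3),      b4 = numeric(c3),
    W5 = he(9 * 2 * c3, c2),  b5 = numeric(c2),
    W6 = he(9 * 2 * c2, c1),  b6 = numeric(c1),
    W7 = he(2 * c1, c1),      b7 = numeric(c1),
    W8 = he(c1, 1),           b8 = numeric(1)
  )
  structure(list(params = params, channels = as.integer(channels),
                 seed = as.integer(seed)),
            class = c("unet_tiny", "seg_model"))
}

#' @export
print.unet_tiny <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<unet_tiny backbone: channels %s, %d parameters>\n",
              paste(x$channels, collapse = "/"), np))
  invisible(x)
}

# ---- index caches for pooling / upsampling ------------------------------

.shape_cache <- new.env(parent = emptyenv())

pool_indices <- function(H, W) {
  key <- paste0("p", H, "x", W)
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  h2 <- H %/% 2L; w2 <- W %/% 2L
  ro <- rep(seq_len(h2), times = w2); co <- rep(seq_len(w2), each = h2)
  i00 <- (2L * ro - 1L) + (2L * co - 2L) * H
  val <- list(i00, i00 + 1L, i00 + H, i00 + H + 1L)
  .shape_cache[[key]] <- val
  val
}

upsample_indices <- function(H, W) {
  # maps output (2H x 2W) pixel rows to input pixel rows
  key <- paste0("u", H, "x", W)
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  orow <- rep(seq_len(2L * H), times = 2L * W)
  ocol <- rep(seq_len(2L * W), each = 2L * H)
  val <- ((orow + 1L) %/% 2L) + (((ocol + 1L) %/% 2L) - 1L) * H
  .shape_cache[[key]] <- val
  val
}

maxpool_fwd <- function(X, H, W) {
  idx <- pool_indices(H, W)
  M <- X[idx[[1]], , drop = FALSE]
  A <- matrix(idx[[1]], nrow(M), ncol(M))
  for (k in 2:4) {
    cand <- X[idx[[k]], , drop = FALSE]
    upd <- cand > M
    M[upd] <- cand[upd]
    A[upd] <- matrix(idx[[k]], nrow(M), ncol(M))[upd]
  }
  list(out = M, argmax = A)
}

maxpool_bwd <- function(dY, argmax, H, W) {
  C <- ncol(dY)
  dX <- matrix(0, H * W, C)
  off <- rep((seq_len(C) - 1L) * H * W, each = nrow(dY))
  dX[as.vector(argmax) + off] <- as.vector(dY)
  dX
}

upsample_fwd <- function(X, H, W) X[upsample_indices(H, W), , drop = FALSE]

upsample_bwd <- function(dY, H, W) {
  g <- upsample_indices(H, W)
  out <- rowsum(dY, group = g) # groups 1..H*W all occur; rows come back sorted
  dimnames(out) <- NULL
  out
}

conv_fwd <- function(X, Wm, b, H, W, relu = TRUE) {
  Xcol <- im2col3(X, H, W)
  Z <- Xcol %*% Wm
  Z <- Z + rep(b, each = nrow(Z))
  list(out = if (relu) pmax(Z, 0) else Z, Xcol = Xcol, Z = Z)
}

conv_bwd <- function(dA, cache, Wm, Cin, H, W, relu = TRUE) {
  dZ <- if (relu) dA * (cache$Z > 0) else dA
  list(dW = crossprod(cache$Xcol, dZ),
       db = colSums(dZ),
       dX = col2im3(dZ %*% t(Wm), H, W, Cin))
}

pad_to_mult8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  H8 <- 8L * ((H + 7L) %/% 8L); W8 <- 8L * ((W + 7L) %/% 8L)
  if (H8 == H && W8 == W) return(list(m = m, H = H, W = W, padded = FALSE))
  out <- matrix(0, H8, W8)
  out[seq_len(H), seq_len(W)] <- m
  list(m = out, H = H, W = W, padded = TRUE)
}

# Full forward pass.  Returns the probability map (cropped to the original
# shape) and, if keep_cache, everything backward() needs.
unet_forward <- function(model, image, keep_cache = FALSE) {
  pd <- pad_to_mult8(if (is_radiograph(image)) image$pixels else image)
  H <- nrow(pd$m); W <- ncol(pd$m)
  p <- model$params
  c1 <- model$channels[1]; c2 <- model$channels[2]; c3 <- model$channels[3]
  X0 <- matrix(as.vector(pd$m), H * W, 1)

  l1 <- conv_fwd(X0, p$W1, p$b1, H, W)                      # H,   c1
  p1 <- maxpool_fwd(l1$out, H, W)                           # H/2
  l2 <- conv_fwd(p1$out, p$W2, p$b2, H / 2, W / 2)          # H/2, c2
  p2 <- maxpool_fwd(l2$out, H / 2, W / 2)                   # H/4
  l3 <- conv_fwd(p2$out, p$W3, p$b3, H / 4, W / 4)          # H/4, c3
  p3 <- maxpool_fwd(l3$out, H / 4, W / 4)                   # H/8
  l4 <- conv_fwd(p3$out, p$W4, p$b4, H / 8, W / 8)          # H/8, c3

  u3 <- upsample_fwd(l4$out, H / 8, W / 8)                  # H/4, c3
  k5 <- cbind(u3, l3$out)                                   # H/4, 2c3
  l5 <- conv_fwd(k5, p$W5, p$b5, H / 4, W / 4)              # H/4, c2
  u2 <- upsample_fwd(l5$out, H / 4, W / 4)                  # H/2, c2
  k6 <- cbind(u2, l2$out)                                   # H/2, 2c2
  l6 <- conv_fwd(k6, p$W6, p$b6, H / 2, W / 2)              # H/2, c1
  u1 <- upsample_fwd(l6$out, H / 2, W / 2)                  # H,   c1
  k7 <- cbind(u1, l1$out)                                   # H,   2c1
  # full-resolution fusion of skip + decoder is 1x1: spatial context comes
  # from the pyramid below; this keeps the most expensive level cheap
  z7 <- k7 %*% p$W7 + rep(p$b7, each = nrow(k7))
  a7 <- pmax(z7, 0)

  z8 <- a7 %*% p$W8 + p$b8
  prob_full <- matrix(1 / (1 + exp(-z8)), H, W)
  prob <- prob_full[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, prob_full = prob_full, H = H, W = W, orig = c(pd$H, pd$W),
       l1 = l1, p1 = p1, l2 = l2, p2 = p2, l3 = l3, p3 = p3, l4 = l4,
       l5 = l5, l6 = l6, k7 = k7, z7 = z7, a7 = a7)
}

# Backward pass from d(loss)/d(logit) on the padded frame.  Returns the
# gradient list, same names/shapes as model$params.
unet_backward <- function(model, cache, dlogit) {
  p <- model$params
  c1 <- model$channels[1]; c2 <- model$channels[2]; c3 <- model$channels[3]
  H <- cache$H; W <- cache$W
  dz8 <- matrix(as.vector(dlogit), H * W, 1)
  g <- list()
  g$W8 <- crossprod(cache$a7, dz8)
  g$b8 <- sum(dz8)
  da7 <- dz8 %*% t(p$W8)
  dz7 <- da7 * (cache$z7 > 0)
  g$W7 <- crossprod(cache$k7, dz7)
  g$b7 <- colSums(dz7)
  dk7 <- dz7 %*% t(p$W7)
  du1 <- dk7[, seq_len(c1), drop = FALSE]
  dl1_skip <- dk7[, c1 + seq_len(c1), drop = FALSE]
  d6 <- upsample_bwd(du1, H / 2, W / 2)
  b6 <- conv_bwd(d6, cache$l6, p$W6, 2 * c2, H / 2, W / 2)
  g$W6 <- b6$dW; g$b6 <- b6$db
  du2 <- b6$dX[, seq_len(c2), drop = FALSE]
  dl2_skip <- b6$dX[, c2 + seq_len(c2), drop = FALSE]
  d5 <- upsample_bwd(du2, H / 4, W / 4)
  b5 <- conv_bwd(d5, cache$l5, p$W5, 2 * c3, H / 4, W / 4)
  g$W5 <- b5$dW; g$b5 <- b5$db
  du3 <- b5$dX[, seq_len(c3), drop = FALSE]
  dl3_skip <- b5$dX[, c3 + seq_len(c3), drop = FALSE]
  d4 <- upsample_bwd(du3, H / 8, W / 8)
  b4 <- conv_bwd(d4, cache$l4, p$W4, c3, H / 8, W / 8)
  g$W4 <- b4$dW; g$b4 <- b4$db
  dp3 <- maxpool_bwd(b4$dX, cache$p3$argmax, H / 4, W / 4)
  b3 <- conv_bwd(dp3 + dl3_skip, cache$l3, p$W3, c2, H / 4, W / 4)
  g$W3 <- b3$dW; g$b3 <- b3$db
  dp2 <- maxpool_bwd(b3$dX, cache$p2$argmax, H / 2, W / 2)
  b2 <- conv_bwd(dp2 + dl2_skip, cache$l2, p$W2, c1, H / 2, W / 2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  dp1 <- maxpool_bwd(b2$dX, cache$p1$argmax, H, W)
  b1 <- conv_bwd(dp1 + dl1_skip, cache$l1, p$W1, 1L, H, W)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g[names(model$params)]
}

# Loss + gradient for one image/mask pair (mean BCE over the valid, unpadded
# pixels; padded pixels contribute neither loss nor gradient).  This is the
# R reference path; unet_loss_grad() runs the same computation through the
# fused C++ pass and is tested against this one.
unet_loss_grad_ref <- function(model, image, mask) {
  cache <- unet_forward(model, image, keep_cache = TRUE)
  H0 <- cache$orig[1]; W0 <- cache$orig[2]
  y <- matrix(as.double(mask), H0, W0)
  loss <- bce_loss(cache$prob, mask)
  dlogit <- matrix(0, cache$H, cache$W)
  dlogit[seq_len(H0), seq_len(W0)] <- (cache$prob - y) / (H0 * W0)
  list(loss = loss, grads = unet_backward(model, cache, dlogit))
}

unet_loss_grad <- function(model, image, mask) {
  img <- if (is_radiograph(image)) image$pixels else image
  pd <- pad_to_mult8(img)
  res <- unet_pass_cpp(model$params, pd$m,
                       matrix(as.double(mask), nrow(img), ncol(img)),
                       nrow(img), ncol(img))
  g <- lapply(names(model$params), function(nm) {
    pi <- model$params[[nm]]
    if (is.matrix(pi)) matrix(res$grads[[nm]], nrow(pi), ncol(pi))
    else as.numeric(res$grads[[nm]])
  })
  names(g) <- names(model$params)
  list(loss = res$loss, grads = g)
}

#' @rdname predict_probs
#' @export
predict_probs.unet_tiny <- function(model, image) {
  img <- if (is_radiograph(image)) image$pixels else image
  pd <- pad_to_mult8(img)
  unet_pass_cpp(model$params, pd$m, NULL, nrow(img), ncol(img))$prob
}

#' Save / load a model checkpoint
#'
#' Checkpoints are written with \code{saveRDS}: a list carrying the class,
#' the architecture description and the parameter matrices.
#'
#' @param model A model implementing the contract.
#' @param path Checkpoint file path.
#' @return \code{load_checkpoint} returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(class = class(model), channels = model$channels,
               seed = model$seed, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(params = x$params, channels = x$channels, seed = x$seed),
            class = x$class)
}
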