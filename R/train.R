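# Mini-batch training with Adam, validation-loss early stopping, and
# shape-grouped batches (full frames and crops can sit in one training set;
# a batch only ever mixes items of one shape).

#' Binary cross-entropy loss between probabilities and a binary mask
#'
#' Mean over pixels of \code{-[y log p + (1-y) log(1-p)]} with probabilities
#' clipped to \code{[eps, 1-eps]}.
#'
#' @param pred Numeric matrix of probabilities in \[0, 1\].
#' @param target Aligned integer 0/1 mask.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  stopifnot_aligned(pred, target, "pred and target")
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.double(target)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training configuration
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Fixed learning rate.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Stop after this many consecutive epochs without
#'   validation-loss improvement (improvement = drop larger than
#'   \code{min_delta}).
#' @param validation_fraction Fraction of training pairs held out to monitor
#'   early stopping (at least one pair when the set has two or more).
#' @param min_delta Minimum loss drop that counts as improvement.
#' @param seed Seed controlling validation split, shuffling and any model
#'   initialisation derived from it.
#' @param deterministic If TRUE (default) all randomness is drawn from seeded
#'   streams so repeated runs are bit-identical.
#' @return A \code{train_config} list.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 1e-3,
                         max_epochs = 100L, early_stop_patience = 5L,
                         validation_fraction = 0.1, min_delta = 1e-4,
                         seed = 1L, deterministic = TRUE) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            early_stop_patience >= 1, early_stop_patience <= max_epochs,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 min_delta = min_delta, seed = as.integer(seed),
                 deterministic = isTRUE(deterministic)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

normalise_pair <- function(e) {
  img <- if (is_radiograph(e$image)) e$image$pixels else e$image
  list(image = img, mask = as_seg_mask(e$mask))
}

# Partition indices into mini-batches that never mix item shapes.
shape_batches <- function(pairs, idx, batch_size) {
  shapes <- vapply(pairs[idx], function(e) paste(dim(e$image), collapse = "x"), "")
  batches <- list()
  for (grp in split(idx, shapes)) {
    starts <- seq(1, length(grp), by = batch_size)
    for (s in starts)
      batches[[length(batches) + 1L]] <- grp[s:min(s + batch_size - 1, length(grp))]
  }
  batches
}

#' Train a segmentation model by mini-batch gradient descent
#'
#' Minimises mean-pixel binary cross-entropy with the Adam update rule at a
#' fixed learning rate.  A validation fraction of the pairs is held out; the
#' run stops when the validation loss has not improved by more than
#' \code{min_delta} for \code{early_stop_patience} consecutive epochs, or at
#' \code{max_epochs}; the returned model carries the best-validation weights.
#'
#' @param model A model implementing the backbone contract (see
#'   \code{\link{predict_probs}}); the built-in \code{\link{unet_tiny}}.
#' @param pairs Non-empty list of \code{list(image, mask)} training pairs
#'   (shapes may differ between pairs; batches are grouped by shape).
#' @param config A \code{\link{train_config}}.
#' @return \code{list(model, curves, best_epoch, epochs_run)} where
#'   \code{curves} is a data.frame with per-epoch train and validation loss.
#' @export
train_segmentation_model <- function(model, pairs, config = train_config()) {
  model_fit(model, pairs, config)
}

#' @rdname predict_probs
#' @export
model_fit.unet_tiny <- function(model, pairs, config = train_config()) {
  if (length(pairs) == 0L) stop("no training pairs", call. = FALSE)
  pairs <- lapply(pairs, normalise_pair)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(draw_seed(config$seed, 1L))

  n <- length(pairs)
  n_val <- if (n >= 2L) max(1L, round(config$validation_fraction * n)) else 0L
  val_idx <- if (n_val > 0) sort(sample(n, n_val)) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) { tr_idx <- val_idx; val_idx <- integer(0) }

  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  curves <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(tr_idx)
    batches <- shape_batches(pairs, perm, config$batch_size)
    if (length(batches) > 1L) batches <- batches[sample(length(batches))]
    ep_loss <- 0; ep_n <- 0L
    for (bt in batches) {
      grads <- NULL
      for (i in bt) {
        lg <- unet_loss_grad(model, pairs[[i]]$image, pairs[[i]]$mask)
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        ep_loss <- ep_loss + lg$loss; ep_n <- ep_n + 1L
        grads <- if (is.null(grads)) lg$grads else Map(`+`, grads, lg$grads)
      }
      grads <- lapply(grads, function(g) g / length(bt))
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params; state <- upd$state
    }
    train_loss <- ep_loss / ep_n
    val_loss <- if (length(val_idx)) {
      mean(vapply(val_idx, function(i)
        bce_loss(predict_probs(model, pairs[[i]]$image), pairs[[i]]$mask), 0))
    } else train_loss
    curves <- rbind(curves, data.frame(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss))
    if (val_loss < best$loss - config$min_delta) {
      best <- list(loss = val_loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  list(model = model, curves = curves, best_epoch = best$epoch,
       epochs_run = nrow(curves))
}
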