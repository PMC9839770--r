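# Seeded generator of radiograph-like test images: a dark background, a row
# of bright tooth-like ellipses, and a few small dark lesion blobs on tooth
# boundaries.  The point is the pixel statistics -- ~300x300 frames with
# ~10x10 lesions give a foreground fraction of roughly 0.1%, the imbalance
# regime that motivates centroid cropping -- not photorealism.

#' Configuration for the synthetic radiograph generator
#'
#' @param height,width Frame size in pixels.
#' @param n_teeth Number of bright elliptical tooth-like structures.
#' @param lesions_range Integer range \code{c(min, max)}: number of lesions
#'   drawn uniformly per image.
#' @param lesion_side_mean,lesion_side_sd Lesion side (pixels): each lesion's
#'   nominal side is drawn from Normal(mean, sd), clipped to
#'   \code{[2, min(height, width)/4]}; the blob covers about side^2 pixels.
#' @param lesion_contrast Intensity drop of lesion pixels relative to the
#'   underlying tooth, in (0, 1].
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian pixel noise.
#' @param seed Base seed; together with a draw index it fully determines each
#'   image, independent of generation order.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(height = 300L, width = 300L, n_teeth = 6L,
                             lesions_range = c(1L, 3L),
                             lesion_side_mean = 10, lesion_side_sd = 2,
                             lesion_contrast = 0.3, noise_sd = 0.03,
                             seed = 1L) {
  stopifnot(height >= 8, width >= 8, n_teeth >= 1,
            length(lesions_range) == 2L,
            lesions_range[1] >= 0, lesions_range[2] >= lesions_range[1],
            lesion_side_mean >= 2, lesion_side_sd >= 0,
            lesion_contrast > 0, lesion_contrast <= 1, noise_sd >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_teeth = as.integer(n_teeth),
                 lesions_range = as.integer(lesions_range),
                 lesion_side_mean = lesion_side_mean,
                 lesion_side_sd = lesion_side_sd,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Mix a base seed with a draw index into a single 31-bit stream seed.
draw_seed <- function(seed, draw_index) {
  as.integer((as.double(seed) * 69069 + as.double(draw_index) * 40503 + 17) %%
               2147483629)
}

#' Generate one synthetic radiograph with its ground-truth lesion mask
#'
#' Fully reproducible from \code{(config$seed, draw_index)}.  The mask's
#' foreground is exactly the set of pixels whose intensity was reduced by a
#' lesion; lesions never touch each other, so the number of 8-connected mask
#' components equals the number of placed lesions.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param draw_index Non-negative integer index of the draw.
#' @return \code{list(id, image, mask)} with \code{image} a
#'   \code{\link{radiograph}} and \code{mask} an integer 0/1 matrix.
#' @export
generate_radiograph <- function(config, draw_index = 0L) {
  stopifnot(inherits(config, "synthetic_config"), draw_index >= 0)
  H <- config$height; W <- config$width
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(draw_seed(config$seed, draw_index))

  img <- matrix(0.15, H, W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  # one row of bright tooth-like ellipses
  for (k in seq_len(config$n_teeth)) {
    cx <- W * (k - 0.5) / config$n_teeth + runif(1, -0.05, 0.05) * W / config$n_teeth
    cy <- H * 0.5 + runif(1, -0.06, 0.06) * H
    a <- 0.40 * W / config$n_teeth * runif(1, 0.85, 1.0)
    b <- 0.30 * H * runif(1, 0.85, 1.0)
    inside <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1
    img[inside] <- 0.7 + runif(1, -0.05, 0.05)
  }
  teeth <- img > 0.4

  mask <- matrix(0L, H, W)
  n_lesions <- if (config$lesions_range[2] == 0L) 0L else
    sample(seq(config$lesions_range[1], config$lesions_range[2]), 1L)
  side_cap <- min(H, W) / 4
  placed <- 0L
  attempts <- 0L
  while (placed < n_lesions && attempts < 100L * n_lesions) {
    attempts <- attempts + 1L
    s <- min(max(rnorm(1, config$lesion_side_mean, config$lesion_side_sd), 2), side_cap)
    ctr <- lesion_centre(config, H, W, s)
    sup <- lesion_support(ctr[1], ctr[2], s, H, W)
    if (is.null(sup)) next
    # keep lesions separated by >= 2 px so components stay distinct
    box <- c(max(1, min(sup$r) - 2), max(1, min(sup$c) - 2),
             min(H, max(sup$r) + 2), min(W, max(sup$c) + 2))
    if (any(mask[box[1]:box[3], box[2]:box[4]] == 1L)) next
    idx <- cbind(sup$r, sup$c)
    mask[idx] <- 1L
    img[idx] <- img[idx] - config$lesion_contrast * (0.5 + 0.5 * sup$g)
    placed <- placed + 1L
  }

  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(H * W, 0, config$noise_sd), H, W)
  img <- pmin(pmax(img, 0), 1)

  id <- sprintf("synth%05d", draw_index)
  list(id = id, image = radiograph(img, id = id), mask = mask)
}

# A point on the boundary of a randomly chosen tooth ellipse, biased so the
# whole blob stays at least a couple of pixels inside the frame.
lesion_centre <- function(config, H, W, s) {
  k <- sample(config$n_teeth, 1L)
  cx <- W * (k - 0.5) / config$n_teeth
  cy <- H * 0.5
  a <- 0.38 * W / config$n_teeth
  b <- 0.28 * H
  phi <- runif(1, 0, 2 * pi)
  r <- cy + b * sin(phi)
  c <- cx + a * cos(phi)
  pad <- s / 2 + 2
  c(min(max(r, 1 + pad), H - pad), min(max(c, 1 + pad), W - pad))
}

# Thresholded anisotropic Gaussian bump with jittered edges; returns the
# 8-connected component containing the centre, as rows/cols plus the bump
# value (normalised to [0, 1]) at each support pixel.
lesion_support <- function(r0, c0, s, H, W) {
  rad <- ceiling(s)
  rr <- max(1, floor(r0 - rad)):min(H, ceiling(r0 + rad))
  cc <- max(1, floor(c0 - rad)):min(W, ceiling(c0 + rad))
  if (length(rr) < 2 || length(cc) < 2) return(NULL)
  e <- runif(1, 0.8, 1.25)
  theta <- runif(1, 0, pi)
  su <- s / 2 * e; sv <- s / 2 / e
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  g <- exp(-0.5 * ((u / su)^2 + (v / sv)^2))
  # threshold so the clean support area is ~ s^2; jitter makes edges ragged
  gn <- g + matrix(runif(length(g), -0.04, 0.04), nrow(g))
  sup <- matrix(as.integer(gn >= exp(-2 / pi)), nrow(g))
  if (sum(sup) < 4) return(NULL)
  lab <- label_components8(sup)
  ctr_lab <- lab[which.min(abs(rr - r0)), which.min(abs(cc - c0))]
  if (ctr_lab == 0L) return(NULL)
  keep <- which(lab == ctr_lab, arr.ind = TRUE)
  if (nrow(keep) < 4) return(NULL)
  list(r = rr[keep[, 1]], c = cc[keep[, 2]],
       g = g[keep] / max(g[keep]))
}

#' Generate a seeded synthetic dataset
#'
#' @param n Number of image/mask pairs.
#' @param config A \code{\link{synthetic_config}}.
#' @return List of \code{n} entries as returned by
#'   \code{\link{generate_radiograph}} with draw indices \code{0..n-1}.
#' @export
generate_dataset <- function(n, config = synthetic_config()) {
  stopifnot(n >= 0)
  lapply(seq_len(n) - 1L, function(i) generate_radiograph(config, i))
}

#' Write a dataset to images/, masks/ and a manifest TSV
#'
#' @param dataset List of \code{list(id, image, mask)} entries.
#' @param dir Output directory (created if needed).
#' @return The manifest as a data.frame (id, n_lesions, fg_pixels), invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(id = character(0), n_lesions = integer(0),
                    fg_pixels = integer(0))
  for (e in dataset) {
    write_radiograph(e$image, file.path(dir, "images", paste0(e$id, ".png")))
    write_mask_image(e$mask, file.path(dir, "masks", paste0(e$id, ".png")))
    man <- rbind(man, data.frame(
      id = e$id, n_lesions = length(find_components(e$mask)),
      fg_pixels = sum(e$mask)))
  }
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(man)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
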