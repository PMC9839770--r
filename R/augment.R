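# Deterministic five-way joint augmentation of image/mask pairs: identity,
# horizontal flip, vertical flip, rotation, x-shear.  Angles and magnitudes
# are fixed (not drawn per item) so the dataset expansion factor is exact
# and a run is reproducible without tracking extra random state.

#' Augmentation specification
#'
#' @param rotation_deg Rotation angle in degrees, applied about the patch
#'   centre; must lie in (-180, 180].
#' @param shear_factor Horizontal shear factor (columns shift proportionally
#'   to the row offset from the centre).
#' @param fill Intensity/label used for pixels mapped from outside the patch.
#' @param transforms Ordered character vector of enabled transforms, a subset
#'   of \code{c("identity", "hflip", "vflip", "rotate", "shear")}.
#' @return An \code{augmentation_spec} list.
#' @export
augmentation_spec <- function(rotation_deg = 15, shear_factor = 0.2, fill = 0,
                              transforms = c("identity", "hflip", "vflip",
                                             "rotate", "shear")) {
  stopifnot(rotation_deg > -180, rotation_deg <= 180, is.finite(shear_factor))
  known <- c("identity", "hflip", "vflip", "rotate", "shear")
  bad <- setdiff(transforms, known)
  if (length(bad)) stop("unknown transform(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(rotation_deg = rotation_deg, shear_factor = shear_factor,
                 fill = fill, transforms = transforms),
            class = "augmentation_spec")
}

# Inverse-mapping affine warp about the patch centre; output shape equals
# input shape.  minv maps output (row, col) offsets to source offsets.
warp_affine <- function(m, minv, filter = c("bilinear", "nearest"), fill = 0) {
  filter <- match.arg(filter)
  H <- nrow(m); W <- ncol(m)
  ctr_r <- (H + 1) / 2; ctr_c <- (W + 1) / 2
  or <- matrix(seq_len(H) - ctr_r, H, W)
  oc <- matrix(seq_len(W) - ctr_c, H, W, byrow = TRUE)
  sr <- ctr_r + minv[1, 1] * or + minv[1, 2] * oc
  sc <- ctr_c + minv[2, 1] * or + minv[2, 2] * oc
  out <- matrix(fill, H, W)
  if (filter == "nearest") {
    ri <- floor(sr + 0.5); ci <- floor(sc + 0.5)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- m[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    acc <- matrix(0, H, W)
    for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      rr <- r0 + corner[1]; cc <- c0 + corner[2]
      w <- (if (corner[1] == 0) 1 - fr else fr) *
           (if (corner[2] == 0) 1 - fc else fc)
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      v <- matrix(fill, H, W)
      v[ok] <- m[cbind(rr[ok], cc[ok])]
      acc <- acc + w * v
    }
    out <- acc
  }
  out
}

#' Apply one named transform jointly to an image and its mask
#'
#' Flips are exact permutations of pixels; rotation and shear resample the
#' image bilinearly and the mask by nearest neighbour, after which the mask
#' is re-binarised at 0.5.  Pixels mapped from outside the patch take
#' \code{spec$fill}.
#'
#' @param image Intensity matrix.
#' @param mask Integer 0/1 matrix aligned with \code{image}.
#' @param transform One of \code{spec$transforms}.
#' @param spec An \code{\link{augmentation_spec}}.
#' @return \code{list(image, mask)} with unchanged shapes.
#' @export
transform_pair <- function(image, mask, transform,
                           spec = augmentation_spec()) {
  mask <- as_seg_mask(mask)
  stopifnot_aligned(image, mask)
  if (!transform %in% spec$transforms)
    stop("transform '", transform, "' is not enabled in the spec", call. = FALSE)
  switch(transform,
    identity = list(image = image, mask = mask),
    hflip = list(image = image[, rev(seq_len(ncol(image))), drop = FALSE],
                 mask = mask[, rev(seq_len(ncol(mask))), drop = FALSE]),
    vflip = list(image = image[rev(seq_len(nrow(image))), , drop = FALSE],
                 mask = mask[rev(seq_len(nrow(mask))), , drop = FALSE]),
    rotate = {
      th <- spec$rotation_deg * pi / 180
      # inverse of a rotation by th is a rotation by -th
      minv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      warp_pair(image, mask, minv, spec$fill)
    },
    shear = {
      # forward: col' = col + k * (row - centre); rows unchanged
      minv <- matrix(c(1, -spec$shear_factor, 0, 1), 2, 2)
      warp_pair(image, mask, minv, spec$fill)
    }
  )
}

warp_pair <- function(image, mask, minv, fill) {
  wm <- warp_affine(mask, minv, filter = "nearest", fill = fill)
  wm <- matrix(as.integer(wm >= 0.5), nrow(mask), ncol(mask))
  list(image = warp_affine(image, minv, filter = "bilinear", fill = fill),
       mask = wm)
}

#' Expand one pair into one pair per enabled transform
#'
#' @inheritParams transform_pair
#' @return List with one \code{list(image, mask, transform)} per enabled
#'   transform, in spec order (default 5, the first being the unmodified
#'   input).
#' @export
augment_pair <- function(image, mask, spec = augmentation_spec()) {
  lapply(spec$transforms, function(tr) {
    p <- transform_pair(image, mask, tr, spec)
    list(image = p$image, mask = p$mask, transform = tr)
  })
}

#' Expand a dataset by the enabled transforms
#'
#' Output size is exactly \code{length(spec$transforms)} times the input
#' size; each output records its source id and transform name.
#'
#' @param pairs List of pairs; each entry needs \code{image} and \code{mask}
#'   fields (\code{\link{ccs_sample_pair}} output works directly).
#' @param spec An \code{\link{augmentation_spec}}.
#' @return Flat list of \code{list(image, mask, id, transform)}.
#' @export
augment_dataset <- function(pairs, spec = augmentation_spec()) {
  out <- vector("list", length(pairs) * length(spec$transforms))
  j <- 0L
  for (e in pairs) {
    img <- if (is_radiograph(e$image)) e$image$pixels else e$image
    id <- if (!is.null(e$id)) e$id else "img"
    for (p in augment_pair(img, e$mask, spec)) {
      j <- j + 1L
      out[[j]] <- list(image = p$image, mask = p$mask, id = id,
                       transform = p$transform)
    }
  }
  out
}
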