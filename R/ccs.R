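# Centroid cropping-based sampling (CCS).  Foreground components of a (real
# or pseudo) mask are located, and a fixed-size window centred on each
# component centroid is cut out of both image and mask.  Because lesions are
# tiny relative to the frame, the crops carry a vastly higher foreground
# fraction than the full frames, removing the class-imbalance problem that
# cripples pixel-wise training on raw radiographs.

#' Find 8-connected foreground components of a binary mask
#'
#' @param mask Integer 0/1 matrix.
#' @return List of components ordered by (top row, then left column) of their
#'   bounding boxes.  Each component is a list with \code{pixels} (n x 2
#'   matrix of 1-based (row, col)), \code{centroid} (mean row, mean col),
#'   \code{bbox} (rmin, cmin, rmax, cmax, inclusive) and \code{area}.
#' @export
find_components <- function(mask) {
  mask <- as_seg_mask(mask)
  lab <- label_components8(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  comps <- vector("list", n)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  for (k in seq_len(n)) {
    px <- idx[labv == k, , drop = FALSE]
    comps[[k]] <- list(
      pixels = unname(px),
      centroid = c(mean(px[, 1]), mean(px[, 2])),
      bbox = c(min(px[, 1]), min(px[, 2]), max(px[, 1]), max(px[, 2])),
      area = nrow(px)
    )
  }
  ord <- order(vapply(comps, function(co) co$bbox[1], 0),
               vapply(comps, function(co) co$bbox[2], 0))
  comps[ord]
}

#' Build a boundary-clamped crop window around a centroid
#'
#' The window is square with side \code{crop_size} (per axis, capped at the
#' frame side), positioned so that the rounded centroid sits at its centre,
#' then shifted -- never shrunk or padded -- by the minimum amount needed to
#' lie fully inside the frame.
#'
#' @param centroid Numeric (row, col), 1-based.
#' @param crop_size Window side in pixels.
#' @param frame Integer (height, width) of the source image.
#' @return A \code{crop_window}: list with 1-based inclusive \code{row},
#'   \code{col} of the top-left corner plus \code{height} and \code{width}.
#' @export
make_crop_window <- function(centroid, crop_size, frame) {
  stopifnot(crop_size >= 1, length(frame) == 2, all(frame >= 1))
  side_h <- min(crop_size, frame[1])
  side_w <- min(crop_size, frame[2])
  # round half away from zero so placement is platform-independent
  top <- floor(centroid[1] + 0.5) - floor(side_h / 2)
  left <- floor(centroid[2] + 0.5) - floor(side_w / 2)
  top <- min(max(top, 1), frame[1] - side_h + 1)
  left <- min(max(left, 1), frame[2] - side_w + 1)
  structure(list(row = as.integer(top), col = as.integer(left),
                 height = as.integer(side_h), width = as.integer(side_w)),
            class = "crop_window")
}

window_rows <- function(w) seq.int(w$row, w$row + w$height - 1L)
window_cols <- function(w) seq.int(w$col, w$col + w$width - 1L)

#' Extract centroid-centred crops from one image/mask pair
#'
#' One crop per foreground component.  If a component's bounding box exceeds
#' \code{crop_size}, the window side is enlarged to cover the box plus a
#' 2-pixel margin (then clamped to the frame), so no lesion is ever
#' truncated.
#'
#' @param image A \code{\link{radiograph}} or intensity matrix.
#' @param mask Integer 0/1 matrix aligned with \code{image}.
#' @param crop_size Nominal window side (default 32).
#' @param min_area Components smaller than this many pixels are skipped
#'   (default 1: keep everything).
#' @param id Source identifier recorded in each crop.
#' @return List of \code{cropped_pair} objects: \code{list(image, mask, id,
#'   component, window)}; empty list for an empty mask.
#' @export
ccs_sample_pair <- function(image, mask, crop_size = 32L, min_area = 1L,
                            id = NULL) {
  if (is_radiograph(image)) {
    if (is.null(id)) id <- image$id
    image <- image$pixels
  }
  if (is.null(id)) id <- "img"
  mask <- as_seg_mask(mask)
  stopifnot_aligned(image, mask)
  frame <- dim(mask)
  comps <- find_components(mask)
  out <- list()
  for (k in seq_along(comps)) {
    co <- comps[[k]]
    if (co$area < min_area) next
    bb_side <- max(co$bbox[3] - co$bbox[1], co$bbox[4] - co$bbox[2]) + 1L
    side <- max(crop_size, bb_side + 4L)
    w <- make_crop_window(co$centroid, side, frame)
    out[[length(out) + 1L]] <- structure(
      list(image = image[window_rows(w), window_cols(w), drop = FALSE],
           mask = mask[window_rows(w), window_cols(w), drop = FALSE],
           id = id, component = k, window = w),
      class = "cropped_pair")
  }
  out
}

#' Extract centroid-centred crops from a dataset
#'
#' @param pairs List of entries \code{list(id, image, mask)} (e.g. from
#'   \code{\link{generate_dataset}}); entries with \code{NULL} or empty masks
#'   contribute no crops.
#' @inheritParams ccs_sample_pair
#' @return Flat list of \code{cropped_pair}s, source order preserved.
#' @export
ccs_sample_dataset <- function(pairs, crop_size = 32L, min_area = 1L) {
  out <- list()
  for (e in pairs) {
    if (is.null(e$mask)) next
    out <- c(out, ccs_sample_pair(e$image, e$mask, crop_size = crop_size,
                                  min_area = min_area, id = e$id))
  }
  out
}
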