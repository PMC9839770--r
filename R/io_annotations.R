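# Image, mask and polygon-annotation input/output.
#
# Coordinate conventions: in memory everything is 1-based [row, col] R matrix
# indexing.  Polygon annotation files (LabelMe JSON dialect) use (x, y) pixel
# coordinates with origin at the top-left and x running along columns; the
# centre of the pixel stored at matrix position [r, c] sits at
# (x = c - 1, y = r - 1) in that frame.

#' Read polygon annotations in the LabelMe JSON dialect
#'
#' Parses a JSON annotation file with top-level keys \code{imageHeight},
#' \code{imageWidth} and \code{shapes}, each shape carrying \code{label} and
#' \code{points} (an n x 2 array of (x, y) vertices).
#'
#' @param path Path to the JSON file.
#' @return A list with elements \code{annotations} (a list of
#'   \code{polygon_annotation} objects, file order preserved), \code{height}
#'   and \code{width}.
#' @export
read_labelme_polygons <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  for (key in c("imageHeight", "imageWidth", "shapes")) {
    if (is.null(doc[[key]]))
      stop("annotation file is missing required key '", key, "': ", path,
           call. = FALSE)
  }
  height <- as.integer(doc$imageHeight)
  width <- as.integer(doc$imageWidth)
  anns <- vector("list", length(doc$shapes))
  for (i in seq_along(doc$shapes)) {
    sh <- doc$shapes[[i]]
    if (is.null(sh$points))
      stop("shape ", i, " is missing required key 'points'", call. = FALSE)
    pts <- sh$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
    pts <- matrix(as.numeric(pts), ncol = 2)
    if (nrow(pts) < 3L)
      stop("shape ", i, " has fewer than 3 vertices", call. = FALSE)
    # clamp vertices into the image frame
    pts[, 1] <- pmin(pmax(pts[, 1], 0), width)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), height)
    anns[[i]] <- polygon_annotation(
      label = if (is.null(sh$label)) "" else as.character(sh$label),
      vertices = pts
    )
  }
  list(annotations = anns, height = height, width = width)
}

#' @rdname read_labelme_polygons
#' @param label Class label string.
#' @param vertices n x 2 numeric matrix of (x, y) vertices, n >= 3.
#' @export
polygon_annotation <- function(label, vertices) {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (nrow(vertices) < 3L)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  structure(list(label = as.character(label), vertices = vertices),
            class = "polygon_annotation")
}

# Even-odd ray-crossing test with explicit boundary inclusion, vectorised
# over query points.  px/py are point coordinates in the annotation frame.
point_in_polygon <- function(px, py, vertices, eps = 1e-9) {
  n <- nrow(vertices)
  xs <- vertices[, 1]; ys <- vertices[, 2]
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # on-segment: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_seg <- abs(cross) <= eps * max(1, sqrt(seg_len2)) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | on_seg
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | boundary
}

#' Rasterise polygon annotations into a binary mask
#'
#' A pixel is foreground iff its centre lies inside or on the boundary of at
#' least one polygon (even-odd fill); overlapping polygons union.
#'
#' @param annotations List of \code{polygon_annotation} objects (possibly
#'   empty).
#' @param height,width Output mask dimensions.
#' @return Integer 0/1 mask of dimension \code{height x width}.
#' @export
rasterize_polygons <- function(annotations, height, width) {
  stopifnot(height >= 1, width >= 1)
  mask <- matrix(0L, height, width)
  if (length(annotations) == 0L) return(mask)
  # pixel centres in the annotation frame
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  for (ann in annotations) {
    v <- if (inherits(ann, "polygon_annotation")) ann$vertices else ann
    hit <- point_in_polygon(px, py, v)
    mask[hit] <- 1L
  }
  mask
}

#' Read and write binary mask images
#'
#' Masks are stored as single-channel 8-bit PNG with 0 = background and
#' 255 = foreground.  On read, any image format supported by
#' \pkg{EBImage} is accepted and binarised at > 127 on the 8-bit scale, so
#' antialiased exports threshold cleanly.  \code{write_mask_image} then
#' \code{read_mask_image} is the identity.
#'
#' @param path File path.
#' @param mask Integer 0/1 matrix.
#' @return \code{read_mask_image}: an integer 0/1 matrix.
#' @export
read_mask_image <- function(path) {
  g <- read_gray_image(path)
  mask <- matrix(0L, nrow(g), ncol(g))
  mask[round(g * 255) > 127] <- 1L
  mask
}

#' @rdname read_mask_image
#' @export
write_mask_image <- function(mask, path) {
  mask <- as_seg_mask(mask)
  png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a grayscale image file as a radiograph
#'
#' PNG, TIFF and JPEG are supported; RGB images are converted to grayscale by
#' luminance.  Intensities are returned on \[0, 1\].
#'
#' @param path Image file path.
#' @param id Identifier; defaults to the file stem.
#' @return A \code{\link{radiograph}}.
#' @export
read_radiograph <- function(path, id = file_stem(path)) {
  radiograph(read_gray_image(path), id = id)
}

read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) != 0) img <- EBImage::channel(img, "luminance")
  m <- EBImage::imageData(img)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (length(m) == 0L) stop("image has zero pixels: ", path, call. = FALSE)
  # EBImage stores x (columns) first; transpose to [row, col]
  m <- t(m)
  pmin(pmax(m, 0), 1)
}

#' Write a radiograph to a grayscale PNG
#'
#' @param image A \code{\link{radiograph}} or intensity matrix.
#' @param path Output path.
#' @export
write_radiograph <- function(image, path) {
  m <- as_intensity_matrix(image)
  png::writePNG(m, path)
  invisible(path)
}

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Load a directory of images with paired masks or annotations
#'
#' Images are matched to masks (or polygon annotation JSON files) by file
#' stem; images with no match are returned unlabelled.  Entries are sorted by
#' image file name, so ordering is deterministic.
#'
#' @param image_dir Directory of PNG/TIFF/JPEG images.
#' @param mask_dir Optional directory of binary mask images.
#' @param annotation_dir Optional directory of LabelMe-dialect JSON files
#'   (used for stems with no mask match).
#' @return A list of entries \code{list(id, image, mask)} where \code{mask} is
#'   \code{NULL} for unlabelled images.
#' @export
load_image_mask_dataset <- function(image_dir, mask_dir = NULL,
                                    annotation_dir = NULL) {
  if (!dir.exists(image_dir)) stop("no such directory: ", image_dir, call. = FALSE)
  img_files <- sort(list.files(image_dir,
                               pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                               ignore.case = TRUE, full.names = TRUE))
  out <- vector("list", length(img_files))
  for (i in seq_along(img_files)) {
    f <- img_files[i]
    stem <- file_stem(f)
    img <- read_radiograph(f, id = stem)
    mask <- NULL
    if (!is.null(mask_dir)) {
      mf <- list.files(mask_dir, pattern = paste0("^", stem, "\\."),
                       full.names = TRUE)
      if (length(mf) > 0) mask <- read_mask_image(sort(mf)[1])
    }
    if (is.null(mask) && !is.null(annotation_dir)) {
      af <- file.path(annotation_dir, paste0(stem, ".json"))
      if (file.exists(af)) {
        ann <- read_labelme_polygons(af)
        mask <- rasterize_polygons(ann$annotations, ann$height, ann$width)
      }
    }
    if (!is.null(mask) && !identical(dim(mask), dim(img$pixels)))
      stop(sprintf("mask/image shape mismatch for '%s': image %s vs mask %s",
                   stem, paste(dim(img$pixels), collapse = "x"),
                   paste(dim(mask), collapse = "x")), call. = FALSE)
    out[[i]] <- list(id = stem, image = img, mask = mask)
  }
  out
}
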