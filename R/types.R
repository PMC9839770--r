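#' Construct a radiograph object
#'
#' A radiograph is a 2-D grayscale intensity grid with an identifier.
#' Intensities live on \[0, 1\]; the matrix is indexed \code{[row, col]} with
#' row 1 at the top of the image.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @param id Character identifier (e.g. the file stem).
#' @return An object of class \code{radiograph}: a list with elements
#'   \code{id}, \code{pixels}, \code{height}, \code{width}.
#' @export
radiograph <- function(pixels, id = "img") {
  pixels <- as_intensity_matrix(pixels)
  structure(
    list(id = as.character(id), pixels = pixels,
         height = nrow(pixels), width = ncol(pixels)),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph '%s' %dx%d, intensity [%.3f, %.3f]>\n",
              x$id, x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @rdname radiograph
#' @param x Object to test.
#' @export
is_radiograph <- function(x) inherits(x, "radiograph")

as_intensity_matrix <- function(pixels) {
  if (is_radiograph(pixels)) pixels <- pixels$pixels
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have positive height and width", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1] with no missing values", call. = FALSE)
  storage.mode(pixels) <- "double"
  pixels
}

#' Validate and coerce a binary segmentation mask
#'
#' Masks are integer matrices over \{0, 1\} aligned pixel-for-pixel with their
#' radiograph; 1 marks lesion (foreground) pixels.
#'
#' @param mask Matrix (numeric or logical) containing only 0/1 (or FALSE/TRUE)
#'   values.
#' @return Integer 0/1 matrix of the same shape.
#' @export
as_seg_mask <- function(mask) {
  if (is.logical(mask)) {
    storage.mode(mask) <- "integer"
  }
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("mask must be a numeric or logical matrix", call. = FALSE)
  if (anyNA(mask) || !all(mask == 0L | mask == 1L))
    stop("mask values must all be 0 or 1", call. = FALSE)
  storage.mode(mask) <- "integer"
  mask
}

stopifnot_aligned <- function(a, b, what = "image and mask") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s shapes differ: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
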