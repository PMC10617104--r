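LABEL_BACKGROUND <- 0L
LABEL_UTERUS <- 1L
LABEL_TUMOR <- 2L

#' Region mask for a label
#'
#' @param mask integer label mask.
#' @param label class label; \code{1} (uterus) includes tumor pixels since the
#'   tumor lies within the uterus.
#' @return logical matrix of the same shape.
#' @export
label_region <- function(mask, label) {
  if (label == LABEL_UTERUS) mask >= LABEL_UTERUS else mask == label
}

# logical lookup of continuous (x, y) points in a mask region; points outside
# the grid are FALSE. Nearest-pixel semantics.
points_in_mask <- function(region, x, y) {
  h <- nrow(region); w <- ncol(region)
  xi <- as.integer(round(x)); yi <- as.integer(round(y))
  ok <- xi >= 0L & xi < w & yi >= 0L & yi < h
  out <- logical(length(x))
  out[ok] <- region[cbind(yi[ok] + 1L, xi[ok] + 1L)]
  out
}

#' Tight bounding box of a mask region
#'
#' @param region logical matrix.
#' @return \code{(x_min, y_min, x_max, y_max)} 0-based half-open, or
#'   \code{NULL} for an empty region.
#' @export
tight_box <- function(region) {
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(x_min = min(idx[, 2L]) - 1L, y_min = min(idx[, 1L]) - 1L,
    x_max = max(idx[, 2L]), y_max = max(idx[, 1L]))
}

#' Read and write 8-bit grayscale PNG images and label masks
#'
#' Images are stored with gray values 0--255; label masks store the raw label
#' values \{0, 1, 2\}.
#'
#' @param path file path.
#' @param image numeric matrix with values in [0, 255].
#' @param mask integer label mask.
#' @name png_io
NULL

#' @rdname png_io
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  round(m * 255)
}

#' @rdname png_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

# largest 8-connected component of a logical region, holes filled
largest_component_filled <- function(region) {
  img <- EBImage::Image(t(region))
  lab <- EBImage::bwlabel(img)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0L) return(matrix(FALSE, nrow(region), ncol(region)))
  keep <- which.max(tab)
  comp <- EBImage::Image(EBImage::imageData(lab) == keep)
  comp <- EBImage::fillHull(comp)
  t(EBImage::imageData(comp)) > 0
}
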