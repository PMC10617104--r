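#' Invertible crop-and-pad transforms between slice and segmenter frames
#'
#' The segmenter consumes a fixed-size square frame built from the detection
#' box: the box region is cropped, isotropically rescaled so its long side
#' fills the frame (no distortion), centered, and the remainder filled with
#' gray value 128. The transform is recorded so predicted masks can be mapped
#' back to the original slice frame. Boxes are 0-based half-open.
#'
#' @name roi_crop
NULL

new_box_transform <- function(source_size, box, scale = NA_real_,
                              pad_offsets = c(0L, 0L), target_size = NA_integer_) {
  structure(list(source_size = as.integer(source_size), box = as.numeric(box),
                 scale = scale, pad_offsets = as.integer(pad_offsets),
                 target_size = as.integer(target_size)),
            class = "box_transform")
}

#' @export
print.box_transform <- function(x, ...) {
  cat(sprintf("box_transform: source %dx%d, box [%g, %g, %g, %g), scale %s, offsets (%d, %d), target %s\n",
              x$source_size[1L], x$source_size[2L], x$box[1L], x$box[2L], x$box[3L], x$box[4L],
              format(x$scale), x$pad_offsets[1L], x$pad_offsets[2L], format(x$target_size)))
  invisible(x)
}

#' Crop an image to a detection box
#'
#' @param image numeric or integer matrix (\code{[y, x]} indexed).
#' @param box \code{(x_min, y_min, x_max, y_max)}, 0-based half-open; clipped
#'   to the image bounds.
#' @param margin extra context in pixels added on every side of the box
#'   before clipping.
#' @return list with \code{crop} (sub-image) and \code{transform}
#'   (a \code{box_transform} recording the box).
#' @export
crop_to_box <- function(image, box, margin = 0) {
  h <- nrow(image); w <- ncol(image)
  box <- box + c(-margin, -margin, margin, margin)
  box <- c(max(0, floor(box[1L])), max(0, floor(box[2L])),
           min(w, ceiling(box[3L])), min(h, ceiling(box[4L])))
  if (box[3L] <= box[1L] || box[4L] <= box[2L]) {
    stop("box does not intersect the image")
  }
  crop <- image[(box[2L] + 1L):box[4L], (box[1L] + 1L):box[3L], drop = FALSE]
  list(crop = crop, transform = new_box_transform(c(w, h), box))
}

# resample a matrix to new dimensions; target pixel centers map to source
# coordinate (i + 0.5) / scale - 0.5 per axis
resample_grid <- function(mat, new_h, new_w, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  h <- nrow(mat); w <- ncol(mat)
  sx <- new_w / w; sy <- new_h / h
  xs <- ((seq_len(new_w) - 0.5) / sx) - 0.5  # 0-based source coords
  ys <- ((seq_len(new_h) - 0.5) / sy) - 0.5
  if (method == "nearest") {
    xi <- pmin(pmax(round(xs), 0), w - 1L) + 1L
    yi <- pmin(pmax(round(ys), 0), h - 1L) + 1L
    mat[yi, xi, drop = FALSE]
  } else {
    x0 <- pmin(pmax(floor(xs), 0), w - 1L); x1 <- pmin(x0 + 1L, w - 1L)
    y0 <- pmin(pmax(floor(ys), 0), h - 1L); y1 <- pmin(y0 + 1L, h - 1L)
    wx <- pmin(pmax(xs - x0, 0), 1); wy <- pmin(pmax(ys - y0, 0), 1)
    m00 <- mat[y0 + 1L, x0 + 1L, drop = FALSE]; m01 <- mat[y0 + 1L, x1 + 1L, drop = FALSE]
    m10 <- mat[y1 + 1L, x0 + 1L, drop = FALSE]; m11 <- mat[y1 + 1L, x1 + 1L, drop = FALSE]
    wxm <- matrix(wx, new_h, new_w, byrow = TRUE)
    wym <- matrix(wy, new_h, new_w)
    (1 - wym) * ((1 - wxm) * m00 + wxm * m01) + wym * ((1 - wxm) * m10 + wxm * m11)
  }
}

#' Letterbox a crop into a square frame
#'
#' Rescales isotropically so the long side equals \code{size}, centers the
#' content, and fills the border with \code{fill} (gray 128 for images, 0 for
#' label masks).
#'
#' @param crop matrix from \code{\link{crop_to_box}} (or any image).
#' @param transform the \code{box_transform} from the crop step (one is
#'   created if omitted).
#' @param size target frame side, pixels.
#' @param fill fill value for the padded border.
#' @param interp "bilinear" for images, "nearest" for label masks.
#' @return list with \code{padded} (size x size matrix) and the completed
#'   \code{transform}.
#' @export
pad_to_square <- function(crop, transform = NULL, size = 256L, fill = 128,
                          interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(crop); w <- ncol(crop)
  if (h == 0L || w == 0L) stop("empty crop")
  if (is.null(transform)) transform <- new_box_transform(c(w, h), c(0, 0, w, h))
  scale <- size / max(w, h)
  cw <- max(1L, round(w * scale)); ch <- max(1L, round(h * scale))
  content <- resample_grid(crop, ch, cw, method = interp)
  left <- (size - cw) %/% 2L; top <- (size - ch) %/% 2L
  padded <- matrix(fill, size, size)
  padded[(top + 1L):(top + ch), (left + 1L):(left + cw)] <- content
  transform$scale <- scale
  transform$pad_offsets <- c(left, top)
  transform$target_size <- as.integer(size)
  list(padded = padded, transform = transform)
}

#' Map a predicted mask back to the original slice frame
#'
#' Discards the padded border, rescales the content back to the crop size
#' with nearest-neighbor label interpolation, and places it at the box
#' position in an otherwise empty full-size mask.
#'
#' @param mask256 label mask in the padded frame.
#' @param transform the completed \code{box_transform}.
#' @return label mask in the source slice frame.
#' @export
unpad_mask <- function(mask256, transform) {
  t <- transform
  if (is.na(t$scale) || is.na(t$target_size)) stop("transform is missing pad information")
  if (!identical(dim(mask256), c(t$target_size, t$target_size))) {
    stop("mask size does not match the transform's target size")
  }
  bw <- t$box[3L] - t$box[1L]; bh <- t$box[4L] - t$box[2L]
  cw <- max(1L, round(bw * t$scale)); ch <- max(1L, round(bh * t$scale))
  left <- t$pad_offsets[1L]; top <- t$pad_offsets[2L]
  content <- mask256[(top + 1L):(top + ch), (left + 1L):(left + cw), drop = FALSE]
  back <- resample_grid(content, bh, bw, method = "nearest")
  full <- matrix(0L, t$source_size[2L], t$source_size[1L])
  full[(t$box[2L] + 1L):t$box[4L], (t$box[1L] + 1L):t$box[3L]] <- back
  full
}

#' Map points between slice frame and padded frame
#'
#' @param transform a completed \code{box_transform}.
#' @param points n x 2 matrix of (x, y) coordinates.
#' @param inverse map padded-frame points back to the slice frame.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points, inverse = FALSE) {
  t <- transform
  points <- matrix(as.numeric(points), ncol = 2L)
  if (!inverse) {
    cbind((points[, 1L] - t$box[1L] + 0.5) * t$scale - 0.5 + t$pad_offsets[1L],
          (points[, 2L] - t$box[2L] + 0.5) * t$scale - 0.5 + t$pad_offsets[2L])
  } else {
    cbind((points[, 1L] - t$pad_offsets[1L] + 0.5) / t$scale - 0.5 + t$box[1L],
          (points[, 2L] - t$pad_offsets[2L] + 0.5) / t$scale - 0.5 + t$box[2L])
  }
}

#' Letterbox a full slice for the detector and map boxes back
#'
#' @param image numeric matrix.
#' @param size detector input side (512).
#' @return list with \code{resized} image and \code{transform}.
#' @export
resize_for_detector <- function(image, size = 512L) {
  cr <- crop_to_box(image, c(0, 0, ncol(image), nrow(image)))
  pad_to_square(cr$crop, cr$transform, size = size, fill = 128, interp = "bilinear")
}

#' Map a detector-frame box back to the slice frame
#'
#' @param box \code{(x_min, y_min, x_max, y_max)} in the padded/detector
#'   frame, half-open.
#' @param transform the transform returned with the resized image.
#' @return box in the source slice frame.
#' @export
box_to_source <- function(box, transform) {
  # half-open boxes map edge coordinates, not pixel centers
  t <- transform
  x <- (c(box[1L], box[3L]) - t$pad_offsets[1L]) / t$scale + t$box[1L]
  y <- (c(box[2L], box[4L]) - t$pad_offsets[2L]) / t$scale + t$box[2L]
  c(x[1L], y[1L], x[2L], y[2L])
}

#' Serialize a box transform to JSON
#'
#' @param transform a \code{box_transform}.
#' @param path optional output file.
#' @export
box_transform_to_json <- function(transform, path = NULL) {
  obj <- unclass(transform)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, digits = NA)
    invisible(path)
  }
}
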