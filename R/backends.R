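#' Detector and segmenter backends
#'
#' The pipeline is written against two small functional contracts so that a
#' trained network could be dropped in later without touching the geometry
#' code:
#' \itemize{
#'   \item a segmenter maps a letterboxed square image to a label mask over
#'     \{0, 1, 2\} on the same grid;
#'   \item a detector maps a detector-frame image (plus side information for
#'     the reference backends) to a list of class-tagged boxes with
#'     confidences in [0, 1].
#' }
#' Two desk-scale reference backends are provided: oracles that transport the
#' phantom ground truth, and an intensity-threshold segmenter that works from
#' the image alone.
#'
#' @name backends
NULL

#' Oracle segmenter built from phantom ground truth
#'
#' Returns a segmenter that ignores the pixel data and transports the
#' ground-truth label mask through the same crop-and-pad transform as the
#' image, with nearest-neighbor label interpolation and background fill.
#'
#' @param case a \code{phantom_case}.
#' @return function(padded_image, transform) -> label mask.
#' @export
oracle_segmenter <- function(case) {
  force(case)
  function(padded_image, transform) {
    cr <- crop_to_box(case$mask, transform$box)
    pad_to_square(cr$crop, cr$transform, size = transform$target_size,
                  fill = 0, interp = "nearest")$padded
  }
}

#' Intensity-threshold segmenter
#'
#' Classifies pixels into background/myometrium/tumor by intensity bands at
#' the midpoints between the configured tissue gray levels, excludes
#' letterbox padding (exact gray 128) from all tissue classes, keeps the
#' largest connected component of the uterus (myometrium plus tumor) with
#' holes filled, and retains only tumor pixels inside that component.
#'
#' @param levels gray values c(background, myometrium, tumor); bands are
#'   split at the midpoints.
#' @return function(padded_image, transform) -> label mask.
#' @export
threshold_segmenter <- function(levels = c(background = 30, myometrium = 120, tumor = 190)) {
  lv <- as.numeric(levels)
  if (is.unsorted(lv, strictly = TRUE)) stop("intensity bands overlap: levels must increase")
  lo <- (lv[1L] + lv[2L]) / 2
  hi <- (lv[2L] + lv[3L]) / 2
  function(padded_image, transform = NULL) {
    pad <- padded_image == 128
    tissue <- padded_image >= lo & !pad
    tumor <- padded_image >= hi & !pad
    if (!any(tissue)) return(matrix(0L, nrow(padded_image), ncol(padded_image)))
    uterus <- largest_component_filled(tissue)
    out <- matrix(0L, nrow(padded_image), ncol(padded_image))
    out[uterus] <- LABEL_UTERUS
    tum_in <- tumor & uterus
    if (any(tum_in)) {
      tum_in <- largest_component_filled(tum_in) & uterus
      out[tum_in] <- LABEL_TUMOR
    }
    out
  }
}

#' Oracle detector over a phantom sequence
#'
#' Emits the ground-truth boxes of every slice with per-class confidence
#' equal to the slice's visibility score normalized by the sequence maximum,
#' optionally jittered, so slice ranking is non-trivial but solvable.
#'
#' @param sequence output of \code{\link{make_sequence}}.
#' @param jitter_sd standard deviation of Gaussian confidence jitter.
#' @param seed seed for the jitter.
#' @return list of per-slice detection records, each
#'   \code{list(slice_index, detections)}.
#' @export
oracle_detector <- function(sequence, jitter_sd = 0, seed = 1L) {
  vis <- sequence$visibility
  norm <- function(v) if (max(v) > 0) v / max(v) else v
  cu <- norm(vis$uterus); ct <- norm(vis$tumor)
  if (jitter_sd > 0) {
    set.seed(seed)
    cu <- pmin(pmax(cu + stats::rnorm(length(cu), sd = jitter_sd), 0), 1)
    ct <- pmin(pmax(ct + stats::rnorm(length(ct), sd = jitter_sd), 0), 1)
  }
  lapply(seq_along(sequence$slices), function(i) {
    case <- sequence$slices[[i]]
    dets <- lapply(case$boxes, function(b) {
      conf <- if (b$class == "uterus") cu[i] else ct[i]
      list(class = b$class, box = as.numeric(b$box), confidence = conf)
    })
    # a slice without a tumor box simply has no tumor detection
    list(slice_index = vis$slice_index[i], detections = dets)
  })
}
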