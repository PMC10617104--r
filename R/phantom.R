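#' Specification of a synthetic uterus/tumor phantom
#'
#' A phantom slice contains a filled (optionally bent) elliptical uterus on a
#' dark background, a ground-truth cavity line along the long axis, and a
#' tumor anchored on the cavity line that infiltrates the myometrium on one
#' side to a controlled fraction \code{infiltration_fraction} of the local
#' wall thickness. Intensities are chosen so the three tissue classes are
#' separable by simple thresholds.
#'
#' @param image_size (width, height) in pixels.
#' @param uterus_center (x, y) center in pixels, 0-based.
#' @param semi_axes (A, B) semi-major / semi-minor axes in pixels, A > B.
#' @param orientation major-axis angle in radians.
#' @param bend curvature coefficient (1/pixels); 0 gives a pure ellipse,
#'   positive values give a banana-like warp implemented as a quadratic shear
#'   of the transverse coordinate as a function of position along the long
#'   axis. The ground-truth cavity line is warped identically.
#' @param tumor_arc (start, end) in radians, within (0, pi): the span of the
#'   ellipse parameter over which the tumor is anchored on the cavity line
#'   (parameter t maps to long-axis position u = A cos t).
#' @param infiltration_fraction f in [0, 1]: the tumor extends on one side of
#'   the cavity line along the local transverse direction to exactly f times
#'   the local cavity-line-to-boundary distance.
#' @param intensity_levels gray values for background, myometrium, tumor.
#' @param noise_sd additive Gaussian noise, gray-value units.
#' @param band_halfwidth half-width in pixels of the thin tumor band that
#'   straddles the cavity line (so tumors cross the line as in clinical
#'   images while infiltrating only one side).
#' @param seed integer seed; identical seed + spec gives bit-identical output.
#' @return a validated \code{phantom_spec} list.
#' @export
phantom_spec <- function(image_size = c(512L, 512L),
                         uterus_center = c(256, 256),
                         semi_axes = c(150, 80),
                         orientation = 0.3,
                         bend = 0,
                         tumor_arc = c(pi / 3, 2 * pi / 3),
                         infiltration_fraction = 0.3,
                         intensity_levels = c(background = 30, myometrium = 120, tumor = 190),
                         noise_sd = 8,
                         band_halfwidth = 2,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size), uterus_center = uterus_center,
               semi_axes = semi_axes, orientation = orientation, bend = bend,
               tumor_arc = sort(tumor_arc), infiltration_fraction = infiltration_fraction,
               intensity_levels = intensity_levels, noise_sd = noise_sd,
               band_halfwidth = band_halfwidth, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  f <- spec$infiltration_fraction
  A <- spec$semi_axes[1L]; B <- spec$semi_axes[2L]
  if (!(f >= 0 && f <= 1)) stop("infiltration_fraction must lie in [0, 1]")
  if (!(A > B && B > 0)) stop("semi_axes must satisfy A > B > 0")
  bp <- phantom_boundary_points(spec)
  w <- spec$image_size[1L]; h <- spec$image_size[2L]
  if (min(bp[, 1L]) < 0 || max(bp[, 1L]) > w - 1 ||
      min(bp[, 2L]) < 0 || max(bp[, 2L]) > h - 1) {
    stop("phantom spec places the uterus outside the image bounds")
  }
  invisible(spec)
}

# local frame: u along the long axis, v transverse; bend shears v' = v + bend u^2
phantom_to_global <- function(spec, u, v) {
  vp <- v + spec$bend * u^2
  ct <- cos(spec$orientation); st <- sin(spec$orientation)
  cbind(spec$uterus_center[1L] + ct * u - st * vp,
        spec$uterus_center[2L] + st * u + ct * vp)
}

phantom_boundary_points <- function(spec, n = 720L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  phantom_to_global(spec, spec$semi_axes[1L] * cos(t), spec$semi_axes[2L] * sin(t))
}

#' Ground-truth cavity line of a phantom
#'
#' @param spec a \code{phantom_spec}.
#' @param n number of points.
#' @return n x 2 matrix of (x, y) points ordered along the line.
#' @export
phantom_cavity_line <- function(spec, n = 201L) {
  u <- seq(-spec$semi_axes[1L], spec$semi_axes[1L], length.out = n)
  phantom_to_global(spec, u, rep(0, n))
}

#' Render a phantom slice
#'
#' Rasterizes the uterus as a filled (optionally bent) ellipse, places the
#' tumor as a band straddling the cavity line over \code{tumor_arc} that
#' infiltrates one side to fraction f of the local wall thickness, clips the
#' tumor to the uterus, and adds Gaussian noise to the rendered image.
#'
#' @param spec a \code{phantom_spec}.
#' @return a \code{phantom_case} list: \code{image} (numeric matrix, 0-255),
#'   \code{mask} (labels 0/1/2), \code{cavity_line} (ground-truth polyline),
#'   \code{true_mi}, \code{true_stage} ("IA" iff f < 0.5), and \code{boxes}
#'   (tight per-class bounding boxes, 0-based half-open).
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  w <- spec$image_size[1L]; h <- spec$image_size[2L]
  A <- spec$semi_axes[1L]; B <- spec$semi_axes[2L]
  f <- spec$infiltration_fraction

  # invert the placement for every pixel center
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  ct <- cos(spec$orientation); st <- sin(spec$orientation)
  dx <- xs - spec$uterus_center[1L]; dy <- ys - spec$uterus_center[2L]
  u <- ct * dx + st * dy
  vp <- -st * dx + ct * dy
  v <- vp - spec$bend * u^2

  uterus <- (u / A)^2 + (v / B)^2 <= 1

  arc <- spec$tumor_arc
  u_range <- sort(A * cos(arc))
  half_th <- B * sqrt(pmax(0, 1 - (u / A)^2))  # local cavity-line-to-boundary distance
  depth <- pmax(spec$band_halfwidth, f * half_th)
  tumor <- uterus & u >= u_range[1L] & u <= u_range[2L] &
    v >= -spec$band_halfwidth & v <= depth

  mask <- matrix(LABEL_BACKGROUND, h, w)
  mask[uterus] <- LABEL_UTERUS
  mask[tumor] <- LABEL_TUMOR

  lv <- spec$intensity_levels
  image <- matrix(lv[[1L]], h, w)
  image[uterus] <- lv[[2L]]
  image[tumor] <- lv[[3L]]
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    image <- image + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  }
  image <- round(pmin(pmax(image, 0), 255))

  boxes <- list(list(class = "uterus", box = tight_box(label_region(mask, LABEL_UTERUS))))
  tb <- tight_box(mask == LABEL_TUMOR)
  if (!is.null(tb)) boxes <- c(boxes, list(list(class = "tumor", box = tb)))

  structure(list(image = image, mask = mask,
                 cavity_line = phantom_cavity_line(spec),
                 true_mi = f,
                 true_stage = if (f < 0.5) "IA" else "IB",
                 boxes = boxes, spec = spec),
            class = "phantom_case")
}

#' Render a phantom slice sequence with varying visibility
#'
#' Emulates an image sequence in which only one or two central slices show the
#' uterus and tumor clearly: away from the optimal slice(s) the anatomy
#' shrinks, blurs, and loses contrast, and distant slices lack the tumor
#' entirely. The per-slice visibility (mask area times contrast factor) drives
#' the oracle detector's confidences.
#'
#' @param spec a \code{phantom_spec} describing the optimal slice.
#' @param n_slices number of slices, at least 3.
#' @param n_optimal 1 or 2 central slices flagged as the reference selection
#'   (two adjacent slices mirror cases where a reader accepts either of two
#'   equally clear slices).
#' @return list with \code{slices} (list of \code{phantom_case}),
#'   \code{optimal_indices} (0-based), and \code{visibility} (data frame with
#'   per-slice uterus/tumor visibility scores).
#' @export
make_sequence <- function(spec, n_slices, n_optimal = 1L) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  n_slices <- as.integer(n_slices)
  n_optimal <- as.integer(n_optimal)
  if (n_slices < 3L) stop("a sequence needs at least 3 slices")
  if (!n_optimal %in% c(1L, 2L)) stop("n_optimal must be 1 or 2")
  mid <- (n_slices + 1L) %/% 2L
  optimal <- if (n_optimal == 1L) mid else c(mid, min(mid + 1L, n_slices))

  slices <- vector("list", n_slices)
  vis <- data.frame(slice_index = 0:(n_slices - 1L), uterus = 0, tumor = 0)
  for (i in seq_len(n_slices)) {
    d <- min(abs(i - optimal))
    shrink <- max(0.45, 1 - 0.12 * d)
    contrast <- max(0.5, 1 - 0.12 * d)
    lv <- spec$intensity_levels
    lv_s <- lv[[1L]] + (c(lv[[1L]], lv[[2L]], lv[[3L]]) - lv[[1L]]) * contrast
    names(lv_s) <- names(spec$intensity_levels)
    has_tumor <- d <= 2L
    sl_spec <- phantom_spec(
      image_size = spec$image_size,
      uterus_center = spec$uterus_center,
      semi_axes = spec$semi_axes * shrink,
      orientation = spec$orientation,
      bend = spec$bend,
      tumor_arc = spec$tumor_arc,
      infiltration_fraction = if (has_tumor) spec$infiltration_fraction else 0,
      intensity_levels = lv_s,
      noise_sd = spec$noise_sd,
      band_halfwidth = spec$band_halfwidth,
      seed = spec$seed + i
    )
    case <- make_phantom(sl_spec)
    if (!has_tumor) {
      case$mask[case$mask == LABEL_TUMOR] <- LABEL_UTERUS
      case$boxes <- Filter(function(b) b$class != "tumor", case$boxes)
      case$true_mi <- 0
      case$true_stage <- "IA"
    }
    if (d > 0) {
      img <- EBImage::gblur(EBImage::Image(t(case$image) / 255), sigma = 0.6 * d)
      case$image <- round(pmin(pmax(t(EBImage::imageData(img)) * 255, 0), 255))
    }
    slices[[i]] <- case
    vis$uterus[i] <- sum(case$mask >= LABEL_UTERUS) * contrast
    vis$tumor[i] <- sum(case$mask == LABEL_TUMOR) * contrast
  }
  list(slices = slices, optimal_indices = optimal - 1L, visibility = vis)
}

#' Generate and write a phantom cohort
#'
#' Samples per-case uterine geometry and infiltration fraction, renders each
#' case, and writes images, label masks, ground-truth detection boxes and a
#' CSV manifest to a directory.
#'
#' @param n_cases number of cases (>= 1).
#' @param f_range interval from which the infiltration fraction is drawn
#'   uniformly.
#' @param seed master seed; the manifest is identical across re-runs.
#' @param dir output directory (created if missing).
#' @param image_size (width, height) of each slice.
#' @param bend_range interval for the curvature coefficient (default: straight
#'   uteri only).
#' @return the manifest data frame (also written as \code{manifest.csv}) with
#'   columns case_id, slice_index, image_path, mask_path, true_mi, true_stage,
#'   optimal.
#' @export
sample_cohort <- function(n_cases, f_range = c(0.05, 0.95), seed = 1L,
                          dir = tempfile("cohort"), image_size = c(512L, 512L),
                          bend_range = c(0, 0)) {
  if (n_cases < 1L) stop("n_cases must be at least 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable directory: ", dir)
  set.seed(seed)
  w <- image_size[1L]; h <- image_size[2L]
  sc <- min(w, h) / 512  # geometry ranges scale with the grid
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    A <- stats::runif(1, 120, 170) * sc
    B <- stats::runif(1, 60 * sc, min(95 * sc, A - 20 * sc))
    theta <- stats::runif(1, -0.5, 0.5)
    arc_mid <- stats::runif(1, pi / 3, 2 * pi / 3)
    arc_hw <- stats::runif(1, 0.25, 0.5)
    f <- stats::runif(1, f_range[1L], f_range[2L])
    bend <- stats::runif(1, bend_range[1L], bend_range[2L])
    case_seed <- sample.int(.Machine$integer.max, 1L)
    spec <- phantom_spec(image_size = image_size,
                         uterus_center = c(w / 2, h / 2) + stats::runif(2, -15, 15) * sc,
                         semi_axes = c(A, B), orientation = theta, bend = bend,
                         tumor_arc = c(arc_mid - arc_hw, arc_mid + arc_hw),
                         infiltration_fraction = f,
                         band_halfwidth = max(2 * sc, 1),
                         seed = case_seed)
    case <- make_phantom(spec)
    id <- sprintf("case_%04d", i)
    img_path <- file.path(dir, paste0(id, "_image.png"))
    mask_path <- file.path(dir, paste0(id, "_mask.png"))
    write_image_png(case$image, img_path)
    write_mask_png(case$mask, mask_path)
    dets <- lapply(case$boxes, function(b) {
      list(slice = 0L, class = b$class, box = as.integer(b$box), confidence = 1.0)
    })
    jsonlite::write_json(dets, file.path(dir, paste0(id, "_boxes.json")),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(case_id = id, slice_index = 0L,
                            image_path = basename(img_path),
                            mask_path = basename(mask_path),
                            true_mi = f, true_stage = case$true_stage,
                            optimal = TRUE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
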