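#' Extract the ordered boundary contour of a labeled region
#'
#' Takes the largest 8-connected component of the requested label, fills its
#' holes, and traces the ordered boundary polyline. The uterus label includes
#' tumor pixels, since the tumor lies within the uterus.
#'
#' @param mask integer label mask.
#' @param label class label (1 = uterus, 2 = tumor).
#' @return matrix of ordered (x, y) boundary points, 0-based pixel centers,
#'   implicitly closed.
#' @export
extract_contour <- function(mask, label = 1L) {
  region <- label_region(mask, label)
  if (!any(region)) stop("empty region: no pixels with label ", label)
  comp <- largest_component_filled(region)
  oc <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(t(comp))))
  pts <- oc[[1L]]  # 0-based (x, y), ordered along the boundary
  colnames(pts) <- c("x", "y")
  pts
}

#' Generate the virtual uterine cavity line
#'
#' Fits an ellipse to the uterine contour by direct least squares, takes the
#' major-axis chord as the cavity line, clips it to the interior of the
#' uterus mask (the longest in-mask run along the chord, so a bent uterus
#' does not produce a line that exits the wall), and samples equally spaced
#' points along the clipped segment.
#'
#' @param uterus_mask label mask (pixels with label >= 1 form the uterus).
#' @param n_samples number of equally spaced sample points on the line.
#' @return a \code{ucl} list: \code{endpoints} (2 x 2 matrix), \code{samples}
#'   (n x 2 matrix), \code{direction} and \code{normal} unit vectors, and
#'   \code{geometry} (the fitted \code{ellipse_geometry}).
#' @export
generate_ucl <- function(uterus_mask, n_samples = 200L) {
  contour <- extract_contour(uterus_mask, LABEL_UTERUS)
  geom <- conic_to_geometry(fit_ellipse(contour))
  ep <- major_axis_endpoints(geom)

  region <- largest_component_filled(label_region(uterus_mask, LABEL_UTERUS))
  # clip the chord to the longest run of in-mask points
  step <- 0.5
  len <- sqrt(sum((ep[2L, ] - ep[1L, ])^2))
  ts <- seq(0, 1, by = step / len)
  px <- ep[1L, 1L] + ts * (ep[2L, 1L] - ep[1L, 1L])
  py <- ep[1L, 2L] + ts * (ep[2L, 2L] - ep[1L, 2L])
  inside <- points_in_mask(region, px, py)
  runs <- rle(inside)
  if (!any(runs$values)) stop("degenerate UCL: major axis does not intersect the uterus mask")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  i0 <- starts[best]; i1 <- ends[best]
  if ((ts[i1] - ts[i0]) * len < 2) stop("degenerate UCL: clipped segment shorter than 2 px")

  p0 <- c(px[i0], py[i0]); p1 <- c(px[i1], py[i1])
  ss <- seq(0, 1, length.out = n_samples)
  samples <- cbind(p0[1L] + ss * (p1[1L] - p0[1L]),
                   p0[2L] + ss * (p1[2L] - p0[2L]))
  colnames(samples) <- c("x", "y")
  dirv <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  structure(list(endpoints = rbind(p0, p1), samples = samples,
                 direction = dirv, normal = c(-dirv[2L], dirv[1L]),
                 geometry = geom),
            class = "ucl")
}

#' Measure myometrial infiltration depth along cavity-line normals
#'
#' From each sample point on the cavity line, rays are cast along both unit
#' normals in sub-pixel steps until they exit the uterus mask. For each ray,
#' n is the distance from the sample point to the exit (the local myometrial
#' thickness on that side) and m is the distance to the farthest tumor pixel
#' encountered strictly before the exit; tumor tissue still present at the
#' last in-wall probe counts as reaching the outer boundary (m = n). The MI
#' depth R is the maximum ratio m/n over all rays; a ray with no tumor
#' contributes 0 and ratios are clamped to 1. Stage IA is assigned when
#' R < 0.5, IB otherwise.
#'
#' A second definition, the ratio of the global maximum tumor reach to the
#' global maximum wall thickness over all rays (which can disagree with the
#' per-ray maximum when the two maxima occur at different cavity-line
#' points), is available as \code{variant = "global"}.
#'
#' @param uterus_mask,tumor_mask label masks on the same grid (a single
#'   combined mask may be passed for both; regions are taken as label >= 1
#'   and label == 2 respectively).
#' @param ucl a \code{ucl} object from \code{\link{generate_ucl}}.
#' @param step ray step in pixels.
#' @param variant "per_ray" (default) maximizes m/n per ray; "global" divides
#'   the maximum m by the maximum n.
#' @return an \code{mi_result} list: \code{per_sample} data frame (sample
#'   point, ray direction sign, m, n, ratio), \code{mi_depth}, \code{argmax},
#'   and \code{stage}.
#' @export
measure_mi <- function(uterus_mask, tumor_mask = uterus_mask, ucl,
                       step = 0.25, variant = c("per_ray", "global")) {
  variant <- match.arg(variant)
  if (!identical(dim(uterus_mask), dim(tumor_mask))) {
    stop("uterus and tumor masks must share the same grid")
  }
  uterus <- label_region(uterus_mask, LABEL_UTERUS)
  tumor <- label_region(tumor_mask, LABEL_TUMOR)

  samples <- ucl$samples
  n_s <- nrow(samples)
  max_len <- 2 * ucl$geometry$semi_minor + 4 * step +
    0.25 * ucl$geometry$semi_major  # generous bound on wall thickness
  ts <- seq(step, max_len, by = step)
  n_t <- length(ts)

  res <- vector("list", 2L)
  for (sgn in c(1, -1)) {
    nx <- sgn * ucl$normal[1L]; ny <- sgn * ucl$normal[2L]
    # rays x steps matrices of probed coordinates
    px <- outer(samples[, 1L], ts * nx, `+`)
    py <- outer(samples[, 2L], ts * ny, `+`)
    inside <- matrix(points_in_mask(uterus, px, py), n_s, n_t)
    in_run <- row_cumall(inside)
    k_in <- rowSums(in_run)                      # consecutive in-mask steps
    # the wall exit lies between the last inside and first outside probe;
    # the midpoint is the unbiased sub-pixel estimate of its distance
    n_dist <- pmin(k_in + 0.5, n_t) * step
    tum <- matrix(points_in_mask(tumor, px, py), n_s, n_t) & in_run
    m_idx <- row_last_true(tum)
    m_dist <- ifelse(m_idx > 0L, (m_idx + 0.5) * step, 0)
    # tumor still present at the last in-wall probe: it reaches the outer
    # boundary on this ray, i.e. full-thickness invasion (m = n)
    reach <- m_idx > 0L & m_idx == k_in
    m_dist[reach] <- n_dist[reach]
    res[[(3 - sgn) / 2]] <- data.frame(
      x = samples[, 1L], y = samples[, 2L], side = sgn,
      m = m_dist, n = ifelse(k_in == 0L, 0, n_dist))
  }
  per <- rbind(res[[1L]], res[[2L]])
  valid <- per$n > 0
  per$ratio <- 0
  per$ratio[valid] <- pmin(per$m[valid] / per$n[valid], 1)
  if (!any(valid)) stop("no valid rays: all cavity-line samples lie on the boundary")

  if (variant == "per_ray") {
    r <- max(per$ratio[valid])
    argmax <- which(valid)[which.max(per$ratio[valid])]
  } else {
    r <- min(max(per$m[valid]) / max(per$n[valid]), 1)
    argmax <- which(valid)[which.max(per$m[valid])]
  }
  structure(list(per_sample = per, mi_depth = r,
                 argmax = per[argmax, , drop = FALSE],
                 stage = classify_stage(r)),
            class = "mi_result")
}

# row-wise cumulative AND (prefix of consecutive TRUEs)
row_cumall <- function(m) {
  t(apply(m, 1L, cumprod)) > 0
}

# per row: index of last TRUE, 0 if none
row_last_true <- function(m) {
  apply(m, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[length(w)] else 0L
  })
}

#' FIGO stage from MI depth
#'
#' Stage IA when the infiltration depth is below half the myometrial
#' thickness; invasion of half or more is IB (the boundary value 0.5 maps to
#' IB, following the FIGO convention that IB is invasion of at least half
#' the myometrium).
#'
#' @param R MI depth in [0, 1].
#' @return "IA" or "IB".
#' @export
classify_stage <- function(R) {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R < 0 | R > 1)) {
    stop("MI depth must lie in [0, 1]")
  }
  ifelse(R < 0.5, "IA", "IB")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI depth R = %.3f -> stage %s (argmax ray at (%.1f, %.1f), side %+d, m = %.2f, n = %.2f)\n",
              x$mi_depth, x$stage, x$argmax$x, x$argmax$y, x$argmax$side,
              x$argmax$m, x$argmax$n))
  invisible(x)
}

#' Serialize an MI result to JSON
#'
#' @param result an \code{mi_result}.
#' @param ucl the \code{ucl} it was measured against.
#' @param path optional output file; if NULL the JSON string is returned.
#' @export
mi_result_to_json <- function(result, ucl, path = NULL) {
  obj <- list(mi_depth = result$mi_depth, stage = result$stage,
              ucl = lapply(seq_len(2L), function(i) as.numeric(ucl$endpoints[i, ])),
              argmax_ray = list(point = c(result$argmax$x, result$argmax$y),
                                side = result$argmax$side,
                                m = result$argmax$m, n = result$argmax$n))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Draw the cavity line and the deepest ray on an image
#'
#' Produces a simple overlay for visual audit: the UCL as a bright line and
#' the argmax ray's m (tumor reach) and n (wall thickness) segments.
#'
#' @param image numeric matrix, gray values 0-255.
#' @param ucl a \code{ucl}.
#' @param result an \code{mi_result}.
#' @param path output PNG path.
#' @export
write_overlay_png <- function(image, ucl, result, path) {
  img <- array(rep(image / 255, 3L), dim = c(dim(image), 3L))
  draw_segment <- function(img, p0, p1, rgb) {
    len <- max(sqrt(sum((p1 - p0)^2)), 1)
    ts <- seq(0, 1, length.out = ceiling(len * 2))
    xi <- round(p0[1L] + ts * (p1[1L] - p0[1L])) + 1L
    yi <- round(p0[2L] + ts * (p1[2L] - p0[2L])) + 1L
    ok <- xi >= 1L & xi <= ncol(img) & yi >= 1L & yi <= nrow(img)
    for (ch in 1:3) img[cbind(yi[ok], xi[ok], ch)] <- rgb[ch]
    img
  }
  img <- draw_segment(img, ucl$endpoints[1L, ], ucl$endpoints[2L, ], c(0, 1, 1))
  p <- c(result$argmax$x, result$argmax$y)
  nrm <- result$argmax$side * ucl$normal
  img <- draw_segment(img, p, p + result$argmax$n * nrm, c(1, 1, 0))
  img <- draw_segment(img, p, p + result$argmax$m * nrm, c(1, 0, 0))
  png::writePNG(img, path)
  invisible(path)
}
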