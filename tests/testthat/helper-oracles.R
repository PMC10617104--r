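# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use different discretizations and naive algorithms.

# sample points on an ellipse in parametric form
ellipse_points <- function(center, a, b, theta, t) {
  ct <- cos(theta); st <- sin(theta)
  cbind(center[1L] + a * ct * cos(t) - b * st * sin(t),
        center[2L] + a * st * cos(t) + b * ct * sin(t))
}

# exhaustive per-ray walker: step along each normal in very small increments,
# testing mask membership pixel by pixel, and maximize m/n over rays
bf_measure_mi <- function(uterus_mask, tumor_mask, ucl, walk_step = 0.05) {
  uterus <- uterus_mask >= 1L
  tumor <- tumor_mask == 2L
  h <- nrow(uterus); w <- ncol(uterus)
  in_region <- function(region, x, y) {
    xi <- round(x); yi <- round(y)
    if (xi < 0 || xi >= w || yi < 0 || yi >= h) return(FALSE)
    region[yi + 1L, xi + 1L]
  }
  best <- 0
  for (i in seq_len(nrow(ucl$samples))) {
    for (sgn in c(1, -1)) {
      nx <- sgn * ucl$normal[1L]; ny <- sgn * ucl$normal[2L]
      t <- walk_step; m <- 0; t_last <- 0
      repeat {
        x <- ucl$samples[i, 1L] + t * nx
        y <- ucl$samples[i, 2L] + t * ny
        if (!in_region(uterus, x, y)) break
        if (in_region(tumor, x, y)) m <- t
        t_last <- t
        t <- t + walk_step
        if (t > w + h) break
      }
      n <- t_last + walk_step / 2     # midpoint exit estimate
      reach <- m > 0 && m == t_last   # tumor present at the wall exit
      if (m > 0) m <- m + walk_step / 2
      if (reach) m <- n
      if (t_last > 0) best <- max(best, min(m / n, 1))
    }
  }
  best
}

# brute-force AP: re-run greedy matching from scratch at every rank cutoff,
# then integrate the precision envelope over achieved recalls
bf_average_precision <- function(detections, ground_truth, iou_threshold = 0.75) {
  n_gt <- length(ground_truth)
  conf <- vapply(detections, function(d) d$confidence, numeric(1L))
  ord <- order(-conf)
  match_count <- function(dets) {
    used <- logical(n_gt)
    tp <- 0L
    for (d in dets) {
      best <- 0; best_i <- 0L
      for (i in seq_len(n_gt)) {
        if (used[i] || !identical(as.character(ground_truth[[i]]$image),
                                  as.character(d$image))) next
        iou <- uclga::box_iou(d$box, ground_truth[[i]]$box)
        if (iou > best) { best <- iou; best_i <- i }
      }
      if (best_i > 0L && best >= iou_threshold) { used[best_i] <- TRUE; tp <- tp + 1L }
    }
    tp
  }
  prec <- numeric(length(ord)); rec <- numeric(length(ord))
  for (k in seq_along(ord)) {
    tp <- match_count(detections[ord[seq_len(k)]])
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  ap <- 0; prev_r <- 0
  for (r in sort(unique(rec))) {
    if (r <= prev_r) next
    ap <- ap + (r - prev_r) * max(prec[rec >= r])
    prev_r <- r
  }
  ap
}

# AUC by exhaustive pair counting, ties counted one half
bf_auc <- function(scores, labels) {
  pos <- scores[labels == "IA"]; neg <- scores[labels == "IB"]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# small random label mask containing an elliptical uterus and a tumor wedge
random_small_case <- function(seed, size = 64L) {
  set.seed(seed)
  spec <- uclga::phantom_spec(
    image_size = c(size, size),
    uterus_center = c(size / 2, size / 2) + runif(2, -2, 2),
    semi_axes = sort(c(runif(1, 16, 24), runif(1, 8, 12)), decreasing = TRUE),
    orientation = runif(1, -0.6, 0.6),
    tumor_arc = sort(runif(2, pi / 3, 2 * pi / 3)) + c(-0.2, 0.2),
    infiltration_fraction = runif(1, 0.1, 0.9),
    noise_sd = 0, band_halfwidth = 1, seed = seed)
  uclga::make_phantom(spec)
}
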