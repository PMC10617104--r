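#' Segmentation overlap metrics
#'
#' Intersection over union, class-wise pixel accuracy (recall against the
#' truth region), and Dice similarity coefficient for one label. Two empty
#' regions agree perfectly (all three = 1); a non-empty prediction against an
#' empty truth scores 0.
#'
#' @param pred,truth label masks on the same grid.
#' @param label class label to evaluate.
#' @return named vector \code{c(iou, pa, dsc)}.
#' @export
overlap_metrics <- function(pred, truth, label = 1L) {
  if (!identical(dim(pred), dim(truth))) stop("masks must share the same grid")
  p <- label_region(pred, label); t <- label_region(truth, label)
  np <- sum(p); nt <- sum(t); ni <- sum(p & t)
  if (np == 0L && nt == 0L) return(c(iou = 1, pa = 1, dsc = 1))
  c(iou = ni / (np + nt - ni),
    pa = if (nt > 0L) ni / nt else 0,
    dsc = 2 * ni / (np + nt))
}

#' Diagnostic statistics from a 2x2 confusion matrix
#'
#' Stage IA is the positive class. Rates whose denominator is zero are
#' returned as NA and flagged in the \code{defined} field rather than
#' propagating NaN.
#'
#' @param tp,fn,fp,tn case counts (IA predicted/true as positive).
#' @return list with \code{acc}, \code{sen}, \code{spe} (fractions) and
#'   \code{defined} (named logical).
#' @export
confusion_stats <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix")
  def <- c(acc = TRUE, sen = (tp + fn) > 0, spe = (tn + fp) > 0)
  list(acc = (tp + tn) / total,
       sen = if (def[["sen"]]) tp / (tp + fn) else NA_real_,
       spe = if (def[["spe"]]) tn / (tn + fp) else NA_real_,
       defined = def)
}

#' Intersection-over-union of two half-open boxes
#'
#' @param a,b boxes \code{(x_min, y_min, x_max, y_max)}, half-open.
#' @return IoU in [0, 1].
#' @export
box_iou <- function(a, b) {
  iw <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- iw * ih
  area <- (a[3L] - a[1L]) * (a[4L] - a[2L]) + (b[3L] - b[1L]) * (b[4L] - b[2L])
  if (area - inter <= 0) return(0)
  inter / (area - inter)
}

#' Average precision of a ranked detector
#'
#' Detections (pooled over images) are sorted by descending confidence and
#' greedily matched one-to-one to unmatched ground-truth boxes of the same
#' image at box-IoU at or above the threshold; each detection is a true
#' positive if it matches, a false positive otherwise. AP is the area under
#' the precision envelope of the resulting precision-recall curve
#' (all-point interpolation).
#'
#' @param detections list of lists with \code{image} (id), \code{box},
#'   \code{confidence}.
#' @param ground_truth list of lists with \code{image} and \code{box}.
#' @param iou_threshold minimum overlap ratio counting a match (default 0.75).
#' @return list with \code{ap}, and the \code{precision}/\code{recall}
#'   vectors of the curve; \code{ap} is NA (flagged) when there is no ground
#'   truth.
#' @export
average_precision <- function(detections, ground_truth, iou_threshold = 0.75) {
  n_gt <- length(ground_truth)
  if (n_gt == 0L) return(list(ap = NA_real_, precision = numeric(0), recall = numeric(0)))
  if (length(detections) == 0L) return(list(ap = 0, precision = numeric(0), recall = numeric(0)))
  conf <- vapply(detections, function(d) d$confidence, numeric(1L))
  ord <- order(-conf)
  gt_img <- vapply(ground_truth, function(g) as.character(g$image), character(1L))
  used <- logical(n_gt)
  tp <- numeric(length(ord))
  for (k in seq_along(ord)) {
    d <- detections[[ord[k]]]
    cand <- which(gt_img == as.character(d$image) & !used)
    if (length(cand)) {
      ious <- vapply(cand, function(i) box_iou(d$box, ground_truth[[i]]$box), numeric(1L))
      best <- which.max(ious)
      if (ious[best] >= iou_threshold) {
        used[cand[best]] <- TRUE
        tp[k] <- 1
      }
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  # precision envelope over all recall points
  env <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * env)
  list(ap = ap, precision = precision, recall = recall)
}

#' ROC curve and AUC for MI-depth staging
#'
#' Stage IA is the positive class and higher scores must indicate IA, so the
#' natural score for an MI depth R is 1 - R. The AUC is the rank statistic:
#' the probability that a random IA case outscores a random IB case, ties
#' counted one half, which equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores numeric per-case scores (higher = more IA-like).
#' @param labels per-case labels "IA"/"IB" (or a factor/logical with IA as
#'   TRUE).
#' @return a \code{roc_curve} list: \code{thresholds}, \code{tpr},
#'   \code{fpr}, \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels_to_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  x <- scores[pos]; y <- scores[!pos]
  # rank formula, ties counted 1/2
  r <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(x >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(y >= t), numeric(1L))
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

labels_to_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("IA", "IB"))) stop("labels must be IA or IB")
    return(labels == "IA")
  }
  stop("labels must be IA/IB strings, a factor, or a logical vector")
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same cases using
#' DeLong's placement-value variance estimate and a two-sided normal
#' approximation. The placement value of a positive case is the fraction of
#' negatives it outscores (ties one half), and symmetrically for negatives;
#' the empirical covariance of paired placement values across the two score
#' sets yields the variance of the AUC difference.
#'
#' @param scores_a,scores_b paired per-case scores (higher = more IA-like).
#' @param labels shared labels, IA positive.
#' @return list with \code{auc_a}, \code{auc_b}, \code{z}, \code{p}, and
#'   \code{degenerate} (TRUE when the variance of the difference is zero, in
#'   which case z and p are NA).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("scores and labels must be paired over the same cases")
  }
  pos <- labels_to_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pv <- function(scores) {
    x <- scores[pos]; y <- scores[!pos]
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1L))
    v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1L))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- pv(scores_a); b <- pv(scores_b)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / m +
    (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / n
  if (!is.finite(var_diff) || var_diff <= 0) {
    return(list(auc_a = a$auc, auc_b = b$auc, z = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  z <- (a$auc - b$auc) / sqrt(var_diff)
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}
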