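#' Score a slice from its detections
#'
#' A slice is a good candidate when both the uterus and the tumor are
#' detected with high confidence. The default rule multiplies the per-class
#' maximum confidences, so a slice missing either structure scores zero;
#' "sum" and "min" combinations are available.
#'
#' @param detections list of detections, each a list with \code{class}
#'   ("uterus" or "tumor"), \code{box}, and \code{confidence} in [0, 1].
#' @param rule confidence combination rule.
#' @return scalar score.
#' @export
score_slice <- function(detections, rule = c("product", "sum", "min")) {
  rule <- match.arg(rule)
  conf <- function(cls) {
    v <- vapply(detections, function(d) {
      if (identical(d$class, cls)) d$confidence else NA_real_
    }, numeric(1L))
    v <- v[!is.na(v)]
    if (length(v)) max(v) else 0
  }
  u <- conf("uterus"); t <- conf("tumor")
  switch(rule, product = u * t, sum = u + t, min = min(u, t))
}

#' Select the top-k slices of a sequence by detection confidence
#'
#' @param sequence list of per-slice detection lists, in slice order; slice
#'   indices are 0-based positions in the list unless elements carry a
#'   \code{slice_index}.
#' @param k number of slices to select.
#' @param rule passed to \code{\link{score_slice}}.
#' @return integer vector of slice indices, by descending score, ties broken
#'   toward the lower slice index.
#' @export
select_top_k <- function(sequence, k = 3L, rule = "product") {
  if (k < 1L) stop("k must be at least 1")
  if (length(sequence) == 0L) stop("empty sequence")
  idx <- vapply(seq_along(sequence), function(i) {
    s <- sequence[[i]]
    if (!is.null(s$slice_index)) as.integer(s$slice_index) else i - 1L
  }, integer(1L))
  dets <- lapply(sequence, function(s) if (!is.null(s$detections)) s$detections else s)
  scores <- vapply(dets, score_slice, numeric(1L), rule = rule)
  ord <- order(-scores, idx)
  idx[ord][seq_len(min(k, length(idx)))]
}

#' CADk slice-selection accuracy
#'
#' Fraction of patients for whom any of the first k automatically selected
#' slices matches the reference (reader-selected) set. CAD1 restricts the
#' match to the single top slice; CAD3 accepts a hit anywhere in the top
#' three.
#'
#' @param selections named list: per patient, the ordered selected indices.
#' @param reference named list: per patient, the reference index set.
#' @param k number of leading selections considered.
#' @return fraction in [0, 1].
#' @export
cadk_accuracy <- function(selections, reference, k) {
  if (!setequal(names(selections), names(reference)) ||
      is.null(names(selections)) || is.null(names(reference))) {
    stop("selections and reference must cover the same named patients")
  }
  if (any(lengths(reference) == 0L)) stop("reference sets must be non-empty")
  hits <- vapply(names(selections), function(p) {
    sel <- selections[[p]]
    any(utils::head(sel, k) %in% reference[[p]])
  }, logical(1L))
  mean(hits)
}

#' Write a per-patient selection table
#'
#' @param selections named list of ordered slice indices with scores attached
#'   as the \code{scores} attribute, or a named list of index vectors.
#' @param path CSV output path with columns case_id, rank, slice_index, score.
#' @export
write_selection_csv <- function(selections, path) {
  rows <- lapply(names(selections), function(p) {
    sel <- selections[[p]]
    sc <- attr(sel, "scores")
    data.frame(case_id = p, rank = seq_along(sel), slice_index = as.integer(sel),
               score = if (is.null(sc)) NA_real_ else as.numeric(sc))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
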