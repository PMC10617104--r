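#' Run configuration
#'
#' A run is fully described by a small config (usually a YAML file): data and
#' output paths, backend choice, cavity-line parameters, the slice-score
#' rule, and mandatory seeds. Unknown keys are rejected so that typos do not
#' silently fall back to defaults, and every command writes its resolved
#' config next to its outputs.
#'
#' @param data_dir directory holding the cohort (manifest.csv plus per-case
#'   files).
#' @param out_dir directory for per-case results and reports.
#' @param backend "oracle" (ground-truth masks) or "threshold" (intensity
#'   bands).
#' @param levels tissue gray levels for the threshold backend.
#' @param n_samples,ray_step,ratio_variant cavity-line measurement
#'   parameters; see \code{\link{generate_ucl}} and \code{\link{measure_mi}}.
#' @param slice_score_rule confidence combination for slice ranking.
#' @param n_cases,f_range,image_size,bend_range cohort simulation parameters.
#' @param seed master seed (mandatory for simulation).
#' @return validated \code{run_config} list.
#' @export
run_config <- function(data_dir = "data", out_dir = "out",
                       backend = c("oracle", "threshold"),
                       levels = c(30, 120, 190),
                       n_samples = 200L, ray_step = 0.25,
                       ratio_variant = c("per_ray", "global"),
                       slice_score_rule = "product",
                       n_cases = 20L, f_range = c(0.05, 0.95),
                       image_size = c(512L, 512L), bend_range = c(0, 0),
                       seed = 1L) {
  cfg <- list(version = 1L, data_dir = data_dir, out_dir = out_dir,
              backend = match.arg(backend), levels = levels,
              n_samples = as.integer(n_samples), ray_step = ray_step,
              ratio_variant = match.arg(ratio_variant),
              slice_score_rule = slice_score_rule,
              n_cases = as.integer(n_cases), f_range = f_range,
              image_size = as.integer(image_size), bend_range = bend_range,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys must be a subset of the \code{run_config}
#'   arguments (unknown keys are an error).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$version <- NULL
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

write_resolved_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(dir, "config_resolved.yaml"))
}

#' Simulate a phantom cohort from a config
#'
#' @param config a \code{run_config}.
#' @return the manifest data frame, invisibly.
#' @export
cmd_simulate <- function(config) {
  manifest <- sample_cohort(config$n_cases, f_range = config$f_range,
                            seed = config$seed, dir = config$data_dir,
                            image_size = config$image_size,
                            bend_range = config$bend_range)
  write_resolved_config(config, config$data_dir)
  invisible(manifest)
}

# one case through detect -> crop -> pad -> segment -> unpad -> UCL -> MI
run_case <- function(image, mask_truth, detections, config) {
  seg_backend <- switch(config$backend,
    oracle = oracle_segmenter(list(mask = mask_truth)),
    threshold = threshold_segmenter(config$levels))

  ub <- Filter(function(d) d$class == "uterus", detections)
  if (length(ub) == 0L) stop("no uterus detection")
  if (!any(vapply(detections, function(d) d$class == "tumor", logical(1L)))) {
    stop("no tumor detection")
  }
  box <- ub[[which.max(vapply(ub, function(d) d$confidence, numeric(1L)))]]$box

  cr <- crop_to_box(image, box)
  pd <- pad_to_square(cr$crop, cr$transform, size = 256L, fill = 128,
                      interp = "bilinear")
  seg256 <- seg_backend(pd$padded, pd$transform)
  seg <- unpad_mask(seg256, pd$transform)
  ucl <- generate_ucl(seg, n_samples = config$n_samples)
  mi <- measure_mi(seg, seg, ucl, step = config$ray_step,
                   variant = config$ratio_variant)
  list(mi = mi, ucl = ucl, segmentation = seg, transform = pd$transform)
}

#' Run the measurement pipeline over a simulated cohort
#'
#' For every case in the manifest: pick the best slice by detection
#' confidence, crop to the uterus box, letterbox to the segmenter frame,
#' segment, map the labels back, generate the cavity line, measure MI depth
#' and stage. Failures are recorded per case and the run continues.
#'
#' @param config a \code{run_config}; the cohort must exist under
#'   \code{config$data_dir}.
#' @param overlays also write an overlay PNG per case.
#' @return data frame with case_id, true_stage, true_mi, mi_depth,
#'   pred_stage, status.
#' @export
cmd_run <- function(config, overlays = FALSE) {
  manifest <- utils::read.csv(file.path(config$data_dir, "manifest.csv"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(config, config$out_dir)
  rows <- lapply(split(manifest, manifest$case_id), function(mf) {
    # among a case's slices, run the highest-scoring one
    best <- NULL; best_score <- -Inf
    dets_by_slice <- list()
    for (i in seq_len(nrow(mf))) {
      dets <- jsonlite::read_json(
        file.path(config$data_dir, paste0(mf$case_id[i], "_boxes.json")),
        simplifyVector = FALSE)
      dets <- Filter(function(d) d$slice == mf$slice_index[i], dets)
      dets <- lapply(dets, function(d) {
        d$box <- as.numeric(unlist(d$box)); d
      })
      sc <- score_slice(dets, rule = config$slice_score_rule)
      if (sc > best_score) { best_score <- sc; best <- i; dets_by_slice <- dets }
    }
    mfi <- mf[best, ]
    out <- tryCatch({
      image <- read_image_png(file.path(config$data_dir, mfi$image_path))
      mask <- read_mask_png(file.path(config$data_dir, mfi$mask_path))
      res <- run_case(image, mask, dets_by_slice, config)
      mi_result_to_json(res$mi, res$ucl,
                        file.path(config$out_dir, paste0(mfi$case_id, "_result.json")))
      if (overlays) {
        write_overlay_png(image, res$ucl, res$mi,
                          file.path(config$out_dir, paste0(mfi$case_id, "_overlay.png")))
      }
      data.frame(case_id = mfi$case_id, true_stage = mfi$true_stage,
                 true_mi = mfi$true_mi, mi_depth = res$mi$mi_depth,
                 pred_stage = res$mi$stage, status = "ok")
    }, error = function(e) {
      data.frame(case_id = mfi$case_id, true_stage = mfi$true_stage,
                 true_mi = mfi$true_mi, mi_depth = NA_real_,
                 pred_stage = NA_character_, status = conditionMessage(e))
    })
    out
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  utils::write.csv(results, file.path(config$out_dir, "results.csv"), row.names = FALSE)
  results
}

#' Evaluate a pipeline run
#'
#' Computes the confusion statistics (IA positive), the ROC/AUC over the
#' score 1 - R, and optionally the DeLong comparison against a second result
#' set, and writes a per-case report CSV plus a JSON summary.
#'
#' @param config a \code{run_config} whose \code{out_dir} holds results.csv.
#' @param results optional results data frame (read from disk if omitted).
#' @param compare_with optional second results data frame over the same cases
#'   for a paired DeLong test.
#' @return summary list with acc, sen, spe, auc (and delong when compared).
#' @export
cmd_evaluate <- function(config, results = NULL, compare_with = NULL) {
  if (is.null(results)) {
    results <- utils::read.csv(file.path(config$out_dir, "results.csv"))
  }
  ok <- results[results$status == "ok", ]
  if (nrow(ok) == 0L) stop("no successful cases to evaluate")
  tp <- sum(ok$true_stage == "IA" & ok$pred_stage == "IA")
  fn <- sum(ok$true_stage == "IA" & ok$pred_stage == "IB")
  fp <- sum(ok$true_stage == "IB" & ok$pred_stage == "IA")
  tn <- sum(ok$true_stage == "IB" & ok$pred_stage == "IB")
  cs <- confusion_stats(tp, fn, fp, tn)
  summary <- list(n = nrow(ok), acc = cs$acc, sen = cs$sen, spe = cs$spe)
  if (length(unique(ok$true_stage)) == 2L) {
    roc <- roc_auc(1 - ok$mi_depth, ok$true_stage)
    summary$auc <- roc$auc
    if (!is.null(compare_with)) {
      cmp <- compare_with[match(ok$case_id, compare_with$case_id), ]
      dl <- delong_test(1 - ok$mi_depth, 1 - cmp$mi_depth, ok$true_stage)
      summary$auc_compare <- dl$auc_b
      summary$delong_z <- dl$z
      summary$delong_p <- dl$p
    }
  }
  report <- ok[, c("case_id", "true_stage", "mi_depth", "pred_stage")]
  utils::write.csv(report, file.path(config$out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary
}
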