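#' Run the full lung-field extraction and correction pipeline
#'
#' Per slice: convex global+local segmentation, removal of the
#' border-connected background, hole filling, slice-wise airway exclusion;
#' per stack: previous-slice exclusion propagation; then per slice:
#' defective-block detection and geometric-contour boundary correction.
#' With `stage = "segmentation"` the run stops after the airway-excluded
#' masks, with `"detect"` after the fractal statistics.
#'
#' @param images a `ct_stack` from [read_ct()], or a list of HU matrices,
#'   or a single HU matrix.
#' @param config a [pipeline_config()]. When `config$output_dir` is set,
#'   per-slice masks (pre- and post-correction, 0/255 PNG), fractal
#'   statistics (JSON), contour traces (JSON) and a JSON-lines run log are
#'   written there.
#' @return Object of class `lung_pipeline`: list with per-slice lists
#'   `segmentation` (raw mask), `lung_mask` (airway-excluded),
#'   `fractal` (fractal_stats), `corrected` (final masks), plus
#'   `convergence` flags and the `config`.
#' @export
run_pipeline <- function(images, config = pipeline_config()) {
  if (inherits(images, "ct_stack")) images <- images$images
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L)
  n_slices <- length(images)

  seg_raw <- vector("list", n_slices)      # mask straight from phi > 0.5
  seg_clean <- vector("list", n_slices)    # background removed, holes filled
  slice_excluded <- vector("list", n_slices)
  seg_results <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    res <- glg_segment(images[[i]], config$segmentation, config$edge)
    seg_results[[i]] <- res
    seg_raw[[i]] <- res$mask
    seg_clean[[i]] <- fill_holes(remove_background(res$mask))
    slice_excluded[[i]] <- exclude_airway_slice(seg_clean[[i]], images[[i]],
                                                config$airway)
  }
  lung_masks <- if (n_slices > 1L) {
    propagate_exclusion(slice_excluded, seg_clean, config$airway)
  } else {
    slice_excluded
  }

  out <- list(segmentation = seg_raw, lung_mask = lung_masks,
              fractal = NULL, corrected = NULL,
              convergence = vapply(seg_results, `[[`, logical(1), "converged"),
              config = config)
  class(out) <- "lung_pipeline"

  if (config$stage != "segmentation") {
    out$fractal <- lapply(lung_masks, detect_defective_blocks,
                          multiplier = config$defect_multiplier)
  }
  if (config$stage == "full") {
    out$corrected <- vector("list", n_slices)
    for (i in seq_len(n_slices)) {
      corr <- correct_boundary(lung_masks[[i]], out$fractal[[i]],
                               params = config$correction)
      out$corrected[[i]] <- corr$mask
      attr(out$corrected[[i]], "trace") <- corr$trace
    }
  }
  if (!is.null(config$output_dir)) write_pipeline_artifacts(out, images)
  out
}

#' @export
print.lung_pipeline <- function(x, ...) {
  cat("lung pipeline:", length(x$segmentation), "slice(s); stage:",
      x$config$stage, "\n")
  for (i in seq_along(x$lung_mask)) {
    cat("  slice", i, ": lung px", sum(x$lung_mask[[i]]))
    if (!is.null(x$fractal)) {
      cat(", defective blocks", sum(x$fractal[[i]]$is_defective))
    }
    if (!is.null(x$corrected)) cat(", corrected px", sum(x$corrected[[i]]))
    cat("\n")
  }
  invisible(x)
}

write_pipeline_artifacts <- function(result, images) {
  dir <- result$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_line <- function(obj) {
    cat(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
        "\n", sep = "", file = log_path, append = TRUE)
  }
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  log_line(list(event = "config", config = strip(result$config)))
  for (i in seq_along(result$lung_mask)) {
    write_mask_png(result$lung_mask[[i]],
                   file.path(dir, sprintf("lung_mask_%03d.png", i)))
    if (!is.null(result$fractal)) {
      write_fractal_json(result$fractal[[i]],
                         file.path(dir, sprintf("fractal_%03d.json", i)))
    }
    if (!is.null(result$corrected)) {
      write_mask_png(result$corrected[[i]],
                     file.path(dir, sprintf("corrected_mask_%03d.png", i)))
      polys <- contour_polylines(result$corrected[[i]])
      jsonlite::write_json(lapply(polys, unname),
                           file.path(dir, sprintf("contour_%03d.json", i)),
                           digits = NA)
    }
    log_line(list(event = "slice", index = i,
                  lung_pixels = sum(result$lung_mask[[i]]),
                  segmentation_converged = result$convergence[i]))
  }
  invisible(dir)
}
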