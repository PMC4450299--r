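#' Read a CT slice stack
#'
#' Supported inputs: NIfTI volumes (`.nii`/`.nii.gz`, slices along the
#' third axis, values taken as HU) and single- or multi-page PNG/TIFF with
#' an explicit linear rescale `HU = slope * stored + intercept` (PNG stores
#' values in `[0, 1]`; supply the slope/intercept of the export). DICOM
#' series are not read directly; convert to NIfTI first.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"nifti"`, `"png"`, `"tiff"`.
#' @param slope,intercept rescale coefficients, required for PNG/TIFF.
#' @return Object of class `ct_stack`: list with `images` (list of HU
#'   matrices) and `source`.
#' @export
read_ct <- function(path, format = c("auto", "nifti", "png", "tiff"),
                    slope = NULL, intercept = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (grepl("\\.png$", path)) "png"
      else if (grepl("\\.tiff?$", path)) "tiff"
      else stop("cannot infer format of ", path)
  }
  images <- switch(format,
    nifti = {
      vol <- RNifti::readNifti(path)
      arr <- as.array(vol)
      if (length(dim(arr)) == 2L) list(arr[, , drop = TRUE])
      else lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
    },
    png = {
      if (is.null(slope) || is.null(intercept)) {
        stop("PNG input needs explicit 'slope' and 'intercept' to map ",
             "stored values to HU")
      }
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      list(slope * img + intercept)
    },
    tiff = {
      if (is.null(slope) || is.null(intercept)) {
        stop("TIFF input needs explicit 'slope' and 'intercept' to map ",
             "stored values to HU")
      }
      pages <- tiff::readTIFF(path, all = TRUE)
      lapply(pages, function(img) {
        if (length(dim(img)) == 3L) img <- img[, , 1]
        slope * img + intercept
      })
    })
  structure(list(images = images, source = path), class = "ct_stack")
}

#' Write a mask stack as a NIfTI volume
#'
#' @param masks list of same-shape 0/1 matrices (or HU matrices).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(masks, path) {
  arr <- simplify2array(lapply(masks, function(m) {
    matrix(as.numeric(m), nrow(m), ncol(m))
  }))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Assemble a full pipeline configuration
#'
#' Bundles every stage's parameter block plus run options into one
#' serializable object.
#'
#' @param edge an [edge_params()].
#' @param segmentation a [seg_params()].
#' @param airway an [airway_params()].
#' @param correction a [correction_params()].
#' @param defect_multiplier threshold multiplier for
#'   [detect_defective_blocks()].
#' @param phantom optional [phantom_spec()] when the run generates its own
#'   input.
#' @param stage run up to this stage: `"segmentation"`, `"detect"`, or
#'   `"full"`.
#' @param output_dir optional directory for mask/report artifacts; `NULL`
#'   keeps everything in memory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(edge = edge_params(),
                            segmentation = seg_params(),
                            airway = airway_params(),
                            correction = correction_params(),
                            defect_multiplier = 1,
                            phantom = NULL,
                            stage = c("full", "segmentation", "detect"),
                            output_dir = NULL) {
  stage <- match.arg(stage)
  structure(list(edge = edge, segmentation = segmentation, airway = airway,
                 correction = correction,
                 defect_multiplier = defect_multiplier,
                 phantom = phantom,
                 stage = stage, output_dir = output_dir),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the configuration object.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  pipeline_config(
    edge = do.call(edge_params, raw$edge),
    segmentation = do.call(seg_params, raw$segmentation),
    airway = do.call(airway_params, raw$airway),
    correction = do.call(correction_params, raw$correction),
    defect_multiplier = raw$defect_multiplier,
    phantom = if (!is.null(raw$phantom)) do.call(phantom_spec, raw$phantom),
    stage = raw$stage,
    output_dir = raw$output_dir)
}
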