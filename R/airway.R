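#' Parameters for central-airway exclusion
#'
#' The lung fields are flanked by ribs, so a dilated neighborhood of a true
#' lung component contains bone-density pixels; the trachea and main
#' bronchi sit centrally, away from bone. Components whose dilated ring
#' contains too little bone are excluded. None of the numeric cutoffs is
#' prescribed by the method itself; the defaults make ribs (~ +400 HU)
#' decisive while tolerating partial-volume blur.
#'
#' @param dilation_radius disk radius of the morphological dilation, pixels.
#' @param bone_hu_threshold HU above which a pixel counts as osseous.
#' @param min_bone_pixels minimum osseous pixel count in the dilated ring.
#' @param overlap_fraction fraction of a region's footprint that must have
#'   been excluded in the previous slice to propagate the exclusion.
#' @return Object of class `airway_params`.
#' @export
airway_params <- function(dilation_radius = 8L, bone_hu_threshold = 200,
                          min_bone_pixels = 20L, overlap_fraction = 0.5) {
  stopifnot(dilation_radius >= 1, min_bone_pixels >= 1,
            overlap_fraction > 0, overlap_fraction <= 1)
  structure(list(dilation_radius = as.integer(dilation_radius),
                 bone_hu_threshold = bone_hu_threshold,
                 min_bone_pixels = as.integer(min_bone_pixels),
                 overlap_fraction = overlap_fraction),
            class = "airway_params")
}

#' Label 8-connected components of a binary mask
#'
#' Components are numbered in raster order of their first pixel, so the
#' labeling is deterministic.
#'
#' @param mask 0/1 matrix.
#' @return Object of class `region_labeling`: list with `labels` (integer
#'   matrix, 0 = background), `region_ids`, and `sizes` (pixel counts).
#' @export
label_regions <- function(mask) {
  m <- as_mask(mask)
  lab <- label_cpp(m, 8L)
  ids <- seq_len(max(lab))
  sizes <- if (length(ids)) tabulate(lab[lab > 0L], nbins = max(lab)) else integer(0)
  structure(list(labels = lab, region_ids = ids, sizes = sizes),
            class = "region_labeling")
}

dilate_disk <- function(mask, radius) {
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                         brush)
  as_mask(matrix(as.numeric(out), nrow(mask), ncol(mask)) > 0.5)
}

#' Test a region for an osseous neighborhood
#'
#' Dilates the region with a disk and checks whether the ring (dilation
#' minus region) contains at least `min_bone_pixels` pixels above
#' `bone_hu_threshold`.
#'
#' @param region_mask 0/1 matrix of one region.
#' @param image HU matrix.
#' @param params an [airway_params()].
#' @return Logical scalar.
#' @export
has_osseous_neighborhood <- function(region_mask, image,
                                     params = airway_params()) {
  m <- as_mask(region_mask)
  stopifnot(sum(m) > 0, identical(dim(m), dim(image)))
  ring <- dilate_disk(m, params$dilation_radius) & !m
  sum(image[ring] > params$bone_hu_threshold) >= params$min_bone_pixels
}

#' Exclude airway components from one slice mask
#'
#' Every 8-connected component of the mask failing the osseous-neighborhood
#' test is removed.
#'
#' @param mask hole-filled 0/1 segmentation mask.
#' @param image HU matrix of the same slice.
#' @param params an [airway_params()].
#' @return 0/1 matrix, a subset of the input mask.
#' @export
exclude_airway_slice <- function(mask, image, params = airway_params()) {
  lab <- label_regions(mask)
  out <- as_mask(mask)
  for (id in lab$region_ids) {
    region <- as_mask(lab$labels == id)
    if (!has_osseous_neighborhood(region, image, params)) {
      out[region == 1L] <- 0L
    }
  }
  if (sum(out) == 0L && sum(as_mask(mask)) > 0L) {
    warning("airway exclusion removed every region; check parameters")
  }
  out
}

#' Propagate airway exclusions through a slice stack
#'
#' A tracheal cartilage ring can make the trachea pass the slice-wise
#' osseous test on isolated slices. From the second slice on, a region is
#' additionally removed when more than `overlap_fraction` of its footprint
#' was excluded (present in the raw mask, absent after processing) in the
#' previously processed slice. Single forward pass.
#'
#' @param mask_stack list of per-slice masks after slice-wise exclusion.
#' @param raw_stack list of per-slice masks before exclusion (same shapes).
#' @param params an [airway_params()].
#' @return List of per-slice masks.
#' @export
propagate_exclusion <- function(mask_stack, raw_stack,
                                params = airway_params()) {
  if (length(mask_stack) != length(raw_stack)) {
    stop("mask_stack and raw_stack lengths differ")
  }
  out <- lapply(mask_stack, as_mask)
  raw <- lapply(raw_stack, as_mask)
  for (i in seq_along(out)) {
    stopifnot(identical(dim(out[[i]]), dim(raw[[i]])))
    if (i == 1L) next
    prev_excluded <- raw[[i - 1L]] == 1L & out[[i - 1L]] == 0L
    lab <- label_regions(out[[i]])
    for (id in lab$region_ids) {
      region <- lab$labels == id
      frac <- sum(region & prev_excluded) / sum(region)
      if (frac > params$overlap_fraction) out[[i]][region] <- 0L
    }
  }
  out
}
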