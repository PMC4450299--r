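#' Specification for a synthetic thoracic CT phantom
#'
#' Describes a CT-like axial slice: an elliptical body on an air background,
#' two elliptical lung fields, rib blobs along the lateral chest wall, a
#' central trachea (optionally wrapped in a cartilage ring on selected
#' slices), and juxtapleural nodules drawn as soft-tissue disks centered on
#' the lung boundary so that density-based segmentation carves a
#' half-disk indentation out of the lung field.
#'
#' Default tissue densities are representative CT values: lung parenchyma
#' -800 HU, soft tissue +40 HU, bone +400 HU, outside air -1000 HU, with
#' additive Gaussian noise of 10 HU. They satisfy the separability the
#' pipeline assumes: `hu_lung < -500 < hu_body < hu_bone`.
#'
#' @param image_size side of the square slice in pixels.
#' @param hu_lung,hu_body,hu_bone,hu_air_outside tissue densities in HU.
#' @param noise_sigma additive Gaussian noise standard deviation, HU.
#' @param nodules list of juxtapleural nodules; each a list with elements
#'   `side` ("left" or "right"), `angle` (degrees along the lung ellipse,
#'   0 = lateral, positive = caudal) and `radius` (pixels, >= 3).
#' @param trachea_radius trachea radius in pixels.
#' @param cartilage_slices integer vector of slice indices that carry a
#'   bone-density cartilage ring around the trachea.
#' @param n_slices number of slices in a stack.
#' @param seed integer seed for the noise (geometry is deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L,
                         hu_lung = -800, hu_body = 40, hu_bone = 400,
                         hu_air_outside = -1000,
                         noise_sigma = 10,
                         nodules = list(),
                         trachea_radius = round(0.04 * image_size),
                         cartilage_slices = 2L,
                         n_slices = 3L,
                         seed = 1L) {
  stopifnot(image_size >= 64,
            hu_lung < -500, -500 < hu_body, hu_body < hu_bone,
            noise_sigma >= 0, trachea_radius >= 3)
  for (nd in nodules) {
    stopifnot(nd$side %in% c("left", "right"), nd$radius >= 3)
  }
  structure(list(image_size = as.integer(image_size),
                 hu_lung = hu_lung, hu_body = hu_body, hu_bone = hu_bone,
                 hu_air_outside = hu_air_outside,
                 noise_sigma = noise_sigma, nodules = nodules,
                 trachea_radius = as.integer(trachea_radius),
                 cartilage_slices = as.integer(cartilage_slices),
                 n_slices = as.integer(n_slices), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("CT phantom spec:", x$image_size, "x", x$image_size, "px,",
      x$n_slices, "slice(s),", length(x$nodules), "nodule(s)\n")
  cat("  HU lung/body/bone/outside:", x$hu_lung, x$hu_body, x$hu_bone,
      x$hu_air_outside, " noise sd:", x$noise_sigma, "\n")
  invisible(x)
}

# Pixel-center coordinate grids (row, col), 1-based.
coord_grid <- function(n) {
  list(r = matrix(seq_len(n), n, n), c = matrix(seq_len(n), n, n, byrow = TRUE))
}

ellipse_mask <- function(g, cr, cc, ar, ac) {
  as_mask(((g$r - cr) / ar)^2 + ((g$c - cc) / ac)^2 <= 1)
}

disk_mask <- function(g, cr, cc, rad) {
  as_mask((g$r - cr)^2 + (g$c - cc)^2 <= rad^2)
}

# Phantom geometry in pixel units, all derived from image_size.
phantom_geometry <- function(spec) {
  n <- spec$image_size
  geo <- list(
    body = list(cr = 0.52 * n, cc = 0.50 * n, ar = 0.40 * n, ac = 0.45 * n),
    lungs = list(
      left  = list(cr = 0.52 * n, cc = 0.30 * n, ar = 0.28 * n, ac = 0.15 * n),
      right = list(cr = 0.52 * n, cc = 0.70 * n, ar = 0.28 * n, ac = 0.15 * n)),
    trachea = list(cr = 0.30 * n, cc = 0.50 * n, rad = spec$trachea_radius),
    rib_angles = c(-50, 0, 50),       # degrees along each lung, 0 = lateral
    rib_offset = 1.15,                # radial scale factor outside the lung
    rib_radius = max(4, round(0.025 * n)),
    cartilage_width = max(3, round(0.015 * n)))
  geo
}

# Point on a lung ellipse at a given angle (0 = lateral, +ve caudal).
lung_boundary_point <- function(lung, side, angle_deg, scale = 1) {
  t <- angle_deg * pi / 180
  sgn <- if (side == "left") -1 else 1
  c(r = lung$cr + scale * lung$ar * sin(t),
    c = lung$cc + sgn * scale * lung$ac * cos(t))
}

#' Generate one phantom slice with ground-truth masks
#'
#' @param spec a [phantom_spec()].
#' @param slice_index 1-based slice index (selects cartilage presence and
#'   the per-slice noise stream).
#' @return A list with `image` (HU matrix) and `masks`, a list of 0/1
#'   matrices: `lung_with_nodules` (the correction target: full lung
#'   ellipses), `lung_without_nodules` (the segmentation target: lungs with
#'   nodule indentations carved out), `trachea`, `bone`, and `body`.
#' @export
phantom_slice <- function(spec, slice_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), slice_index >= 1)
  n <- spec$image_size
  g <- coord_grid(n)
  geo <- phantom_geometry(spec)

  body <- ellipse_mask(g, geo$body$cr, geo$body$cc, geo$body$ar, geo$body$ac)
  lungL <- ellipse_mask(g, geo$lungs$left$cr, geo$lungs$left$cc,
                        geo$lungs$left$ar, geo$lungs$left$ac)
  lungR <- ellipse_mask(g, geo$lungs$right$cr, geo$lungs$right$cc,
                        geo$lungs$right$ar, geo$lungs$right$ac)
  lung_full <- as_mask(lungL | lungR)
  trachea <- disk_mask(g, geo$trachea$cr, geo$trachea$cc, geo$trachea$rad)

  # Ribs: bone blobs just outside the lateral lung boundary.
  bone <- matrix(0L, n, n)
  for (side in c("left", "right")) {
    lung <- geo$lungs[[side]]
    for (a in geo$rib_angles) {
      p <- lung_boundary_point(lung, side, a, scale = geo$rib_offset)
      bone <- as_mask(bone | disk_mask(g, p["r"], p["c"], geo$rib_radius))
    }
  }
  bone <- as_mask(bone & body & !lung_full)

  # Cartilage ring around the trachea, on selected slices only.
  if (slice_index %in% spec$cartilage_slices) {
    ring <- as_mask(disk_mask(g, geo$trachea$cr, geo$trachea$cc,
                              geo$trachea$rad + geo$cartilage_width) &
                    !trachea)
    bone <- as_mask(bone | ring)
  }

  # Juxtapleural nodules: soft-tissue disks centered on the lung boundary.
  nodule <- matrix(0L, n, n)
  for (nd in spec$nodules) {
    lung <- geo$lungs[[nd$side]]
    p <- lung_boundary_point(lung, nd$side, nd$angle, scale = 1)
    dtr <- sqrt((p["r"] - geo$trachea$cr)^2 + (p["c"] - geo$trachea$cc)^2)
    if (dtr <= nd$radius + geo$trachea$rad + geo$cartilage_width + 2) {
      stop("nodule at (", round(p["r"]), ",", round(p["c"]),
           ") overlaps the trachea specification")
    }
    nodule <- as_mask(nodule | disk_mask(g, p["r"], p["c"], nd$radius))
  }
  lung_seg <- as_mask(lung_full & !nodule)

  img <- matrix(spec$hu_air_outside, n, n)
  img[body == 1L] <- spec$hu_body
  img[lung_seg == 1L] <- spec$hu_lung
  img[trachea == 1L] <- spec$hu_lung
  img[bone == 1L] <- spec$hu_bone

  if (spec$noise_sigma > 0) {
    noise <- with_local_seed(spec$seed + slice_index,
                             matrix(rnorm(n * n, 0, spec$noise_sigma), n, n))
    img <- img + noise
  }

  list(image = img,
       masks = list(lung_with_nodules = lung_full,
                    lung_without_nodules = lung_seg,
                    trachea = trachea, bone = bone, body = body))
}

#' Generate an aligned phantom slice stack
#'
#' Slices share geometry; by default only the middle slice carries the
#' tracheal cartilage ring, so the trachea passes the osseous-neighborhood
#' test there and must be removed by previous-slice propagation.
#'
#' @param spec a [phantom_spec()] with `n_slices >= 3`.
#' @return A list with `images` (list of HU matrices) and `masks` (list of
#'   per-slice truth-mask lists as in [phantom_slice()]).
#' @export
phantom_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_slices < 3) stop("a phantom stack needs n_slices >= 3")
  slices <- lapply(seq_len(spec$n_slices), function(i) phantom_slice(spec, i))
  list(images = lapply(slices, `[[`, "image"),
       masks = lapply(slices, `[[`, "masks"))
}

#' Default end-to-end phantom: one juxtapleural nodule on the left lung
#'
#' Convenience wrapper used throughout the examples and tests: a 3-slice
#' stack with a radius-8 nodule on the left lateral lung boundary and a
#' cartilage ring on slice 2 only.
#'
#' @param image_size slice side in pixels.
#' @param nodule_radius nodule radius in pixels.
#' @param seed noise seed.
#' @param noise_sigma noise standard deviation in HU.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(image_size = 512L, nodule_radius = 8L,
                                 seed = 1L, noise_sigma = 10) {
  phantom_spec(image_size = image_size,
               nodules = list(list(side = "left", angle = 25,
                                   radius = nodule_radius)),
               seed = seed, noise_sigma = noise_sigma)
}
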