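#' Parameters for the boundary-correction contour
#'
#' The correction evolves a signed level set (positive inside) under a
#' region-coded balloon force, a growing curve-length force, a small area
#' force, and Gaussian regularization applied after every step.
#'
#' @param kappa1_factor per-iteration length-weight multiplier; the length
#'   weight at iteration `n` is `kappa1_factor * n`.
#' @param kappa1_cap upper bound on the length weight; the printed rule
#'   grows without bound, which would force the time step to zero, so the
#'   weight saturates here.
#' @param kappa2 area-term weight.
#' @param eps1 Dirac regularization width.
#' @param sigma1 Gaussian regularization standard deviation, pixels.
#' @param dt time step; with unit balloon speed the default 0.1 respects
#'   the CFL bound comfortably.
#' @param max_iters,tol stopping controls: stop when the fraction of pixels
#'   whose sign changed in a step stays below `tol` for 5 consecutive
#'   iterations.
#' @param area_term_sign +1 expands (balloon-consistent, the default), -1
#'   shrinks.
#' @return Object of class `correction_params`.
#' @export
correction_params <- function(kappa1_factor = 5, kappa1_cap = 30,
                              kappa2 = 0.1, eps1 = 0.5, sigma1 = 1,
                              dt = 0.1, max_iters = 120L, tol = 1e-4,
                              area_term_sign = 1) {
  stopifnot(kappa1_factor > 0, kappa1_cap > 0, kappa2 >= 0, eps1 > 0,
            sigma1 > 0, dt > 0, max_iters >= 1, tol > 0,
            area_term_sign %in% c(-1, 1))
  structure(list(kappa1_factor = kappa1_factor, kappa1_cap = kappa1_cap,
                 kappa2 = kappa2, eps1 = eps1, sigma1 = sigma1, dt = dt,
                 max_iters = as.integer(max_iters), tol = tol,
                 area_term_sign = area_term_sign),
            class = "correction_params")
}

#' Region-coded speed map for the correction contour
#'
#' Partitions the image into the four evolution regions and codes them as
#' per-pixel speeds: +1 outside the lung (shrink any overshoot), -1 inside
#' the lung and on every pixel of a defective block (balloon outward to
#' refill the indentation), and 0 on boundary pixels lying in non-defective
#' boundary blocks (anchor the already-correct boundary).
#'
#' @param mask airway-excluded 0/1 lung mask.
#' @param stats a [detect_defective_blocks()] result for `mask`.
#' @param grid block grid; defaults to `stats$grid`.
#' @return Integer matrix with values in `{-1, 0, 1}`.
#' @export
build_speed_map <- function(mask, stats, grid = stats$grid) {
  m <- as_mask(mask)
  k <- matrix(1L, nrow(m), ncol(m))
  k[m == 1L] <- -1L
  for (bi in seq_len(grid$n_rows)) {
    for (bj in seq_len(grid$n_cols)) {
      if (stats$is_defective[bi, bj]) {
        ext <- block_extent(grid, bi, bj)
        k[ext$rows, ext$cols] <- -1L
      }
    }
  }
  boundary <- extract_boundary(m)
  for (bi in seq_len(grid$n_rows)) {
    for (bj in seq_len(grid$n_cols)) {
      if (stats$is_boundary[bi, bj] && !stats$is_defective[bi, bj]) {
        ext <- block_extent(grid, bi, bj)
        blk <- boundary[ext$rows, ext$cols]
        kb <- k[ext$rows, ext$cols]
        kb[blk == 1L] <- 0L
        k[ext$rows, ext$cols] <- kb
      }
    }
  }
  k
}

#' Initialize the signed correction level set from a mask
#'
#' `phi0 = +2` inside, `-2` outside, followed by one Gaussian smoothing so
#' the zero crossing has a non-degenerate gradient band.
#'
#' @param mask nonempty 0/1 mask.
#' @param sigma1 smoothing standard deviation.
#' @return Numeric matrix, positive inside the mask.
#' @export
init_correction_levelset <- function(mask, sigma1 = 1) {
  m <- as_mask(mask)
  if (sum(m) == 0L) stop("cannot initialize a contour from an empty mask")
  phi <- matrix(ifelse(m == 1L, 2, -2), nrow(m), ncol(m))
  gaussian_regularize(phi, sigma1)
}

# Godunov upwind gradient magnitudes for motion with signed normal speed.
upwind_gradients <- function(phi) {
  dmr <- phi - mat_shift(phi, -1L, 0L)   # backward differences
  dpr <- mat_shift(phi, 1L, 0L) - phi    # forward differences
  dmc <- phi - mat_shift(phi, 0L, -1L)
  dpc <- mat_shift(phi, 0L, 1L) - phi
  list(plus = sqrt(pmax(dmr, 0)^2 + pmin(dpr, 0)^2 +
                   pmax(dmc, 0)^2 + pmin(dpc, 0)^2),
       minus = sqrt(pmin(dmr, 0)^2 + pmax(dpr, 0)^2 +
                    pmin(dmc, 0)^2 + pmax(dpc, 0)^2))
}

# Mean curvature div(grad(phi)/|grad(phi)|) by central differences.
curvature <- function(phi, floor_grad = 1e-8) {
  g <- grad_central(phi)
  pr <- g$gr; pc <- g$gc
  prr <- mat_shift(phi, 1L, 0L) - 2 * phi + mat_shift(phi, -1L, 0L)
  pcc <- mat_shift(phi, 0L, 1L) - 2 * phi + mat_shift(phi, 0L, -1L)
  prc <- (mat_shift(phi, 1L, 1L) - mat_shift(phi, 1L, -1L) -
          mat_shift(phi, -1L, 1L) + mat_shift(phi, -1L, -1L)) / 4
  num <- prr * pc^2 - 2 * pr * pc * prc + pcc * pr^2
  den <- (pr^2 + pc^2)^1.5
  num / pmax(den, floor_grad)
}

#' One explicit step of the region-coded geometric active contour
#'
#' Updates `phi <- phi + dt * (-k |grad phi| + kappa1(n) delta(phi) curv +
#' kappa2 delta(phi))` with the level set positive inside: a speed code of
#' -1 balloons the front outward at unit speed, +1 pulls it inward, 0
#' leaves the balloon off. The balloon term uses the entropy-satisfying
#' Godunov upwind gradient; curvature uses central differences with the
#' gradient magnitude floored at 1e-8.
#'
#' @param phi signed level set.
#' @param k speed-code matrix from [build_speed_map()].
#' @param params a [correction_params()].
#' @param n iteration number (drives the length weight `kappa1_factor * n`,
#'   saturating at `kappa1_cap`).
#' @return Updated phi.
#' @export
gac_step <- function(phi, k, params = correction_params(), n = 1L) {
  stopifnot(identical(dim(phi), dim(k)), all(is.finite(phi)))
  a <- -k                               # outward normal speed
  uw <- upwind_gradients(phi)
  balloon <- ifelse(a > 0, a * uw$minus, a * uw$plus)
  kappa1 <- min(params$kappa1_factor * n, params$kappa1_cap)
  del <- dirac_eps(phi, params$eps1)
  out <- phi + params$dt *
    (balloon + kappa1 * del * curvature(phi) +
     params$area_term_sign * params$kappa2 * del)
  if (!all(is.finite(out))) {
    stop("non-finite level set after gac_step (n = ", n, ")")
  }
  out
}

#' Gaussian regularization of the level set
#'
#' Convolution with a unit-sum Gaussian kernel (replicate boundary),
#' applied after every contour step; the smoothed field is the next
#' iteration's level set.
#'
#' @param phi numeric matrix.
#' @param sigma1 standard deviation, pixels.
#' @return Smoothed matrix.
#' @export
gaussian_regularize <- function(phi, sigma1 = 1) {
  stopifnot(sigma1 > 0)
  conv2_replicate(phi, gaussian_kernel(sigma1))
}

#' Correct a defective lung boundary
#'
#' Evolves the region-coded contour from the current mask until the
#' fraction of sign-changing pixels stays below `tol` for 5 consecutive
#' iterations (or `max_iters`). Non-defective boundary pixels are anchored
#' by their zero speed code; inside defective blocks the balloon force
#' refills the indentation left by a juxtapleural nodule, restrained by
#' the growing length term.
#'
#' @param mask airway-excluded 0/1 lung mask.
#' @param stats a [detect_defective_blocks()] result for `mask`.
#' @param grid block grid; defaults to `stats$grid`.
#' @param params a [correction_params()].
#' @return Object of class `boundary_correction`: list with `mask`
#'   (corrected, from `phi > 0`), `phi`, `converged`, `iterations`, and
#'   `trace` (per-iteration sign-change fractions).
#' @export
correct_boundary <- function(mask, stats, grid = stats$grid,
                             params = correction_params()) {
  m <- as_mask(mask)
  k <- build_speed_map(m, stats, grid)
  phi <- init_correction_levelset(m, params$sigma1)
  npix <- length(phi)
  trace <- numeric(0)
  stable <- 0L
  converged <- FALSE
  for (n in seq_len(params$max_iters)) {
    phi_new <- gaussian_regularize(gac_step(phi, k, params, n), params$sigma1)
    # amplitude limiting: the level set is an indicator-like field; without
    # it the balloon term grows phi without bound and the smoothed interior
    # drags the zero crossing outward
    phi_new <- pmin(pmax(phi_new, -2), 2)
    trace[n] <- sum((phi_new > 0) != (phi > 0)) / npix
    phi <- phi_new
    stable <- if (trace[n] < params$tol) stable + 1L else 0L
    if (stable >= 5L) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("boundary correction did not stabilize in ", params$max_iters,
            " iterations")
  }
  structure(list(mask = as_mask(phi > 0), phi = phi, converged = converged,
                 iterations = length(trace), trace = trace),
            class = "boundary_correction")
}

#' @export
print.boundary_correction <- function(x, ...) {
  cat("boundary correction:", x$iterations, "iterations;",
      if (x$converged) "stable" else "NOT stable", ";",
      sum(x$mask), "foreground px\n")
  invisible(x)
}

#' Extract contour coordinates for overlay export
#'
#' Boundary pixel coordinates of a mask, grouped by 8-connected component,
#' suitable for JSON export of the evolving contour.
#'
#' @param mask 0/1 matrix.
#' @return List of matrices with columns `row`, `col`.
#' @export
contour_polylines <- function(mask) {
  b <- extract_boundary(mask)
  lab <- label_regions(b)
  lapply(lab$region_ids, function(id) {
    xy <- which(lab$labels == id, arr.ind = TRUE)
    colnames(xy) <- c("row", "col")
    xy
  })
}
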