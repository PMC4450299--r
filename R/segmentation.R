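#' Parameters for the convex global+local segmentation
#'
#' The energy combines a global two-mean (Chan-Vese) data term, a local
#' binary fitting (LBF) data term and a total-variation length term weighted
#' by the binary edge indicator. The binary indicator also acts as an
#' adaptive weight: pixels flagged as edges carry the global term with
#' weight `alpha_prime`, non-edge pixels carry the local term with weight
#' `beta_prime`.
#'
#' @param alpha_prime weight of the global data term at edge pixels.
#' @param beta_prime weight of the local data term at non-edge pixels.
#' @param lam split-Bregman penalty (lambda); larger values tie the
#'   auxiliary field more tightly to the gradient of phi.
#' @param mu data-term weight; default `3 * lam`.
#' @param omega standard deviation of the LBF Gaussian window, pixels; the
#'   window spans `(4*omega + 1)^2` pixels.
#' @param eps regularization width of the smoothed Heaviside/Dirac used in
#'   the nonconvex-model helpers ([heaviside_eps()], [dirac_eps()]). The
#'   convex solver splits regions with `M1 = phi, M2 = 1 - phi` directly.
#' @param hu_init_threshold HU threshold for the default initialization
#'   (lung parenchyma is radiolucent, so `phi = 1` below the threshold).
#' @param max_outer_iters,tol outer-loop controls; convergence is declared
#'   when the mean absolute change of phi per outer iteration drops below
#'   `tol`.
#' @param n_inner Gauss-Seidel sweeps per coefficient refresh.
#' @param invert_edge_map use `1 - g*` in the length-term weight (see
#'   [edge_indicator()]).
#' @param normalize_intensity min-max rescale intensities to `[0, 1]` before
#'   computing region statistics, so the default weights are balanced
#'   regardless of the HU range.
#' @return Object of class `seg_params`.
#' @export
seg_params <- function(alpha_prime = 0.9, beta_prime = 0.1,
                       lam = 1e3, mu = 3 * lam, omega = 1, eps = 1,
                       hu_init_threshold = -500,
                       max_outer_iters = 200L, tol = 1e-4,
                       n_inner = 1L, invert_edge_map = TRUE,
                       normalize_intensity = TRUE) {
  stopifnot(alpha_prime > 0, beta_prime > 0, lam > 0, mu > 0,
            omega > 0, eps > 0, max_outer_iters >= 1, tol > 0, n_inner >= 1)
  structure(list(alpha_prime = alpha_prime, beta_prime = beta_prime,
                 lam = lam, mu = mu, omega = omega, eps = eps,
                 hu_init_threshold = hu_init_threshold,
                 max_outer_iters = as.integer(max_outer_iters), tol = tol,
                 n_inner = as.integer(n_inner),
                 invert_edge_map = invert_edge_map,
                 normalize_intensity = normalize_intensity),
            class = "seg_params")
}

#' Smoothed Heaviside and Dirac functions
#'
#' The arctangent regularizations `H_eps(x) = (1 + (2/pi) atan(x/eps)) / 2`
#' and its derivative `delta_eps(x) = eps / (pi (eps^2 + x^2))`, used by the
#' nonconvex level-set formulation and by the correction contour.
#'
#' @param x numeric.
#' @param eps regularization width.
#' @return Numeric of the same shape.
#' @export
heaviside_eps <- function(x, eps = 1) 0.5 * (1 + (2 / pi) * atan(x / eps))

#' @rdname heaviside_eps
#' @export
dirac_eps <- function(x, eps = 1) eps / (pi * (eps^2 + x^2))

#' Threshold initialization of the segmentation level set
#'
#' `phi = 1` where the image is below the HU threshold (radiolucent lung),
#' 0 elsewhere.
#'
#' @param image HU matrix.
#' @param hu_threshold HU cutoff; default -500.
#' @return 0/1 numeric matrix (a valid `[0,1]` level set).
#' @export
init_levelset <- function(image, hu_threshold = -500) {
  stopifnot(is.matrix(image))
  phi <- matrix(as.numeric(image < hu_threshold), nrow(image), ncol(image))
  if (all(phi == 0) || all(phi == 1)) {
    warning("degenerate initialization: threshold ", hu_threshold,
            " puts every pixel on one side")
  }
  phi
}

#' Global region means under a relaxed membership
#'
#' Weighted means of the image inside (`c1`) and outside (`c2`) the region,
#' with membership `M1 = phi` (or `H_eps(phi)` if `eps` is given) and
#' `M2 = 1 - M1`.
#'
#' @param image numeric matrix.
#' @param phi membership matrix in `[0, 1]`; with `eps` given, a signed
#'   level set (any range) passed through the smoothed Heaviside instead,
#'   as in the nonconvex formulation.
#' @param eps if non-NULL, pass phi through [heaviside_eps()] first.
#' @return Named numeric vector `c(c1, c2)`.
#' @export
region_means <- function(image, phi, eps = NULL) {
  stopifnot(identical(dim(image), dim(phi)))
  if (is.null(eps)) stopifnot(min(phi) >= 0, max(phi) <= 1)
  m1 <- if (is.null(eps)) phi else heaviside_eps(phi, eps)
  m2 <- 1 - m1
  wmean <- function(w) {
    sw <- sum(w)
    if (sw < 1e-12) {
      warning("membership weight sum ~ 0; falling back to the global mean")
      return(mean(image))
    }
    sum(w * image) / sw
  }
  c(c1 = wmean(m1), c2 = wmean(m2))
}

#' Local fitted intensities and fit energies (LBF terms)
#'
#' Local means `f_i = K * (M_i I) / K * M_i` over a unit-sum Gaussian
#' window of size `(4*omega + 1)^2`, and the pointwise fit energies
#' `e_i(x) = sum_y K(y - x) (I(x) - f_i(y))^2`, expanded as
#' `e_i = I^2 (K*1) - 2 I (K*f_i) + K*(f_i^2)`.
#'
#' Pixels where the membership-weight denominator vanishes take the global
#' region mean `c_i` instead (reported once per call).
#'
#' @param image numeric matrix.
#' @param phi membership in `[0, 1]`.
#' @param omega Gaussian window standard deviation, pixels.
#' @param eps optional Heaviside width as in [region_means()].
#' @param c_fallback optional `c(c1, c2)` used at degenerate pixels;
#'   defaults to [region_means()] of the inputs.
#' @return Object of class `region_fits`: list with matrices `f1`, `f2`,
#'   `e1`, `e2`.
#' @export
local_fits <- function(image, phi, omega = 1, eps = NULL, c_fallback = NULL) {
  stopifnot(omega > 0, identical(dim(image), dim(phi)))
  if (is.null(c_fallback)) {
    c_fallback <- suppressWarnings(region_means(image, phi, eps))
  }
  m1 <- if (is.null(eps)) phi else heaviside_eps(phi, eps)
  m2 <- 1 - m1
  k <- gaussian_kernel(omega, 4 * ceiling(omega) + 1)
  fit_one <- function(m, cf) {
    num <- conv2_replicate(m * image, k)
    den <- conv2_replicate(m, k)
    bad <- den < 1e-12
    f <- num / pmax(den, 1e-12)
    if (any(bad)) {
      f[bad] <- cf
      message("local_fits: ", sum(bad),
              " pixel(s) with vanishing membership; substituted region mean")
    }
    f
  }
  f1 <- fit_one(m1, c_fallback[["c1"]])
  f2 <- fit_one(m2, c_fallback[["c2"]])
  ksum <- conv2_replicate(matrix(1, nrow(image), ncol(image)), k)
  energy <- function(f) {
    image^2 * ksum - 2 * image * conv2_replicate(f, k) + conv2_replicate(f^2, k)
  }
  structure(list(f1 = f1, f2 = f2, e1 = energy(f1), e2 = energy(f2)),
            class = "region_fits")
}

#' Data-attachment speed field
#'
#' `s = -(F1 + F2)` with `F1 = alpha' g* (-(I - c1)^2 + (I - c2)^2)` and
#' `F2 = beta' (1 - g*) (-e1 + e2)`: edge pixels carry only the global term,
#' non-edge pixels only the local term. Negative `s` favors membership
#' (phi rises), positive `s` favors the complement.
#'
#' @param image numeric matrix (same intensity scale as `c1`, `c2`, fits).
#' @param c1,c2 global region means.
#' @param fits a [local_fits()] result.
#' @param gstar an [edge_indicator()] result (or 0/1 matrix).
#' @param params a [seg_params()].
#' @return Numeric matrix `s`.
#' @export
data_speed <- function(image, c1, c2, fits, gstar, params = seg_params()) {
  g <- if (inherits(gstar, "edge_map")) gstar$values else as_mask(gstar)
  stopifnot(identical(dim(image), dim(g)))
  f1 <- params$alpha_prime * g * (-(image - c1)^2 + (image - c2)^2)
  f2 <- params$beta_prime * (1 - g) * (-fits$e1 + fits$e2)
  -(f1 + f2)
}

#' One Gauss-Seidel sweep of the split-Bregman phi subproblem
#'
#' Sweeps the image in raster (row-major) order, using freshly updated
#' neighbor values immediately, and clamps each result to `[0, 1]`. Each
#' update is the exact minimizer of the discrete energy
#' `lambda/2 ||(d - b) - grad(phi)||^2 + mu <phi, s>` in that coordinate,
#' which makes the sweep a monotone descent step.
#'
#' @param phi level set in `[0, 1]`.
#' @param state split-Bregman state: list with matrices `dx`, `dy`, `bx`,
#'   `by` (see [bregman_state()]).
#' @param s data-speed matrix.
#' @param params a [seg_params()] (supplies `mu / lam`).
#' @return Updated phi matrix, clamped to `[0, 1]`.
#' @export
gauss_seidel_sweep <- function(phi, state, s, params = seg_params()) {
  stopifnot(identical(dim(phi), dim(s)))
  if (!all(is.finite(s))) stop("non-finite data speed")
  gs_sweep_cpp(phi, state$dx - state$bx, state$dy - state$by, s,
               params$mu / params$lam)
}

#' Zero-initialized split-Bregman auxiliary state
#'
#' @param nrow,ncol field dimensions.
#' @return List of zero matrices `dx`, `dy`, `bx`, `by` and `iteration = 0`.
#' @export
bregman_state <- function(nrow, ncol) {
  z <- matrix(0, nrow, ncol)
  list(dx = z, dy = z, bx = z, by = z, iteration = 0L)
}

#' Soft-threshold (shrink) operator
#'
#' For a scalar field, `shrink(z, theta) = sign(z) * max(|z| - theta, 0)`,
#' the proximal operator of `theta * |.|`. For a 2-vector field (`zy`
#' given), the magnitude `sqrt(zx^2 + zy^2)` is shrunk and the direction
#' kept; zero vectors map to zero.
#'
#' @param zx numeric; the scalar field, or the first vector component.
#' @param zy optional second vector component.
#' @param theta non-negative threshold (scalar or same-shape field).
#' @return The shrunk field, or a list `(x, y)` of components.
#' @export
shrink <- function(zx, zy = NULL, theta) {
  stopifnot(all(theta >= 0))
  if (is.null(zy)) {
    return(sign(zx) * pmax(abs(zx) - theta, 0))
  }
  mag <- sqrt(zx^2 + zy^2)
  scale <- ifelse(mag > 0, pmax(mag - theta, 0) / pmax(mag, 1e-300), 0)
  list(x = zx * scale, y = zy * scale)
}

#' Split-Bregman auxiliary and Bregman variable update
#'
#' `d <- shrink(b + grad(phi), g*/lambda)` applied to the 2-vector
#' magnitude pixel-wise, then `b <- b + grad(phi) - d`. Gradients are
#' forward differences with replicate boundary. Where the edge weight is 0
#' the shrink threshold is 0, so `d` tracks `b + grad(phi)` exactly and the
#' new `b` is 0 there.
#'
#' @param phi freshly swept level set.
#' @param state current split-Bregman state.
#' @param gstar edge map (weight of the length term).
#' @param lam split-Bregman penalty.
#' @return Updated state list.
#' @export
bregman_update <- function(phi, state, gstar, lam) {
  g <- if (inherits(gstar, "edge_map")) gstar$values else as_mask(gstar)
  gr <- grad_forward(phi)
  th <- g / lam
  sh <- shrink(state$bx + gr$gr, state$by + gr$gc, th)
  list(dx = sh$x, dy = sh$y,
       bx = state$bx + gr$gr - sh$x,
       by = state$by + gr$gc - sh$y,
       iteration = state$iteration + 1L)
}

# Discrete convex energy, for diagnostics: TV(g*) + mu <phi, s>.
glg_energy <- function(phi, s, gstar, mu) {
  g <- if (inherits(gstar, "edge_map")) gstar$values else gstar
  gr <- grad_forward(phi)
  sum(g * sqrt(gr$gr^2 + gr$gc^2)) + mu * sum(phi * s)
}

#' Convex global+local lung-field segmentation by split Bregman
#'
#' Alternates coefficient refreshes (global means, local fits, data speed)
#' with Gauss-Seidel sweeps and shrink/Bregman updates until the mean
#' absolute change of phi per outer iteration falls below `tol`. The final
#' mask is the 0.5 superlevel set of phi.
#'
#' @param image HU matrix.
#' @param params a [seg_params()].
#' @param edge_params an [edge_params()].
#' @param init optional initial phi in `[0, 1]`; defaults to
#'   [init_levelset()] at `params$hu_init_threshold`.
#' @return Object of class `glg_segmentation`: list with `mask` (0/1
#'   matrix), `phi`, `converged`, `iterations`, `phi_change` and `energy`
#'   traces, `phi_range_ok` (TRUE iff phi stayed in `[0,1]` after every
#'   sweep), region means `c1`, `c2`, and the edge map `gstar`.
#' @export
glg_segment <- function(image, params = seg_params(),
                        edge_params = lungfield::edge_params(),
                        init = NULL) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  phi <- if (is.null(init)) {
    init_levelset(image, params$hu_init_threshold)
  } else {
    stopifnot(identical(dim(init), dim(image)), min(init) >= 0, max(init) <= 1)
    init
  }
  img <- image
  if (params$normalize_intensity) {
    rng <- range(image)
    img <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  }
  gstar <- edge_indicator(image, edge_params, invert = params$invert_edge_map)
  state <- bregman_state(nrow(image), ncol(image))
  changes <- numeric(0)
  energies <- numeric(0)
  range_ok <- TRUE
  converged <- FALSE
  cm <- c(c1 = NA_real_, c2 = NA_real_)
  for (it in seq_len(params$max_outer_iters)) {
    cm <- region_means(img, phi)
    fits <- local_fits(img, phi, params$omega, c_fallback = cm)
    s <- data_speed(img, cm[["c1"]], cm[["c2"]], fits, gstar, params)
    phi_old <- phi
    for (k in seq_len(params$n_inner)) {
      phi <- gauss_seidel_sweep(phi, state, s, params)
      if (min(phi) < 0 || max(phi) > 1) range_ok <- FALSE
    }
    state <- bregman_update(phi, state, gstar, params$lam)
    changes[it] <- mean(abs(phi - phi_old))
    energies[it] <- glg_energy(phi, s, gstar, params$mu)
    if (changes[it] < params$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("glg_segment did not converge in ", params$max_outer_iters,
            " outer iterations (last mean |dphi| = ",
            format(tail(changes, 1)), ")")
  }
  structure(list(mask = as_mask(phi > 0.5), phi = phi,
                 converged = converged, iterations = length(changes),
                 phi_change = changes, energy = energies,
                 phi_range_ok = range_ok,
                 c1 = cm[["c1"]], c2 = cm[["c2"]], gstar = gstar),
            class = "glg_segmentation")
}

#' @export
print.glg_segmentation <- function(x, ...) {
  cat("GLg segmentation:", nrow(x$mask), "x", ncol(x$mask), "px;",
      x$iterations, "outer iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  foreground:", sum(x$mask), "px; c1 =", format(x$c1),
      " c2 =", format(x$c2), "\n")
  invisible(x)
}

#' Fill interior holes of a binary mask
#'
#' Background 4-connected components not reaching the image border are set
#' to foreground.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- as_mask(mask)
  bg <- 1L - m
  lab <- label_cpp(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  hole <- bg == 1L & !(lab %in% border)
  m[hole] <- 1L
  m
}

#' Remove mask components touching the image border
#'
#' Density-based lung-field extraction necessarily captures the air outside
#' the body; those components touch the image border and are removed here
#' before hole filling.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix without border-connected components.
#' @export
remove_background <- function(mask) {
  m <- as_mask(mask)
  lab <- label_cpp(m, 8L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  m[lab %in% border] <- 0L
  m
}
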