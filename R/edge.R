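#' Parameters for the structure-tensor edge indicator
#'
#' @param sigma standard deviation of the tensor-smoothing Gaussian, pixels.
#' @param kappa dimensionless weight on the standard deviation in the
#'   statistical threshold `T_c = mean(T) + kappa * sd(T)`. Negative values
#'   lower the threshold below the mean.
#' @param kernel_size odd side length of the smoothing kernel. The default
#'   3 is deliberately narrow relative to `sigma = 3` (the kernel is
#'   truncated and renormalized to unit sum); widen it for smoother tensors.
#' @return An object of class `edge_params`.
#' @export
edge_params <- function(sigma = 3, kappa = -0.05, kernel_size = 3L) {
  stopifnot(sigma > 0, kernel_size >= 3, kernel_size %% 2 == 1)
  structure(list(sigma = sigma, kappa = kappa,
                 kernel_size = as.integer(kernel_size)),
            class = "edge_params")
}

#' Structure tensor of an image
#'
#' Gaussian-smoothed outer product of the central-difference image
#' gradients: entries `jxx = K * Ix^2`, `jxy = K * Ix Iy`, `jyy = K * Iy^2`.
#' The per-pixel 2x2 matrix is symmetric positive semidefinite.
#'
#' @param image numeric matrix, at least as large as the kernel.
#' @param params an [edge_params()].
#' @return An object of class `tensor_field`: list with matrices
#'   `jxx`, `jxy`, `jyy`.
#' @export
structure_tensor <- function(image, params = edge_params()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (nrow(image) < params$kernel_size || ncol(image) < params$kernel_size) {
    stop("image smaller than the smoothing kernel")
  }
  k <- gaussian_kernel(params$sigma, params$kernel_size)
  g <- grad_central(image)
  structure(list(jxx = conv2_replicate(g$gr * g$gr, k),
                 jxy = conv2_replicate(g$gr * g$gc, k),
                 jyy = conv2_replicate(g$gc * g$gc, k)),
            class = "tensor_field")
}

#' Per-pixel eigenvalue difference of a 2x2 tensor field
#'
#' For a symmetric 2x2 matrix the eigenvalue gap has the closed form
#' `sqrt((jxx - jyy)^2 + 4 jxy^2)`; it is large on edges (one dominant
#' gradient direction) and near zero in flat regions.
#'
#' @param tensor a [structure_tensor()] result.
#' @return Non-negative numeric matrix.
#' @export
eigen_difference <- function(tensor) {
  stopifnot(inherits(tensor, "tensor_field"))
  sqrt((tensor$jxx - tensor$jyy)^2 + 4 * tensor$jxy^2)
}

#' Statistical threshold on the eigenvalue-difference field
#'
#' `T_c = mean(T) + kappa * sd(T)` over all pixels, with the population
#' (divide-by-N) standard deviation.
#'
#' @param t_field numeric matrix (or vector) of eigenvalue differences.
#' @param kappa threshold weight.
#' @return Scalar threshold.
#' @export
edge_threshold <- function(t_field, kappa) {
  v <- as.numeric(t_field)
  if (length(v) == 0L) stop("empty field")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  m + kappa * s
}

#' Binary structure-tensor edge indicator
#'
#' Marks pixels whose tensor eigenvalue gap exceeds the statistical
#' threshold: `g* = 1` where `T > T_c`, else 0 (ties map to 0). With
#' `invert = TRUE` the coding is flipped, for downstream weights that
#' expect edges to be 0.
#'
#' @param image numeric matrix.
#' @param params an [edge_params()].
#' @param invert flip the 0/1 coding.
#' @return Object of class `edge_map`: list with `values` (0/1 integer
#'   matrix) and `threshold_used`.
#' @export
edge_indicator <- function(image, params = edge_params(), invert = FALSE) {
  tf <- structure_tensor(image, params)
  tt <- eigen_difference(tf)
  tc <- edge_threshold(tt, params$kappa)
  v <- matrix(as.integer(tt > tc), nrow(image), ncol(image))
  if (invert) v <- 1L - v
  structure(list(values = v, threshold_used = tc, inverted = invert),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat("edge map:", nrow(x$values), "x", ncol(x$values), "px,",
      sum(x$values), "flagged, threshold", format(x$threshold_used), "\n")
  invisible(x)
}

#' Classical gradient-magnitude edge function
#'
#' The smooth baseline `g = 1 / (1 + |grad(G_sigma * I)|^2)`, valued in
#' (0, 1]: near 1 in flat regions, small on strong edges. Provided for
#' comparison with the binary [edge_indicator()].
#'
#' @param image numeric matrix.
#' @param sigma Gaussian pre-smoothing standard deviation, pixels.
#' @return Numeric matrix in (0, 1].
#' @export
classical_edge_function <- function(image, sigma = 3) {
  stopifnot(is.matrix(image), sigma > 0)
  size <- 2L * ceiling(3 * sigma) + 1L
  fit <- min(dim(image)) - (1L - min(dim(image)) %% 2L)  # largest odd fit
  sm <- conv2_replicate(image, gaussian_kernel(sigma, min(size, fit)))
  g <- grad_central(sm)
  1 / (1 + g$gr^2 + g$gc^2)
}

#' Write an edge map (or any binary mask) as an 8-bit PNG
#'
#' @param x an `edge_map`, or a 0/1 matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  m <- if (inherits(x, "edge_map")) x$values else as_mask(x)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}
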