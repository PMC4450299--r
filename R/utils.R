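#' Dice similarity coefficient between two binary masks
#'
#' @param a,b binary matrices (0/1 or logical) of identical shape.
#' @return Scalar in `[0, 1]`; 1 for identical masks. Two empty masks have
#'   Dice 1 by convention.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Symmetric Hausdorff distance between two mask boundaries
#'
#' Computed on the 1-pixel boundaries of the two masks, in pixel units
#' (Euclidean). Intended for small images; the pairwise distance matrix is
#' formed explicitly.
#'
#' @param a,b binary matrices of identical shape.
#' @return Scalar distance in pixels; 0 if boundaries coincide.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  pa <- which(extract_boundary(a) == 1L, arr.ind = TRUE)
  pb <- which(extract_boundary(b) == 1L, arr.ind = TRUE)
  if (nrow(pa) == 0L && nrow(pb) == 0L) return(0)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(Inf)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  directed <- function(m) max(apply(m, 1, min))
  sqrt(max(directed(d2), directed(t(d2))))
}

# Coerce logical/numeric input to an integer 0/1 matrix.
as_mask <- function(x) {
  stopifnot(is.matrix(x))
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

# Shift a matrix by (dr, dc) with replicate (edge-clamp) boundary:
# result[i, j] = x[clamp(i + dr), clamp(j + dc)].
mat_shift <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  ri <- pmin(pmax(seq_len(n) + dr, 1L), n)
  ci <- pmin(pmax(seq_len(m) + dc, 1L), m)
  x[ri, ci, drop = FALSE]
}

# Central-difference gradients with replicate boundary.
# gr: derivative along rows, gc: along columns.
grad_central <- function(x) {
  list(gr = (mat_shift(x, 1L, 0L) - mat_shift(x, -1L, 0L)) / 2,
       gc = (mat_shift(x, 0L, 1L) - mat_shift(x, 0L, -1L)) / 2)
}

# Forward-difference gradients with replicate boundary (last row/col -> 0).
grad_forward <- function(x) {
  list(gr = mat_shift(x, 1L, 0L) - x,
       gc = mat_shift(x, 0L, 1L) - x)
}

#' Truncated, unit-sum Gaussian kernel
#'
#' @param sigma standard deviation in pixels.
#' @param size odd kernel side length; default covers +/- 3 sigma.
#' @return A `size x size` matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, size = 2L * ceiling(3 * sigma) + 1L) {
  stopifnot(sigma > 0, size >= 1, size %% 2 == 1)
  r <- (size - 1L) / 2L
  d <- seq(-r, r)
  k <- outer(d, d, function(u, v) exp(-(u^2 + v^2) / (2 * sigma^2)))
  k / sum(k)
}

# 2D convolution with replicate boundary handling (EBImage FFT filter).
conv2_replicate <- function(x, kern) {
  stopifnot(is.matrix(x), is.matrix(kern))
  if (nrow(x) < nrow(kern) || ncol(x) < ncol(kern)) {
    stop("image (", nrow(x), "x", ncol(x), ") smaller than kernel (",
         nrow(kern), "x", ncol(kern), ")")
  }
  out <- EBImage::filter2(x, kern, boundary = "replicate")
  matrix(as.numeric(out), nrow(x), ncol(x))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
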