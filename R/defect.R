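#' Minimum enclosing rectangle of a mask
#'
#' @param mask nonempty 0/1 matrix.
#' @return Named integer vector `c(row0, col0, height, width)` (1-based
#'   origin, closed extent of `height` rows and `width` columns).
#' @export
min_enclosing_rect <- function(mask) {
  m <- as_mask(mask)
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no enclosing rectangle")
  r <- range(idx[, 1]); c <- range(idx[, 2])
  c(row0 = r[1], col0 = c[1], height = r[2] - r[1] + 1L,
    width = c[2] - c[1] + 1L)
}

#' Partition a rectangle into the block grid
#'
#' A 10 x 10 grid when the mask has two or more subregions, 2 x 2 when
#' there is a single subregion (so blocks stay large enough for the
#' box-counting fit). Uneven divisions push the remainder pixels into the
#' last block row/column; the blocks tile the rectangle exactly.
#'
#' @param rect rectangle as returned by [min_enclosing_rect()].
#' @param n_subregions number of 8-connected mask components.
#' @return Object of class `block_grid`: list with `rect`, `n_rows`,
#'   `n_cols`, and integer break vectors `row_breaks`, `col_breaks`
#'   (block k spans rows `row_breaks[k] .. row_breaks[k+1] - 1`).
#' @export
make_block_grid <- function(rect, n_subregions) {
  n_blocks <- if (n_subregions >= 2) 10L else 2L
  h <- rect[["height"]]; w <- rect[["width"]]
  if (h < n_blocks || w < n_blocks) {
    stop("rectangle ", h, "x", w, " too small for a ", n_blocks, "x",
         n_blocks, " grid; consider the 2x2 fallback")
  }
  breaks <- function(origin, extent) {
    side <- extent %/% n_blocks
    b <- origin + side * (0:(n_blocks - 1L))
    c(b, origin + extent)      # last block absorbs the remainder
  }
  structure(list(rect = rect, n_rows = n_blocks, n_cols = n_blocks,
                 row_breaks = breaks(rect[["row0"]], h),
                 col_breaks = breaks(rect[["col0"]], w)),
            class = "block_grid")
}

block_extent <- function(grid, bi, bj) {
  list(rows = grid$row_breaks[bi]:(grid$row_breaks[bi + 1L] - 1L),
       cols = grid$col_breaks[bj]:(grid$col_breaks[bj + 1L] - 1L))
}

#' Extract the 1-pixel boundary of a mask
#'
#' Foreground pixels with at least one background 4-neighbor; pixels on the
#' image border count out-of-image as background.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix of boundary pixels.
#' @export
extract_boundary <- function(mask) {
  m <- as_mask(mask)
  pad <- function(dr, dc) {
    n <- nrow(m); mm <- ncol(m)
    out <- matrix(0L, n, mm)
    rs <- seq_len(n) + dr; cs <- seq_len(mm) + dc
    ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= mm
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nb_min <- pmin(pad(1L, 0L), pad(-1L, 0L), pad(0L, 1L), pad(0L, -1L))
  as_mask(m == 1L & nb_min == 0L)
}

#' Flag blocks containing boundary pixels
#'
#' @param grid a [make_block_grid()].
#' @param boundary boundary mask from [extract_boundary()] (full image
#'   coordinates).
#' @return Logical `n_rows x n_cols` matrix.
#' @export
boundary_blocks <- function(grid, boundary) {
  b <- as_mask(boundary)
  flags <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (bi in seq_len(grid$n_rows)) {
    for (bj in seq_len(grid$n_cols)) {
      ext <- block_extent(grid, bi, bj)
      flags[bi, bj] <- sum(b[ext$rows, ext$cols]) > 0L
    }
  }
  flags
}

#' Box-counting fractal dimension of a binary block
#'
#' Covers the block with square grids of side `s` (powers of two from the
#' largest power not exceeding the block side down to 2, anchored at the
#' block's top-left corner), counts occupied boxes `N(s)`, and returns the
#' least-squares slope of `log N(s)` against `log(1/s)`. Roughly 1 for a
#' smooth curve, 2 for an area-filling set, 0 for an isolated point.
#'
#' @param block_boundary 0/1 matrix of the boundary pixels inside one block.
#' @return Scalar dimension estimate.
#' @export
box_counting_dimension <- function(block_boundary) {
  b <- as_mask(block_boundary)
  if (sum(b) == 0L) stop("block contains no boundary pixels")
  side <- min(dim(b))
  sizes <- 2^(floor(log2(side)):1)
  if (length(sizes) < 3L) {
    stop("block of ", nrow(b), "x", ncol(b),
         " px supports fewer than 3 box scales")
  }
  counts <- vapply(sizes, function(s) {
    idx <- which(b == 1L, arr.ind = TRUE)
    boxes <- paste((idx[, 1] - 1L) %/% s, (idx[, 2] - 1L) %/% s)
    length(unique(boxes))
  }, numeric(1))
  unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
}

#' Statistical threshold on boundary-block fractal dimensions
#'
#' `T_f = mean(d) + multiplier * sd(d)` with the sample (N-1) standard
#' deviation; the default multiplier 1 is the plain mean-plus-one-sd rule.
#'
#' @param dims numeric vector of at least 2 block dimensions.
#' @param multiplier scale factor on the standard deviation.
#' @return Scalar threshold.
#' @export
defect_threshold <- function(dims, multiplier = 1) {
  if (length(dims) < 2L) stop("need at least 2 boundary blocks")
  mean(dims) + multiplier * sd(dims)
}

#' Detect defective boundary blocks by fractal dimension
#'
#' Full pipeline: minimum enclosing rectangle of the mask, block grid,
#' boundary blocks, per-block box-counting dimension, threshold
#' `T_f = mean + multiplier * sd`, and flags `D > T_f` (strict). A smooth
#' boundary arc has dimension near 1; the jagged indentation left by a
#' carved-out juxtapleural nodule raises the block's dimension above the
#' statistical threshold.
#'
#' @param mask hole-filled, airway-excluded 0/1 lung mask.
#' @param n_subregions number of lung subregions; default counts the
#'   8-connected components of `mask`.
#' @param multiplier threshold multiplier, see [defect_threshold()].
#' @return Object of class `fractal_stats`: list with the `grid`,
#'   `dimensions` (matrix, NA off boundary blocks), `is_boundary`,
#'   `is_defective` (logical matrices), `t_f`, `mean_d`, `sd_d`.
#' @export
detect_defective_blocks <- function(mask, n_subregions = NULL,
                                    multiplier = 1) {
  m <- as_mask(mask)
  if (is.null(n_subregions)) {
    n_subregions <- length(label_regions(m)$region_ids)
  }
  rect <- min_enclosing_rect(m)
  grid <- make_block_grid(rect, n_subregions)
  boundary <- extract_boundary(m)
  is_boundary <- boundary_blocks(grid, boundary)
  dims <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (bi in seq_len(grid$n_rows)) {
    for (bj in seq_len(grid$n_cols)) {
      if (!is_boundary[bi, bj]) next
      ext <- block_extent(grid, bi, bj)
      dims[bi, bj] <- box_counting_dimension(boundary[ext$rows, ext$cols])
    }
  }
  dvals <- dims[is_boundary]
  t_f <- defect_threshold(dvals, multiplier)
  structure(list(grid = grid, dimensions = dims, is_boundary = is_boundary,
                 is_defective = !is.na(dims) & dims > t_f,
                 t_f = t_f, mean_d = mean(dvals), sd_d = sd(dvals)),
            class = "fractal_stats")
}

#' @export
print.fractal_stats <- function(x, ...) {
  cat("fractal boundary stats:", sum(x$is_boundary), "boundary blocks,",
      sum(x$is_defective), "defective; T_f =", format(x$t_f),
      "(mean", format(x$mean_d), "+ sd", format(x$sd_d), ")\n")
  invisible(x)
}

#' Export fractal statistics as JSON
#'
#' @param stats a [detect_defective_blocks()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fractal_json <- function(stats, path) {
  obj <- list(rect = as.list(stats$grid$rect),
              n_rows = stats$grid$n_rows, n_cols = stats$grid$n_cols,
              t_f = stats$t_f, mean_d = stats$mean_d, sd_d = stats$sd_d,
              dimensions = stats$dimensions,
              is_boundary = stats$is_boundary,
              is_defective = stats$is_defective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
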