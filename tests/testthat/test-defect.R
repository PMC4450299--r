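test_that("minimum enclosing rectangle is the tight bounding box", {
  m <- matrix(0L, 12, 12); m[5, 7] <- 1L
  expect_equal(min_enclosing_rect(m),
               c(row0 = 5, col0 = 7, height = 1, width = 1))
  full <- matrix(1L, 6, 9)
  expect_equal(min_enclosing_rect(full),
               c(row0 = 1, col0 = 1, height = 6, width = 9))
  expect_error(min_enclosing_rect(matrix(0L, 4, 4)), "empty")
  set.seed(61)
  m <- matrix(rbinom(400, 1, 0.1), 20, 20)
  idx <- which(m == 1L, arr.ind = TRUE)
  r <- min_enclosing_rect(m)
  expect_equal(unname(r), c(min(idx[, 1]), min(idx[, 2]),
                            diff(range(idx[, 1])) + 1,
                            diff(range(idx[, 2])) + 1))
})

test_that("block grids tile the rectangle exactly, with fallback to 2x2", {
  rect <- c(row0 = 1, col0 = 1, height = 100, width = 100)
  g <- make_block_grid(rect, n_subregions = 2)
  expect_equal(g$n_rows, 10L)
  expect_equal(diff(g$row_breaks), rep(10, 10))
  g1 <- make_block_grid(rect, n_subregions = 1)
  expect_equal(g1$n_rows, 2L)
  # uneven division: last block absorbs the remainder, union covers rect
  g2 <- make_block_grid(c(row0 = 3, col0 = 5, height = 105, width = 103), 2)
  expect_equal(diff(g2$row_breaks), c(rep(10, 9), 15))
  expect_equal(g2$row_breaks[11] - g2$row_breaks[1], 105)
  expect_equal(g2$col_breaks[11] - g2$col_breaks[1], 103)
  expect_error(make_block_grid(c(row0 = 1, col0 = 1, height = 8, width = 8), 2),
               "2x2")
})

test_that("boundary extraction gives 1-px 4-neighbor boundaries", {
  m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
  b <- extract_boundary(m)
  expect_equal(sum(b), 8)
  expect_equal(b[3, 3], 0L)
  expect_equal(sum(extract_boundary(matrix(0L, 5, 5))), 0)
  d <- disk_fixture(64, 32, 32, 20)
  len <- sum(extract_boundary(d))
  expect_lt(abs(len - 2 * pi * 20) / (2 * pi * 20), 0.12)
})

test_that("boundary blocks are flagged exactly where boundary pixels fall", {
  grid <- make_block_grid(c(row0 = 1, col0 = 1, height = 100, width = 100), 2)
  b <- matrix(0L, 100, 100); b[15, 15] <- 1L     # block (2, 2) only
  flags <- boundary_blocks(grid, b)
  expect_equal(sum(flags), 1)
  expect_true(flags[2, 2])
  expect_equal(sum(boundary_blocks(grid, matrix(0L, 100, 100))), 0)
  d <- disk_fixture(100, 50, 50, 35)
  fl <- boundary_blocks(grid, extract_boundary(d))
  expect_gt(sum(fl), 8)                          # a ring of blocks
})

test_that("box-counting dimension hits its analytic anchors", {
  line <- matrix(0L, 32, 32); line[16, ] <- 1L
  expect_gte(box_counting_dimension(line), 0.95)
  expect_lte(box_counting_dimension(line), 1.05)
  filled <- matrix(1L, 32, 32)
  expect_gte(box_counting_dimension(filled), 1.9)
  expect_lte(box_counting_dimension(filled), 2.1)
  single <- matrix(0L, 32, 32); single[7, 9] <- 1L
  expect_lt(abs(box_counting_dimension(single)), 0.05)
  expect_error(box_counting_dimension(matrix(0L, 32, 32)), "no boundary")
  tiny <- matrix(1L, 4, 4)
  expect_error(box_counting_dimension(tiny), "3 box scales")
})

test_that("defect threshold is mean plus one sample sd", {
  expect_equal(defect_threshold(c(1, 1, 1)), 1)
  expect_equal(defect_threshold(c(1.0, 1.2)), 1.1 + sd(c(1, 1.2)))
  expect_equal(defect_threshold(c(1.0, 1.2)), 1.2414, tolerance = 1e-4)
  expect_error(defect_threshold(1), "at least 2")
  # all-equal dimensions: nothing exceeds the threshold
  expect_true(all(c(1.3, 1.3, 1.3) <= defect_threshold(c(1.3, 1.3, 1.3))))
})

test_that("jagging a straight boundary does not lower its dimension", {
  set.seed(63)
  base <- matrix(0L, 32, 32); base[16, ] <- 1L
  d0 <- box_counting_dimension(base)
  for (i in 1:20) {
    jag <- base
    walk <- cumsum(sample(c(-1L, 1L), 12, TRUE))
    cols <- 10:21
    for (j in seq_along(cols)) {
      lo <- min(16L, 16L + walk[j]); hi <- max(16L, 16L + walk[j])
      jag[lo:hi, cols[j]] <- 1L
    }
    expect_gte(box_counting_dimension(jag), d0 - 0.01)  # fit tolerance
  }
})

test_that("the indentation blocks are flagged with at most two false positives", {
  ph <- phantom_slice(default_phantom_spec())
  mask <- ph$masks$lung_without_nodules
  stats <- detect_defective_blocks(mask)
  indent <- as_mask_int(ph$masks$lung_with_nodules == 1L & mask == 0L)
  # the defective arc: mask-boundary pixels adjacent to the carved region
  arc <- as_mask_int(extract_boundary(mask) == 1L &
                     dilate_by_one(indent) == 1L)
  ib <- boundary_blocks(stats$grid, arc)
  expect_gt(sum(ib & stats$is_boundary), 0)
  # every block holding a piece of the indentation arc is flagged
  expect_true(all(stats$is_defective[ib & stats$is_boundary]))
  expect_lte(sum(stats$is_defective & !ib), 2)
})

test_that("a smooth elliptical boundary yields few statistical flags", {
  ph <- phantom_slice(phantom_spec())            # no nodules
  stats <- detect_defective_blocks(ph$masks$lung_without_nodules)
  expect_lte(sum(stats$is_defective) / sum(stats$is_boundary), 0.10)
})

test_that("flags are invariant under whole-image translation", {
  ph <- phantom_slice(phantom_spec(image_size = 448))
  m <- ph$masks$lung_without_nodules
  s1 <- detect_defective_blocks(m)
  shifted <- matrix(0L, nrow(m) + 20, ncol(m) + 20)
  shifted[8 + seq_len(nrow(m)), 13 + seq_len(ncol(m))] <- m
  s2 <- detect_defective_blocks(shifted)
  expect_equal(s1$dimensions, s2$dimensions)
  expect_identical(s1$is_defective, s2$is_defective)
})

test_that("single-block boundaries surface the threshold precondition", {
  m <- matrix(0L, 60, 60)
  m[25:35, 25:35] <- 1L
  # a small square within one grid cell of its own MER: few boundary blocks
  stats <- try(detect_defective_blocks(m), silent = TRUE)
  # the 11x11 MER cannot host a 10x10 grid of >= 8 px blocks
  expect_true(inherits(stats, "try-error"))
})
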