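test_that("threshold initialization separates radiolucent tissue", {
  expect_warning(p <- init_levelset(matrix(-800, 8, 8), -500), "degenerate")
  expect_true(all(p == 1))
  expect_warning(p <- init_levelset(matrix(0, 8, 8), -500), "degenerate")
  expect_true(all(p == 0))
  ph <- phantom_slice(phantom_spec(image_size = 128, noise_sigma = 0,
                                   trachea_radius = 5))
  phi <- init_levelset(ph$image, -500)
  inside <- ph$masks$lung_without_nodules == 1L | ph$masks$trachea == 1L
  outside_body <- ph$masks$body == 0L
  expect_true(all(phi[inside] == 1))
  expect_true(all(phi[outside_body] == 1))    # outside air is also < -500 HU
  expect_true(all(phi[!inside & !outside_body] == 0))
})

test_that("region means recover the phase values and the equal-weight limit", {
  img <- matrix(c(rep(2, 32), rep(9, 32)), 8, 8)
  phi <- matrix(c(rep(1, 32), rep(0, 32)), 8, 8)
  cm <- region_means(img, phi)
  expect_equal(unname(cm), c(2, 9))
  # signed level set through the Heaviside: indicator limit as eps -> 0
  cm_eps <- region_means(img, 2 * phi - 1, eps = 1e-8)
  expect_equal(unname(cm_eps), c(2, 9), tolerance = 1e-6)
  cm_half <- region_means(img, matrix(0.5, 8, 8))
  expect_equal(unname(cm_half), rep(mean(img), 2))
  set.seed(31)
  img <- matrix(rnorm(64), 8, 8); phi <- matrix(runif(64), 8, 8)
  cm <- region_means(img, phi)
  expect_lt(abs(cm[["c1"]] - sum(phi * img) / sum(phi)), 1e-10)
  expect_lt(abs(cm[["c2"]] - sum((1 - phi) * img) / sum(1 - phi)), 1e-10)
})

test_that("local fits: constant image, degenerate membership, loop oracle", {
  img <- matrix(7, 12, 12)
  fits <- local_fits(img, matrix(runif(144), 12, 12))
  expect_true(all(abs(fits$f1 - 7) < 1e-8) && all(abs(fits$f2 - 7) < 1e-8))
  expect_true(all(abs(fits$e1) < 1e-6) && all(abs(fits$e2) < 1e-6))

  # phi == 1 everywhere: M2 vanishes, fallback path substitutes c2
  set.seed(33)
  img <- matrix(rnorm(144), 12, 12)
  expect_message(fits <- local_fits(img, matrix(1, 12, 12)),
                 "vanishing membership")
  k <- gaussian_kernel(1, 5)
  f1_expect <- conv2_loop(img, k) / conv2_loop(matrix(1, 12, 12), k)
  expect_lt(max(abs(fits$f1 - f1_expect)), 1e-8)

  # e_i against the brute-force double loop over the kernel window
  set.seed(34)
  img <- matrix(rnorm(256), 16, 16)
  phi <- matrix(runif(256), 16, 16)
  fits <- local_fits(img, phi, omega = 1)
  e1_loop <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    acc <- 0
    for (a in -2:2) for (b in -2:2) {
      fy <- fits$f1[clampi(i + a, 16L), clampi(j + b, 16L)]
      acc <- acc + k[a + 3, b + 3] * (img[i, j] - fy)^2
    }
    e1_loop[i, j] <- acc
  }
  expect_lt(max(abs(fits$e1 - e1_loop)), 1e-8)
})

test_that("data speed combines global and local terms per the edge code", {
  img <- matrix(0, 4, 4)
  fits <- structure(list(e1 = matrix(2, 4, 4), e2 = matrix(2, 4, 4)),
                    class = "region_fits")
  s <- data_speed(img, c1 = 0, c2 = 0, fits, matrix(1L, 4, 4))
  expect_true(all(s == 0))
  # g* = 1, I = 0, c1 = 1, c2 = 3: F1 = 0.9 (-1 + 9) = 7.2, s = -7.2
  fits0 <- structure(list(e1 = matrix(0, 4, 4), e2 = matrix(0, 4, 4)),
                     class = "region_fits")
  s <- data_speed(img, 1, 3, fits0, matrix(1L, 4, 4))
  expect_equal(unique(as.numeric(s)), -7.2)
  # g* = 0 carries only the local term
  s <- data_speed(img, 1, 3, structure(list(e1 = matrix(1, 4, 4),
                                            e2 = matrix(5, 4, 4)),
                                       class = "region_fits"),
                  matrix(0L, 4, 4))
  expect_equal(unique(as.numeric(s)), -0.1 * 4)
})

test_that("Gauss-Seidel sweep: fixed point, clamping, non-finite guard", {
  p <- seg_params()
  st <- bregman_state(6, 6)
  phi <- matrix(0.5, 6, 6)
  out <- gauss_seidel_sweep(phi, st, matrix(0, 6, 6), p)
  expect_equal(out, phi)
  # strong negative s drives to the 1 bound; strong positive to 0
  out <- gauss_seidel_sweep(phi, st, matrix(-10, 6, 6), p)
  expect_true(all(out == 1))
  out <- gauss_seidel_sweep(phi, st, matrix(10, 6, 6), p)
  expect_true(all(out == 0))
  expect_error(gauss_seidel_sweep(phi, st, matrix(NaN, 6, 6), p),
               "non-finite")
})

test_that("iterated sweeps solve the clamped data-Laplace system (dense oracle)", {
  # Left half: strong positive s clamps phi to 0 exactly (beta < 0 there).
  # Right half: small negative source; the free values solve a linear
  # system with the clamped pixels as boundary, assembled densely here.
  set.seed(41)
  n <- 8
  s <- matrix(2, n, n)
  s[, 5:8] <- -matrix(runif(n * 4, 0, 0.01), n, 4)
  p <- seg_params()                      # mu/lam = 3
  st <- bregman_state(n, n)
  phi <- matrix(0.5, n, n)
  for (it in 1:4000) phi <- gauss_seidel_sweep(phi, st, s, p)

  free <- which(col(s) >= 5)
  idx <- matrix(0L, n, n); idx[free] <- seq_along(free)
  A <- matrix(0, length(free), length(free))
  b <- numeric(length(free))
  r <- row(s); cc <- col(s)
  for (q in seq_along(free)) {
    i <- r[free[q]]; j <- cc[free[q]]
    cnt <- 0
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > n || jj < 1 || jj > n) next
      cnt <- cnt + 1
      if (idx[ii, jj] > 0) A[q, idx[ii, jj]] <- A[q, idx[ii, jj]] - 1
      # clamped neighbors contribute phi = 0: nothing added to b
    }
    A[q, q] <- cnt
    b[q] <- -(p$mu / p$lam) * s[i, j]
  }
  phi_free <- solve(A, b)
  expect_true(all(phi_free > 0 & phi_free < 1))   # interior solution
  expect_true(all(phi[col(s) < 5] == 0))
  expect_lt(max(abs(phi[free] - phi_free)), 1e-6)
})

test_that("shrink is the soft-threshold proximal operator", {
  expect_equal(shrink(0, theta = 2), 0)
  expect_equal(shrink(5, theta = 2), 3)
  expect_equal(shrink(-5, theta = 2), -3)
  expect_equal(shrink(1, theta = 2), 0)
  # grid-search prox oracle on 100 random (z, theta)
  set.seed(43)
  grid <- seq(-12, 12, by = 1e-4)
  for (i in 1:100) {
    z <- rnorm(1, sd = 3); th <- runif(1, 0, 3)
    w <- grid[which.min(0.5 * (grid - z)^2 + th * abs(grid))]
    expect_lt(abs(shrink(z, theta = th) - w), 1e-3)
  }
})

test_that("shrink is odd and 1-Lipschitz; vector shrink keeps direction", {
  set.seed(45)
  for (i in 1:50) {
    a <- rnorm(1, sd = 4); b <- rnorm(1, sd = 4); th <- runif(1, 0, 2)
    expect_equal(shrink(-a, theta = th), -shrink(a, theta = th))
    expect_lte(abs(shrink(a, theta = th) - shrink(b, theta = th)),
               abs(a - b) + 1e-12)
  }
  v <- shrink(matrix(3, 1, 1), matrix(4, 1, 1), theta = 1)   # |z| = 5 -> 4
  expect_equal(as.numeric(v$x), 3 * 4 / 5)
  expect_equal(as.numeric(v$y), 4 * 4 / 5)
  v0 <- shrink(matrix(0, 2, 2), matrix(0, 2, 2), theta = 1)
  expect_true(all(v0$x == 0) && all(v0$y == 0))
})

test_that("bregman update matches a per-pixel scalar reference loop", {
  set.seed(47)
  n <- 10
  phi <- matrix(runif(n * n), n, n)
  st <- list(dx = matrix(rnorm(n * n), n, n), dy = matrix(rnorm(n * n), n, n),
             bx = matrix(rnorm(n * n), n, n), by = matrix(rnorm(n * n), n, n),
             iteration = 0L)
  g <- matrix(sample(0:1, n * n, TRUE), n, n)
  lam <- 1000
  out <- bregman_update(phi, st, g, lam)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gr <- phi[min(i + 1, n), j] - phi[i, j]
    gc <- phi[i, min(j + 1, n)] - phi[i, j]
    zx <- st$bx[i, j] + gr; zy <- st$by[i, j] + gc
    mag <- sqrt(zx^2 + zy^2)
    sc <- if (mag > 0) max(mag - g[i, j] / lam, 0) / mag else 0
    expect_lt(abs(out$dx[i, j] - zx * sc), 1e-12)
    expect_lt(abs(out$by[i, j] - (zy - zy * sc)), 1e-12)
  }
  # zero-threshold pixels: d absorbs b + grad, new b is 0
  out0 <- bregman_update(phi, st, matrix(0L, n, n), lam)
  expect_lt(max(abs(out0$bx)), 1e-14)
  expect_lt(max(abs(out0$by)), 1e-14)
})

test_that("alternating sweep and shrink descend the fixed-coefficient energy", {
  set.seed(49)
  p <- seg_params()
  for (inst in 1:10) {
    n <- 8
    s <- matrix(rnorm(n * n, sd = 0.3), n, n)
    g <- matrix(sample(0:1, n * n, TRUE), n, n)
    phi <- matrix(runif(n * n), n, n)
    dx <- dy <- matrix(0, n, n)
    st0 <- list(dx = dx, dy = dy, bx = dx, by = dy)     # b fixed at 0
    e_prev <- sb_energy(phi, dx, dy, s, g, p$mu, p$lam)
    for (it in 1:25) {
      phi <- gauss_seidel_sweep(phi, list(dx = dx, dy = dy,
                                          bx = dx * 0, by = dy * 0), s, p)
      gr <- rbind(phi[-1, ], phi[n, ]) - phi
      gc <- cbind(phi[, -1], phi[, n]) - phi
      sh <- shrink(gr, gc, g / p$lam)
      dx <- sh$x; dy <- sh$y
      e <- sb_energy(phi, dx, dy, s, g, p$mu, p$lam)
      expect_lte(e, e_prev + 1e-9)
      e_prev <- e
    }
  }
})

test_that("segmentation of a noisy two-phase image is essentially exact", {
  fx <- two_phase_fixture(64)
  res <- quiet_segment(fx$image)
  expect_gte(dice_coefficient(res$mask, fx$truth), 0.98)
  expect_true(res$phi_range_ok)
})

test_that("segmentation is invariant to a common HU offset of image and threshold", {
  fx <- two_phase_fixture(48)
  r1 <- quiet_segment(fx$image)
  p2 <- seg_params(hu_init_threshold = -500 + 250)
  r2 <- quiet_segment(fx$image + 250, p2)
  expect_identical(r1$mask, r2$mask)
})

test_that("local term resolves an intensity ramp that defeats the global term", {
  # Object and background share the intensity range through a strong ramp;
  # only the local fits can place the boundary. The literal edge coding
  # (edges = 1) routes off-edge pixels to the local term, the inverted
  # coding with a negligible local weight approximates a pure global run.
  set.seed(51)
  n <- 64
  img <- matrix(10 * col(matrix(0, n, n)), n, n)
  img[, 1:32] <- img[, 1:32] + 150
  img <- img + matrix(rnorm(n * n, 0, 2), n, n)
  truth <- matrix(0L, n, n); truth[, 1:32] <- 1L
  boundary_col <- function(mask) {
    apply(mask, 1, function(r) { w <- which(r == 1L); if (length(w)) max(w) else NA })
  }
  local_run <- quiet_segment(img, seg_params(invert_edge_map = FALSE,
                                             hu_init_threshold = 330))
  global_run <- quiet_segment(img, seg_params(beta_prime = 1e-9,
                                              hu_init_threshold = 330))
  err_local <- abs(boundary_col(local_run$mask) - 32)
  err_global <- abs(boundary_col(global_run$mask) - 32)
  expect_lte(stats::median(err_local, na.rm = TRUE), 2)
  expect_gt(stats::median(err_global, na.rm = TRUE), 2)
})

test_that("hole filling closes interior cavities only", {
  d <- disk_fixture(32, 16, 16, 9)
  expect_identical(fill_holes(d), d)
  annulus <- d - disk_fixture(32, 16, 16, 4)
  expect_identical(fill_holes(annulus), d)
  punched <- d; punched[15:17, 15:17] <- 0L   # 3-px hole
  filled <- fill_holes(punched)
  expect_identical(filled, d)
})

test_that("background removal drops border-connected components only", {
  m <- matrix(0L, 16, 16)
  m[1:4, 1:4] <- 1L          # touches border
  m[8:10, 8:10] <- 1L        # interior
  out <- remove_background(m)
  expect_equal(sum(out[1:4, 1:4]), 0)
  expect_equal(sum(out[8:10, 8:10]), 9)
})
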