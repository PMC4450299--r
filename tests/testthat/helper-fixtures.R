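# Shared fixtures and brute-force oracles, independent of the package's
# vectorized implementations.

# Replicate-clamped index
clampi <- function(i, n) pmin(pmax(i, 1L), n)

# Brute-force 2D convolution with replicate boundary (centered odd kernel).
conv2_loop <- function(x, kern) {
  n <- nrow(x); m <- ncol(x)
  kr <- (nrow(kern) - 1L) / 2L; kc <- (ncol(kern) - 1L) / 2L
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      acc <- acc + kern[a + kr + 1L, b + kc + 1L] *
        x[clampi(i + a, n), clampi(j + b, m)]
    }
    out[i, j] <- acc
  }
  out
}

# Brute-force central-difference gradients with replicate boundary.
grad_central_loop <- function(x) {
  n <- nrow(x); m <- ncol(x)
  gr <- gc <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    gr[i, j] <- (x[clampi(i + 1L, n), j] - x[clampi(i - 1L, n), j]) / 2
    gc[i, j] <- (x[i, clampi(j + 1L, m)] - x[i, clampi(j - 1L, m)]) / 2
  }
  list(gr = gr, gc = gc)
}

# 4-neighborhood dilation by one pixel (zero padding).
dilate_by_one <- function(m) {
  out <- m
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sh <- matrix(0L, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + d[1]; cs <- seq_len(ncol(m)) + d[2]
    ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
    sh[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out <- matrix(as.integer(out | sh), nrow(m), ncol(m))
  }
  out
}

# Bone pixels within 6 px of the trachea disk: the cartilage neighborhood.
dilate_ring <- function(trachea) {
  idx <- which(trachea == 1L, arr.ind = TRUE)
  cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
  rad <- sqrt(nrow(idx) / pi)
  g <- expand.grid(r = seq_len(nrow(trachea)), c = seq_len(ncol(trachea)))
  matrix((g$r - cr)^2 + (g$c - cc)^2 <= (rad + 6)^2, nrow(trachea))
}

# Logical matrix -> integer 0/1 matrix.
as_mask_int <- function(x) matrix(as.integer(x != 0), nrow(x), ncol(x))

# A disk mask fixture.
disk_fixture <- function(n, cr, cc, rad) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix(as.integer((g$r - cr)^2 + (g$c - cc)^2 <= rad^2), n, n)
}

# Two-phase noisy ellipse fixture used for segmentation quality checks.
two_phase_fixture <- function(n = 128, noise_sd = 8, seed = 42) {
  truth <- matrix(0L, n, n)
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  truth[matrix(((g$r - n / 2) / (0.31 * n))^2 +
               ((g$c - n / 2) / (0.23 * n))^2 <= 1, n, n)] <- 1L
  set.seed(seed)
  img <- ifelse(truth == 1L, -800, 0) + matrix(rnorm(n * n, 0, noise_sd), n, n)
  list(image = img, truth = truth)
}

# Discrete split-Bregman energy with b = 0 (forward differences, replicate
# boundary), used by the monotone-descent property test.
sb_energy <- function(phi, dx, dy, s, g, mu, lam) {
  n <- nrow(phi); m <- ncol(phi)
  gr <- rbind(phi[-1, , drop = FALSE], phi[n, , drop = FALSE]) - phi
  gc <- cbind(phi[, -1, drop = FALSE], phi[, m, drop = FALSE]) - phi
  sum(g * sqrt(dx^2 + dy^2)) + mu * sum(phi * s) +
    lam / 2 * sum((dx - gr)^2 + (dy - gc)^2)
}

quiet_segment <- function(...) suppressMessages(suppressWarnings(glg_segment(...)))
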