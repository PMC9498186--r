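# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package internals.

# scalar-queue breadth-first search region growing; gray is an integer
# matrix, seed_rc is 0-based (row, col)
bfs_grow_oracle <- function(gray, seed_rc, tol, constraint = NULL,
                            connectivity = 4L) {
  H <- nrow(gray)
  W <- ncol(gray)
  out <- matrix(FALSE, H, W)
  sr <- seed_rc[1] + 1L
  sc <- seed_rc[2] + 1L
  g0 <- gray[sr, sc]
  offs <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  qr <- integer(H * W)
  qc <- integer(H * W)
  qr[1] <- sr
  qc[1] <- sc
  head <- 1L
  tail <- 1L
  out[sr, sc] <- TRUE
  while (head <= tail) {
    pr <- qr[head]
    pc <- qc[head]
    head <- head + 1L
    for (o in offs) {
      r <- pr + o[1]
      cc <- pc + o[2]
      if (r < 1L || r > H || cc < 1L || cc > W) next
      if (out[r, cc]) next
      if (abs(gray[r, cc] - g0) > tol) next
      if (!is.null(constraint) && !constraint[r, cc]) next
      out[r, cc] <- TRUE
      tail <- tail + 1L
      qr[tail] <- r
      qc[tail] <- cc
    }
  }
  out
}

# connected-component count by repeated scalar BFS over a logical mask
count_components_oracle <- function(mask, connectivity = 4L) {
  gray <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    idx <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- bfs_grow_oracle(gray, c(idx[1] - 1L, idx[2] - 1L), tol = 255L,
                            constraint = remaining, connectivity = connectivity)
    remaining <- remaining & !comp
    k <- k + 1L
  }
  k
}

# random image fixture
random_image <- function(H, W, ppm = 12.2674, max_gray = 255L) {
  calibrated_image(matrix(sample.int(max_gray + 1L, H * W, replace = TRUE) - 1L,
                          nrow = H),
                   calibration_spec(ppm))
}

# a small in-memory phantom with one explicit cystic lobule
small_lobule_phantom <- function(seed, cystic = c(10, 6), solid = c(40, 8),
                                 background = c(68.3, 11.3), size = 120L,
                                 ppm = 3) {
  spec <- phantom_spec(
    width = size, height = size, calibration = calibration_spec(ppm),
    background = background,
    lesion = list(center = c(size / 2, size / 2), semi_axes_mm = c(13, 15),
                  mean = solid[1], sd = solid[2]),
    lobules = list(list(center = c(size / 2, size / 2), semi_axes_mm = c(6, 7),
                        mean = cystic[1], sd = cystic[2])),
    seed = seed
  )
  render_phantom(spec)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
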