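test_that("polygon rasterization matches pixel-center membership", {
  # axis-aligned rectangle through half-integer corners: exactly 10x10 centers
  rect <- rbind(c(-0.5, -0.5), c(-0.5, 9.5), c(9.5, 9.5), c(9.5, -0.5))
  m <- rasterize_polygon(rect, width = 20, height = 20)
  expect_equal(sum(m), 100L)
  expect_true(all(which(m, arr.ind = TRUE) <= 10))

  # triangle: against an independent point-in-polygon oracle (sp)
  tri <- rbind(c(0, 0), c(0, 4), c(4, 0))
  m <- rasterize_polygon(tri, width = 8, height = 8)
  grid <- expand.grid(r = 0:7, c = 0:7)
  oracle <- sp::point.in.polygon(grid$r, grid$c, tri[, 1], tri[, 2])
  expect_true(all(m[cbind(grid$r + 1, grid$c + 1)][oracle == 1L]))
  expect_false(any(m[cbind(grid$r + 1, grid$c + 1)][oracle == 0L]))

  # fully outside the image
  far <- rbind(c(100, 100), c(100, 110), c(110, 100))
  expect_equal(sum(rasterize_polygon(far, 20, 20)), 0L)

  # degenerate (zero area)
  expect_error(rasterize_polygon(rbind(c(0, 0), c(5, 5), c(10, 10)), 20, 20),
               "degenerate|zero")
})

test_that("random convex polygons agree with the sp oracle off the boundary", {
  set.seed(101)
  for (i in 1:40) {
    pts <- cbind(runif(8, 0.3, 22.7), runif(8, 0.3, 22.7)) + 0.13 # avoid centers
    hull <- pts[chull(pts), ]
    m <- rasterize_polygon(hull, 24, 24)
    grid <- expand.grid(r = 0:23, c = 0:23)
    oracle <- sp::point.in.polygon(grid$r, grid$c, hull[, 1], hull[, 2])
    got <- m[cbind(grid$r + 1, grid$c + 1)]
    strict <- oracle == 1L
    outside <- oracle == 0L
    expect_true(all(got[strict]), label = sprintf("iter %d interior", i))
    expect_false(any(got[outside]), label = sprintf("iter %d exterior", i))
  }
})

test_that("rectangles in center coordinates rasterize to width x height pixels", {
  set.seed(7)
  for (i in 1:25) {
    r0 <- sample(0:10, 1); r1 <- r0 + sample(1:12, 1)
    c0 <- sample(0:10, 1); c1 <- c0 + sample(1:12, 1)
    rect <- rbind(c(r0 - 0.5, c0 - 0.5), c(r0 - 0.5, c1 + 0.5),
                  c(r1 + 0.5, c1 + 0.5), c(r1 + 0.5, c0 - 0.5))
    m <- rasterize_polygon(rect, 30, 30)
    expect_equal(sum(m), (r1 - r0 + 1L) * (c1 - c0 + 1L))
  }
})

test_that("seeded growing reproduces the worked 4x4 examples", {
  gray <- rbind(c(10, 10, 50, 50),
                c(10, 12, 50, 50),
                c(60, 60, 60, 50),
                c(10, 10, 10, 50))
  storage.mode(gray) <- "integer"
  img <- calibrated_image(gray, calibration_spec(1)) # rows of `gray` are image rows

  m5 <- grow_region(img, c(0, 0), tolerance = 5)
  expect_equal(sum(m5), 4L)
  expect_true(all(m5[1:2, 1:2]))

  m0 <- grow_region(img, c(0, 0), tolerance = 0)
  expect_equal(sum(m0), 3L)
  expect_true(m0[1, 1] && m0[1, 2] && m0[2, 1])
  expect_false(m0[2, 2]) # gray 12 differs from seed 10

  expect_equal(sum(grow_region(img, c(0, 0), tolerance = 255)), 16L)
  expect_error(grow_region(img, c(9, 0), tolerance = 5), "out of")
  constraint <- matrix(FALSE, 4, 4)
  expect_error(grow_region(img, c(0, 0), tolerance = 5, constraint = constraint),
               "constraint")
})

test_that("growing equals brute-force BFS on random instances (both connectivities)", {
  set.seed(202)
  for (i in 1:150) {
    H <- sample(4:16, 1); W <- sample(4:16, 1)
    img <- random_image(H, W, max_gray = 40L)
    seed <- c(sample(0:(H - 1), 1), sample(0:(W - 1), 1))
    tol <- sample(0:20, 1)
    conn <- sample(c(4L, 8L), 1)
    got <- grow_region(img, seed, tol, connectivity = conn)
    want <- bfs_grow_oracle(img$gray, seed, tol, connectivity = conn)
    expect_identical(got, want)
  }
})

test_that("tolerance and constraint monotonicity hold", {
  set.seed(303)
  for (i in 1:60) {
    img <- random_image(12, 12, max_gray = 60L)
    seed <- c(sample(0:11, 1), sample(0:11, 1))
    t1 <- sample(0:20, 1)
    t2 <- t1 + sample(0:20, 1)
    m1 <- grow_region(img, seed, t1)
    m2 <- grow_region(img, seed, t2)
    expect_true(all(m2[m1])) # nested admissible sets => nested regions
    constraint <- matrix(sample(c(TRUE, FALSE), 144, TRUE, prob = c(0.8, 0.2)), 12)
    constraint[seed[1] + 1, seed[2] + 1] <- TRUE
    mc <- grow_region(img, seed, t2, constraint = constraint)
    expect_true(all(m2[mc])) # constraining never adds pixels
  }
})

test_that("calibrated circles rasterize to disc areas", {
  cal <- calibration_spec(12.2674)
  m <- rasterize_circle(c(100, 100), 5, cal, 200, 200)
  expect_equal(sum(m), pi * (2.5 * 12.2674)^2, tolerance = 0.01)

  cal1 <- calibration_spec(1)
  m <- rasterize_circle(c(5, 5), 2, cal1, 11, 11) # radius exactly 1 px
  expect_equal(sum(m), 5L) # center + 4-neighbourhood
  m <- rasterize_circle(c(5, 5), 1e-9, cal1, 11, 11)
  expect_equal(sum(m), 1L)
  expect_error(rasterize_circle(c(500, 500), 5, cal1, 20, 20), "outside")
  expect_error(rasterize_circle(c(5, 5), -1, cal1, 20, 20), "> 0")
})

test_that("mask algebra: union, subtraction, stray-pixel tolerance", {
  # two disjoint 10-pixel masks
  m1 <- matrix(FALSE, 10, 10); m1[1, 1:10] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[5, 1:10] <- TRUE
  expect_equal(sum(union_masks(list(m1, m2))), 20L)
  expect_identical(union_masks(list(m1, m1)), m1)

  # overlap of 3 pixels, sizes 10 and 8 -> union 15 (inclusion-exclusion)
  m3 <- matrix(FALSE, 10, 10); m3[2, 1:8] <- TRUE
  m4 <- matrix(FALSE, 10, 10); m4[2, 6:10] <- TRUE; m4[3, 1:5] <- TRUE
  expect_equal(sum(m3), 8L); expect_equal(sum(m4), 10L)
  expect_equal(sum(m3 & m4), 3L)
  expect_equal(sum(union_masks(list(m3, m4))), 15L)

  # subtraction with b subset of a
  A <- matrix(TRUE, 10, 10)
  B <- matrix(FALSE, 10, 10); B[1:4, 1:10] <- TRUE
  expect_equal(sum(subtract_mask(A, B)), 60L)
  expect_equal(sum(subtract_mask(A, A)), 0L)
  # 5 stray subtrahend pixels outside the minuend
  A2 <- matrix(FALSE, 10, 10); A2[1:5, ] <- TRUE
  B2 <- matrix(FALSE, 10, 10); B2[4:6, 1:5] <- TRUE
  B2[6, 1:5] <- TRUE
  expect_warning(res <- subtract_mask(A2, B2), "5 pixel")
  expect_equal(sum(res), sum(A2) - sum(A2 & B2))
  m5 <- matrix(FALSE, 9, 9)
  expect_error(subtract_mask(A, m5), "dimensions")
})

test_that("lobule counting is connected-component counting", {
  m1 <- matrix(FALSE, 12, 12); m1[2:4, 2:4] <- TRUE
  m2 <- matrix(FALSE, 12, 12); m2[8:10, 8:10] <- TRUE
  expect_equal(count_lobules(list(m1, m2)), 2L)

  # regions sharing an edge-adjacent pixel merge into one lobule
  m3 <- matrix(FALSE, 12, 12); m3[2:4, 5:7] <- TRUE # touches m1 at column 5
  expect_equal(count_lobules(list(m1, m3)), 1L)
  expect_equal(count_components_oracle(m1 | m3), 1L)
  expect_equal(count_lobules(list()), 0L)

  # diagonal touch: separate under 4-connectivity, merged under 8
  d1 <- matrix(FALSE, 8, 8); d1[2:3, 2:3] <- TRUE
  d2 <- matrix(FALSE, 8, 8); d2[4:5, 4:5] <- TRUE
  expect_equal(count_lobules(list(d1, d2), connectivity = 4L), 2L)
  expect_equal(count_lobules(list(d1, d2), connectivity = 8L), 1L)

  set.seed(44)
  for (i in 1:20) {
    m <- matrix(runif(144) < 0.35, 12, 12)
    expect_equal(count_lobules(list(m)), count_components_oracle(m))
  }
})
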