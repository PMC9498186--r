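test_that("moment accumulation matches hand sums", {
  cal <- calibration_spec(1)
  img <- calibrated_image(matrix(c(10L, 20L, 30L, 99L), 2, 2), cal)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  m <- compute_moments(img, mask)
  expect_equal(m$n, 3)
  expect_equal(m$sum_gray, 60)
  expect_equal(m$sum_sq, 1400)

  z <- calibrated_image(matrix(0L, 1, 5), cal)
  mz <- compute_moments(z, matrix(TRUE, 1, 5))
  expect_equal(c(mz$n, mz$sum_gray, mz$sum_sq), c(5, 0, 0))

  one <- calibrated_image(matrix(255L, 1, 1), cal)
  m1 <- compute_moments(one, matrix(TRUE, 1, 1))
  expect_equal(c(m1$n, m1$sum_gray, m1$sum_sq), c(1, 255, 65025))

  expect_error(compute_moments(img, matrix(FALSE, 2, 2)), "empty")
  expect_error(gray_moments(3, 900, 1400), "sum_gray")      # mean > 255
  expect_error(gray_moments(3, 60, 100), "Cauchy")          # sum_sq too small
})

test_that("echogenicity, inhomogeneity and density reproduce worked values", {
  cal <- calibration_spec(12.2674)
  m <- gray_moments(3, 60, 1400, cal)
  expect_equal(mean_gray(m), 20)
  expect_equal(sd_gray(m), 10) # sqrt((1400 - 1200)/2)
  expect_equal(sd_gray(m, "population"), sqrt(200 / 3))

  const <- gray_moments(7, 7 * 42, 7 * 42^2, cal)
  expect_equal(sd_gray(const), 0)
  two <- gray_moments(2, 255, 65025, cal)
  expect_equal(sd_gray(two), sqrt(32512.5)) # pixels {0, 255}

  # density at the study calibration: mean 27.8 -> ~4183.6 sum-gray/mm^2
  m278 <- gray_moments(1000, 27.8 * 1000, 27.8^2 * 1000 + 1, cal)
  expect_equal(density_gray(m278), 27.8 * 12.2674^2, tolerance = 1e-12)
  expect_equal(density_gray(m278), 4183.6, tolerance = 1e-4)

  unit <- gray_moments(3, 60, 1400, calibration_spec(1))
  expect_equal(area_mm2(unit), 3)
  expect_equal(density_gray(unit), 20)
  expect_error(mean_gray(gray_moments(0, 0, 0, cal)), "empty")
  expect_error(sd_gray(gray_moments(1, 10, 100, cal)), "fewer than 2")
})

test_that("density identity: density = mean gray x pixels per mm^2", {
  set.seed(9)
  for (i in 1:50) {
    ppm <- runif(1, 0.5, 30)
    img <- random_image(10, 10, ppm = ppm)
    mask <- matrix(runif(100) < 0.6, 10, 10)
    if (!any(mask)) next
    m <- compute_moments(img, mask)
    expect_equal(density_gray(m), mean_gray(m) * ppm^2, tolerance = 1e-9)
  }
})

test_that("moment subtraction equals direct computation on the difference mask", {
  cal <- calibration_spec(1)
  whole <- gray_moments(10, 100, 1200, cal)
  cyst <- gray_moments(4, 20, 120, cal)
  solid <- subtract_moments(whole, cyst)
  expect_equal(c(solid$n, solid$sum_gray, solid$sum_sq), c(6, 80, 1080))
  expect_equal(mean_gray(solid), 80 / 6)
  expect_equal(sd_gray(solid), sqrt((1080 - 80^2 / 6) / 5))

  expect_equal(subtract_moments(whole, gray_moments(0, 0, 0, cal))$n, 10)
  expect_error(subtract_moments(cyst, cyst), "fully cystic")
  expect_error(subtract_moments(cyst, whole), "inconsistent")

  set.seed(19)
  for (i in 1:300) {
    img <- random_image(8, 8, ppm = 2)
    a <- matrix(runif(64) < 0.7, 8, 8)
    b <- a & matrix(runif(64) < 0.5, 8, 8)
    if (!any(b) || !any(a & !b)) next
    mw <- compute_moments(img, a)
    mc <- compute_moments(img, b)
    ms <- subtract_moments(mw, mc)
    md <- compute_moments(img, a & !b)
    expect_identical(c(ms$n, ms$sum_gray, ms$sum_sq), c(md$n, md$sum_gray, md$sum_sq))
    expect_equal(sd_gray(ms), sd_gray(md), tolerance = 1e-9)
  }
})

test_that("whole-lesion measurement satisfies the mixture and area identities", {
  ph <- small_lobule_phantom(seed = 21)
  rec <- measure_lesion(ph$image, ph$truth$annotation, group = "SCN")
  expect_equal(rec$area_whole_mm2, rec$area_cystic_mm2 + rec$area_solid_mm2,
               tolerance = 1e-9)
  expect_equal(rec$area_ratio, rec$area_cystic_mm2 / rec$area_whole_mm2,
               tolerance = 1e-12)
  ppm2 <- ph$image$calibration$pixels_per_mm^2
  n_w <- rec$area_whole_mm2 * ppm2
  n_c <- rec$area_cystic_mm2 * ppm2
  n_s <- rec$area_solid_mm2 * ppm2
  expect_equal(rec$mean_whole * n_w, rec$mean_cystic * n_c + rec$mean_solid * n_s,
               tolerance = 1e-6)
  for (part in c("whole", "cystic", "solid")) {
    expect_equal(rec[[paste0("density_", part)]],
                 rec[[paste0("mean_", part)]] * ppm2, tolerance = 1e-9)
  }
  expect_equal(rec$lobule_count, 1L)
})

test_that("measurement recovers phantom truth", {
  ph <- small_lobule_phantom(seed = 33, cystic = c(10, 6), solid = c(45, 8))
  rec <- measure_lesion(ph$image, ph$truth$annotation)
  truth_ratio <- sum(ph$truth$masks$cystic) / sum(ph$truth$masks$whole)
  expect_equal(rec$area_ratio, truth_ratio, tolerance = 0.02)
  cy <- ph$truth$realized["cystic", ]
  expect_lt(abs(rec$mean_cystic - cy$mean), 3 * cy$sd / sqrt(cy$n) + 0.5)
})

test_that("seedless and fully-cystic annotations degrade explicitly", {
  ph <- small_lobule_phantom(seed = 2)
  ann <- ph$truth$annotation
  ann$cystic_seeds <- ann$cystic_seeds[0, ]
  rec <- measure_lesion(ph$image, ann)
  expect_true(is.na(rec$mean_cystic))
  expect_equal(rec$mean_solid, rec$mean_whole)
  expect_equal(rec$lobule_count, 0L)
  expect_equal(rec$area_ratio, 0)

  # a cyst that fills the whole polygon leaves no solid part
  cal <- calibration_spec(1)
  flat <- calibrated_image(matrix(5L, 30, 30), cal)
  ann2 <- lesion_annotation(
    "flat", rbind(c(4.5, 4.5), c(4.5, 20.5), c(20.5, 20.5), c(20.5, 4.5)),
    cystic_seeds = data.frame(row = 10, col = 10, tolerance = 30),
    calibration = cal
  )
  rec2 <- measure_lesion(flat, ann2)
  expect_true(is.na(rec2$mean_solid))
  expect_equal(rec2$area_ratio, 1)
  expect_false(is.na(rec2$mean_cystic))
})

test_that("scale equivariance: calibration rescales densities and areas only", {
  set.seed(55)
  gray <- matrix(sample.int(256L, 900, replace = TRUE) - 1L, 30, 30)
  ann_poly <- rbind(c(2, 2), c(2, 27), c(27, 27), c(27, 2))
  mk <- function(ppm) {
    img <- calibrated_image(gray, calibration_spec(ppm))
    ann <- lesion_annotation("s", ann_poly,
                             cystic_seeds = data.frame(row = 10, col = 10, tolerance = 3),
                             calibration = calibration_spec(ppm))
    measure_lesion(img, ann)
  }
  r1 <- mk(5)
  r2 <- mk(10)
  expect_equal(r1$mean_whole, r2$mean_whole)
  expect_equal(r1$sd_whole, r2$sd_whole)
  expect_equal(r2$density_whole, 4 * r1$density_whole, tolerance = 1e-9)
  expect_equal(r2$area_whole_mm2, r1$area_whole_mm2 / 4, tolerance = 1e-9)
})

test_that("parenchyma reference block pools three circles and checks homogeneity", {
  cal <- calibration_spec(4)
  H <- 60L; W <- 160L
  circles <- data.frame(row = 30, col = c(30, 80, 130), diameter_mm = 5)

  flat <- calibrated_image(matrix(68L, H, W), cal)
  res <- measure_parenchyma(flat, circles, cal)
  expect_equal(res$mean, 68)
  expect_equal(res$sd, 0)
  expect_true(all(res$homogeneity$pass))

  # one circle at a different constant: its two pairs fail
  g <- matrix(68L, H, W)
  g[, 101:160] <- 90L
  res2 <- measure_parenchyma(calibrated_image(g, cal), circles, cal)
  expect_equal(sum(!res2$homogeneity$pass), 2L)
  expect_true(res2$homogeneity$pass[res2$homogeneity$pair == "1-2"])

  expect_error(measure_parenchyma(flat, circles[1:2, ], cal), "exactly 3")
  bad <- data.frame(row = 2, col = c(30, 80, 130), diameter_mm = 5)
  expect_error(measure_parenchyma(flat, bad, cal), "beyond the image")
})

test_that("homogeneous parenchyma passes the pairwise checks in most replicates", {
  # three 5-mm discs sampled from one noise field at the group-table values
  cal <- calibration_spec(4)
  circles <- data.frame(row = 30, col = c(30, 80, 130), diameter_mm = 5)
  pass <- means <- numeric(400)
  for (s in 1:400) {
    set.seed(4000 + s)
    g <- matrix(as.integer(pmin(pmax(round(rnorm(60 * 160, 68.3, 11.3)), 0), 255)),
                60, 160)
    res <- measure_parenchyma(calibrated_image(g, cal), circles, cal)
    pass[s] <- all(res$homogeneity$pass)
    means[s] <- res$mean
  }
  expect_gte(mean(pass), 0.85)
  n_tot <- 3 * pi * (2.5 * 4)^2
  expect_lt(abs(mean(means) - 68.3), 3 * 11.3 / sqrt(n_tot * 400))
})
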