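#' First-order gray-level moments of a region
#'
#' The `(n, sum_gray, sum_sq)` triple over a region's pixels is the basis of
#' every reported metric: echogenicity (mean), inhomogeneity (SD), and
#' integrated density per calibrated area. Moment algebra also gives the
#' solid-part values exactly, by subtracting the cystic moments from the
#' whole-lesion moments.
#'
#' @param n Pixel count (>= 0).
#' @param sum_gray Sum of gray values over the region.
#' @param sum_sq Sum of squared gray values.
#' @param calibration A [calibration_spec()].
#' @return Object of class `gray_moments`.
#' @export
gray_moments <- function(n, sum_gray, sum_sq, calibration = calibration_spec()) {
  stopifnot(inherits(calibration, "calibration_spec"))
  if (n < 0 || sum_gray < 0 || sum_sq < 0 ||
      sum_gray > 255 * n || sum_sq > 255^2 * n) {
    stop("inconsistent moments: need 0 <= sum_gray <= 255 n and 0 <= sum_sq <= 255^2 n",
         call. = FALSE)
  }
  if (n > 0 && sum_sq * n < sum_gray^2 - 1e-6) {
    stop("inconsistent moments: sum_sq * n < sum_gray^2 violates Cauchy-Schwarz",
         call. = FALSE)
  }
  structure(
    list(n = as.numeric(n), sum_gray = as.numeric(sum_gray),
         sum_sq = as.numeric(sum_sq), calibration = calibration),
    class = "gray_moments"
  )
}

#' @export
print.gray_moments <- function(x, ...) {
  cat(sprintf("Gray moments: n = %g px, sum = %g, sum of squares = %g\n",
              x$n, x$sum_gray, x$sum_sq))
  invisible(x)
}

#' Accumulate gray moments over a masked region
#'
#' Exact integer accumulation of pixel count, gray sum and squared gray sum
#' over the member pixels of a mask (doubles hold these exactly: the largest
#' possible sum of squares for a full 1280 x 960 frame is far below 2^53).
#'
#' @param image A [calibrated_image()].
#' @param mask Logical mask matrix matching the image dimensions.
#' @return A [gray_moments()].
#' @export
compute_moments <- function(image, mask) {
  stopifnot(inherits(image, "calibrated_image"))
  check_same_dim(image$gray, mask, "image and mask")
  g <- as.numeric(image$gray[mask])
  if (!length(g)) stop("empty region: mask has no member pixels", call. = FALSE)
  gray_moments(length(g), sum(g), sum(g * g), image$calibration)
}

#' Echogenicity: mean gray value of a region
#' @param m A [gray_moments()].
#' @return Mean gray level in `[0, 255]`.
#' @export
mean_gray <- function(m) {
  stopifnot(inherits(m, "gray_moments"))
  if (m$n < 1) stop("empty region: mean gray undefined", call. = FALSE)
  m$sum_gray / m$n
}

#' Inhomogeneity: gray-value standard deviation of a region
#'
#' By default the sample (`n - 1` denominator) standard deviation, matching
#' mainstream image-measurement software; `denominator = "population"`
#' switches to the `n` denominator.
#'
#' @param m A [gray_moments()].
#' @param denominator `"sample"` (default) or `"population"`.
#' @return Standard deviation in gray levels.
#' @export
sd_gray <- function(m, denominator = c("sample", "population")) {
  stopifnot(inherits(m, "gray_moments"))
  denominator <- match.arg(denominator)
  if (m$n < 2) stop("SD undefined for regions with fewer than 2 pixels", call. = FALSE)
  ss <- m$sum_sq - m$sum_gray^2 / m$n
  ss <- max(ss, 0) # guard tiny negative from floating subtraction
  sqrt(ss / (m$n - if (denominator == "sample") 1 else 0))
}

#' Density: integrated gray value per calibrated area
#'
#' Sum of the region's gray values divided by its area in mm\eqn{^2};
#' algebraically identical to `mean_gray(m) * pixels_per_mm^2`, which is the
#' internal-consistency relation linking the echogenicity and density columns
#' of the group table.
#'
#' @param m A [gray_moments()].
#' @return Density in gray-value units per mm\eqn{^2}.
#' @export
density_gray <- function(m) {
  stopifnot(inherits(m, "gray_moments"))
  if (m$n < 1) stop("empty region: density undefined", call. = FALSE)
  m$sum_gray / (m$n * m$calibration$pixel_area_mm2)
}

#' Area of a region in mm^2
#' @param m A [gray_moments()].
#' @return Area in mm\eqn{^2}.
#' @export
area_mm2 <- function(m) {
  stopifnot(inherits(m, "gray_moments"))
  m$n * m$calibration$pixel_area_mm2
}

#' Solid-part moments by subtraction
#'
#' The solid part of a lesion is defined as whole minus cystic; because the
#' moments are additive over disjoint pixel sets, subtracting the cystic
#' moments from the whole-lesion moments equals computing moments directly on
#' the set-difference mask, exactly.
#'
#' @param whole,cystic [gray_moments()] of the whole lesion and of the cystic
#'   union (cystic must be a pixel subset of whole).
#' @return A [gray_moments()] for the solid part.
#' @export
subtract_moments <- function(whole, cystic) {
  stopifnot(inherits(whole, "gray_moments"), inherits(cystic, "gray_moments"))
  if (!isTRUE(all.equal(whole$calibration$pixels_per_mm,
                        cystic$calibration$pixels_per_mm))) {
    stop("moments have different calibrations", call. = FALSE)
  }
  n <- whole$n - cystic$n
  s <- whole$sum_gray - cystic$sum_gray
  ss <- whole$sum_sq - cystic$sum_sq
  if (n < 0 || s < 0 || ss < 0) {
    stop("inconsistent regions: cystic moments exceed whole-lesion moments", call. = FALSE)
  }
  if (n == 0) {
    stop("fully cystic lesion: solid part is empty, metrics undefined", call. = FALSE)
  }
  gray_moments(n, s, ss, whole$calibration)
}

metric_row <- function(m, denominator) {
  list(area = area_mm2(m), mean = mean_gray(m),
       sd = if (m$n >= 2) sd_gray(m, denominator) else NA_real_,
       density = density_gray(m))
}

#' Measure one lesion image against its annotation
#'
#' Runs the full per-image protocol: rasterize the lesion polygon to the
#' whole-lesion mask; grow one region per cystic seed at its tolerance
#' (clipped to the lesion by default), merge them by union; derive the solid
#' part as whole minus cystic by moment subtraction; count cystic lobules as
#' connected components of the cystic union; and measure the optional 3-circle
#' parenchyma reference block. Echogenicity, inhomogeneity, density and
#' calibrated area are reported per part, together with the cystic/whole area
#' ratio.
#'
#' A lesion whose cystic union fills the polygon has no solid part: the solid
#' metrics are reported as missing (`NA`), never as zeros. An annotation with
#' no cystic seeds yields missing cystic metrics, `solid = whole`,
#' `lobule_count = 0` and `area_ratio = 0`.
#'
#' @param image A [calibrated_image()].
#' @param annotation A [lesion_annotation()] for this image.
#' @param group Optional diagnosis group label carried into the record.
#' @param sd_denominator `"sample"` (default) or `"population"`.
#' @param clip_cystic_to_lesion Constrain seeded growth to the lesion polygon
#'   (default `TRUE`).
#' @param connectivity 4 (default) or 8, for growing and lobule counting.
#' @return Object of class `lesion_measurement`: a named list of the record
#'   fields (see [measurement_columns()]).
#' @export
measure_lesion <- function(image, annotation, group = NA_character_,
                           sd_denominator = c("sample", "population"),
                           clip_cystic_to_lesion = TRUE, connectivity = 4L) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(annotation, "lesion_annotation"))
  sd_denominator <- match.arg(sd_denominator)
  whole_mask <- rasterize_polygon(annotation$lesion_polygon, image$width, image$height)
  if (!any(whole_mask)) {
    stop("lesion polygon rasterizes to an empty mask (outside the image?)", call. = FALSE)
  }
  whole <- compute_moments(image, whole_mask)

  seeds <- annotation$cystic_seeds
  cystic_masks <- list()
  if (nrow(seeds)) {
    constraint <- if (clip_cystic_to_lesion) whole_mask else NULL
    for (i in seq_len(nrow(seeds))) {
      cystic_masks[[i]] <- grow_region(
        image, c(seeds$row[i], seeds$col[i]), seeds$tolerance[i],
        constraint = constraint, connectivity = connectivity
      )
    }
  }

  empty <- list(area = NA_real_, mean = NA_real_, sd = NA_real_, density = NA_real_)
  w <- metric_row(whole, sd_denominator)
  if (length(cystic_masks)) {
    cyst_mask <- union_masks(cystic_masks)
    if (clip_cystic_to_lesion) cyst_mask <- cyst_mask & whole_mask
    cystic <- compute_moments(image, cyst_mask)
    cy <- metric_row(cystic, sd_denominator)
    lobules <- count_lobules(list(cyst_mask), connectivity)
    solid <- tryCatch(subtract_moments(whole, cystic), error = function(e) NULL)
    so <- if (is.null(solid)) empty else metric_row(solid, sd_denominator)
    ratio <- cystic$n / whole$n
  } else {
    cy <- empty
    so <- w
    lobules <- 0L
    ratio <- 0
  }

  par_mean <- NA_real_
  par_sd <- NA_real_
  parenchyma <- NULL
  if (!is.null(annotation$parenchyma_circles)) {
    parenchyma <- measure_parenchyma(image, annotation$parenchyma_circles,
                                     annotation$calibration,
                                     sd_denominator = sd_denominator)
    par_mean <- parenchyma$mean
    par_sd <- parenchyma$sd
  }

  structure(
    list(
      image_id = annotation$image_id,
      group = group,
      area_whole_mm2 = w$area, area_cystic_mm2 = cy$area, area_solid_mm2 = so$area,
      area_ratio = ratio,
      mean_whole = w$mean, mean_cystic = cy$mean, mean_solid = so$mean,
      sd_whole = w$sd, sd_cystic = cy$sd, sd_solid = so$sd,
      density_whole = w$density, density_cystic = cy$density, density_solid = so$density,
      lobule_count = as.integer(lobules),
      parenchyma_mean = par_mean, parenchyma_sd = par_sd,
      parenchyma = parenchyma
    ),
    class = "lesion_measurement"
  )
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat(sprintf("Lesion measurement '%s'%s\n", x$image_id,
              if (is.na(x$group)) "" else sprintf(" [%s]", x$group)))
  cat(sprintf("  whole : area %8.1f mm^2, mean %6.2f, SD %6.2f, density %8.1f /mm^2\n",
              x$area_whole_mm2, x$mean_whole, x$sd_whole, x$density_whole))
  if (!is.na(x$mean_cystic)) {
    cat(sprintf("  cystic: area %8.1f mm^2, mean %6.2f, SD %6.2f, density %8.1f /mm^2\n",
                x$area_cystic_mm2, x$mean_cystic, x$sd_cystic, x$density_cystic))
  }
  if (!is.na(x$mean_solid)) {
    cat(sprintf("  solid : area %8.1f mm^2, mean %6.2f, SD %6.2f, density %8.1f /mm^2\n",
                x$area_solid_mm2, x$mean_solid, x$sd_solid, x$density_solid))
  }
  cat(sprintf("  area ratio %.3f, %d cystic lobule(s)", x$area_ratio, x$lobule_count))
  if (!is.na(x$parenchyma_mean)) {
    cat(sprintf(", parenchyma %.1f +/- %.1f", x$parenchyma_mean, x$parenchyma_sd))
  }
  cat("\n")
  invisible(x)
}

#' Measure the healthy-parenchyma reference block
#'
#' Pools the pixels of three 5-mm circles placed over healthy pancreatic
#' parenchyma into one mean/SD, and checks their homogeneity by pairwise
#' two-sample comparisons (normality-routed, see [compare_two_samples()]) at
#' `alpha`; the protocol requires the three reference areas to be mutually
#' indistinguishable so that parenchyma echogenicity comes from one sample
#' population.
#'
#' @param image A [calibrated_image()].
#' @param circles Data frame with columns `row`, `col`, `diameter_mm`
#'   (exactly 3 rows); every circle must lie fully inside the image.
#' @param calibration A [calibration_spec()].
#' @param alpha Significance level of the homogeneity checks.
#' @param sd_denominator Passed to [sd_gray()].
#' @return List with `mean`, `sd`, `n` (pooled over the union of the discs)
#'   and `homogeneity`, a data frame with one row per circle pair
#'   (`pair`, `route`, `p_value`, `pass`).
#' @export
measure_parenchyma <- function(image, circles, calibration = image$calibration,
                               alpha = 0.05,
                               sd_denominator = c("sample", "population")) {
  stopifnot(inherits(image, "calibrated_image"))
  sd_denominator <- match.arg(sd_denominator)
  circles <- as.data.frame(circles)
  if (nrow(circles) != 3L) {
    stop(sprintf("parenchyma reference requires exactly 3 circles, got %d", nrow(circles)),
         call. = FALSE)
  }
  masks <- vector("list", 3L)
  for (i in 1:3) {
    radius <- circles$diameter_mm[i] / 2 * calibration$pixels_per_mm
    if (circles$row[i] - radius < -0.5 || circles$row[i] + radius > image$height - 0.5 ||
        circles$col[i] - radius < -0.5 || circles$col[i] + radius > image$width - 0.5) {
      stop(sprintf("parenchyma circle %d extends beyond the image", i), call. = FALSE)
    }
    masks[[i]] <- rasterize_circle(c(circles$row[i], circles$col[i]),
                                   circles$diameter_mm[i], calibration,
                                   image$width, image$height)
  }
  pooled <- compute_moments(image, union_masks(masks))
  pairs <- utils::combn(3L, 2L)
  homog <- data.frame(pair = character(0), route = character(0),
                      p_value = numeric(0), pass = logical(0))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    gi <- as.numeric(image$gray[masks[[i]]])
    gj <- as.numeric(image$gray[masks[[j]]])
    res <- compare_two_samples(gi, gj, alpha = alpha)
    homog <- rbind(homog, data.frame(
      pair = sprintf("%d-%d", i, j), route = res$route,
      p_value = res$p_value, pass = !res$significant
    ))
  }
  list(
    mean = mean_gray(pooled),
    sd = if (pooled$n >= 2) sd_gray(pooled, sd_denominator) else NA_real_,
    n = pooled$n,
    homogeneity = homog
  )
}
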