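# Synthetic EUS-like phantom generator. Regions (parenchyma background,
# solid lesion tissue, optional wall, anechoic cystic lobules) are ellipses;
# pixel noise is an independent per-pixel truncated normal on [0, 255],
# rounded to integers. Only first-order statistics are modelled - the group
# table reports nothing beyond mean/SD per region - so no spatially
# correlated speckle is simulated by default.

# moments of N(mu, sigma) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo = 0, hi = 255) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) whose [0,255]-truncation realizes the target mean/sd.
# The group table's region statistics are measurements of 8-bit pixels, i.e.
# of the truncated distribution, so the generator matches realized moments.
match_truncnorm <- function(target_mean, target_sd, lo = 0, hi = 255) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  # truncation negligible when the parent lies well inside [lo, hi]
  if (target_mean - 5 * target_sd >= lo && target_mean + 5 * target_sd <= hi) {
    return(c(mu = target_mean, sigma = target_sd))
  }
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# n draws from the moment-matched truncated normal, rounded to 8-bit ints.
# Sampling is by inverse CDF (exactly the truncated distribution - draws
# outside [0, 255] never occur, equivalent to redrawing them); the tail that
# holds [0, 255] is computed in whichever tail of the normal is better
# conditioned, so even far-out parent parameters sample correctly.
rtrunc8 <- function(n, target_mean, target_sd) {
  if (target_sd == 0) return(rep(as.integer(round(target_mean)), n))
  par <- match_truncnorm(target_mean, target_sd)
  a <- (0 - par[["mu"]]) / par[["sigma"]]
  b <- (255 - par[["mu"]]) / par[["sigma"]]
  if (a >= 0) { # window in the upper tail: work with upper-tail probabilities
    ua <- stats::pnorm(a, lower.tail = FALSE)
    ub <- stats::pnorm(b, lower.tail = FALSE)
    z <- stats::qnorm(stats::runif(n, ub, ua), lower.tail = FALSE)
  } else if (b <= 0) {
    ua <- stats::pnorm(a)
    ub <- stats::pnorm(b)
    z <- stats::qnorm(stats::runif(n, ua, ub))
  } else {
    z <- stats::qnorm(stats::runif(n, stats::pnorm(a), stats::pnorm(b)))
  }
  x <- par[["mu"]] + par[["sigma"]] * z
  as.integer(pmin(pmax(round(x), 0), 255))
}

# ellipse semi_axes_mm[1] spans rows, [2] spans cols
ellipse_member <- function(rows, cols, ellipse, pixels_per_mm) {
  a_px <- ellipse$semi_axes_mm[1] * pixels_per_mm
  b_px <- ellipse$semi_axes_mm[2] * pixels_per_mm
  ((rows - ellipse$center[1]) / a_px)^2 + ((cols - ellipse$center[2]) / b_px)^2 <= 1
}

ellipse_polygon <- function(ellipse, pixels_per_mm, n_vertices = 72L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(ellipse$center[1] + ellipse$semi_axes_mm[1] * pixels_per_mm * sin(th),
        ellipse$center[2] + ellipse$semi_axes_mm[2] * pixels_per_mm * cos(th))
}

#' Phantom specification
#'
#' The stated world of one synthetic frame: image geometry and calibration,
#' background (parenchyma) noise, a solid-tissue lesion ellipse, anechoic
#' cystic content inside it, and an optional echogenic wall ring. All region
#' statistics are realized (post-truncation) mean/SD in 8-bit gray levels;
#' ellipse centers are `(row, col)` pixel coordinates and semi-axes are in
#' millimetres (`semi_axes_mm[1]` along rows, `[2]` along columns).
#'
#' The cystic content can be given in one of two ways:
#' \itemize{
#'   \item `lobules`: an explicit list of lobule ellipses (`center`,
#'     `semi_axes_mm`, `mean`, `sd`), each fully inside the lesion;
#'   \item `cystic_partition`: a concentric similar ellipse split into `k`
#'     lobules by `k - 1` thin solid-tissue septa perpendicular to the long
#'     axis, sized so the *net* cystic/whole area fraction (septa excluded)
#'     is `fraction`. This is how the cohort generator reaches high cystic
#'     fractions with several lobules, which packings of disjoint ellipses
#'     cannot (two equal non-overlapping lobules cap the fraction at 0.5),
#'     and it mirrors the septated morphology of real multilocular lesions.
#' }
#'
#' @param width,height Image size in pixels (defaults: the source frames'
#'   1280 x 960).
#' @param calibration A [calibration_spec()] (default 12.2674 px/mm).
#' @param background `c(mean, sd)` of the parenchyma noise field.
#' @param lesion List `center`, `semi_axes_mm`, `mean`, `sd` of the solid
#'   lesion tissue.
#' @param lobules List of explicit lobule ellipses (see above).
#' @param cystic_partition List `fraction`, `k`, `mean`, `sd`, optional
#'   `septum_mm` (default 1.2, a typical intracystic septum thickness);
#'   mutually exclusive with `lobules`.
#' @param wall Optional list `thickness_mm`, `mean`, `sd`: an inner ring of
#'   the lesion ellipse rendered as wall tissue.
#' @param parenchyma_circles Optional 3-row data frame (`row`, `col`,
#'   `diameter_mm`); `NULL` requests automatic placement in the background.
#' @param seed Integer random seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 1280L, height = 960L,
                         calibration = calibration_spec(),
                         background = c(68.3, 11.3),
                         lesion = list(center = c(height / 2, width / 2),
                                       semi_axes_mm = c(12, 12),
                                       mean = 39.0, sd = 21.1),
                         lobules = list(),
                         cystic_partition = NULL,
                         wall = NULL,
                         parenchyma_circles = NULL,
                         seed = 1L) {
  stopifnot(inherits(calibration, "calibration_spec"),
            length(background) == 2L, background[2] >= 0)
  ppm <- calibration$pixels_per_mm
  check_mean <- function(m) m >= 0 && m <= 255
  stopifnot(check_mean(background[1]), check_mean(lesion$mean), lesion$sd >= 0)
  if (length(lobules) && !is.null(cystic_partition)) {
    stop("give either explicit 'lobules' or a 'cystic_partition', not both", call. = FALSE)
  }
  for (i in seq_along(lobules)) {
    lb <- lobules[[i]]
    stopifnot(check_mean(lb$mean), lb$sd >= 0)
    th <- seq(0, 2 * pi, length.out = 37L)
    br <- lb$center[1] + lb$semi_axes_mm[1] * ppm * sin(th)
    bc <- lb$center[2] + lb$semi_axes_mm[2] * ppm * cos(th)
    if (!all(ellipse_member(br, bc, lesion, ppm))) {
      stop(sprintf("lobule %d is not fully inside the lesion ellipse", i), call. = FALSE)
    }
  }
  if (!is.null(cystic_partition)) {
    cp <- cystic_partition
    stopifnot(cp$fraction > 0, cp$fraction < 1, cp$k >= 1,
              check_mean(cp$mean), cp$sd >= 0)
    if (is.null(cp$septum_mm)) cystic_partition$septum_mm <- 1.2
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         calibration = calibration, background = background,
         lesion = lesion, lobules = lobules,
         cystic_partition = cystic_partition, wall = wall,
         parenchyma_circles = parenchyma_circles, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# deterministic placement of three 5-mm parenchyma circles in the background:
# scan a coarse grid, keep the first three centers whose disc stays inside
# the image and clear of the lesion ellipse
place_parenchyma_circles <- function(spec) {
  ppm <- spec$calibration$pixels_per_mm
  radius <- 2.5 * ppm
  margin <- radius + 2
  if (spec$height - 1 - margin < margin || spec$width - 1 - margin < margin) {
    stop("image too small for 5-mm parenchyma circles", call. = FALSE)
  }
  rows <- seq(margin, spec$height - 1 - margin, by = max(radius, 4))
  cols <- seq(margin, spec$width - 1 - margin, by = max(2.2 * radius, 8))
  lesion_grow <- spec$lesion
  lesion_grow$semi_axes_mm <- lesion_grow$semi_axes_mm + radius / ppm + 2 / ppm
  found <- NULL
  for (r in rows) {
    for (cc in cols) {
      if (!ellipse_member(r, cc, lesion_grow, ppm)) {
        found <- rbind(found, c(r, cc))
        if (nrow(found) == 3L) {
          return(data.frame(row = found[, 1], col = found[, 2], diameter_mm = 5))
        }
      }
    }
  }
  stop("could not place three 5-mm parenchyma circles clear of the lesion", call. = FALSE)
}

# lobule masks and seed points for a septa-partitioned concentric cystic
# region; returns list(masks = list, seeds = data.frame-ready list)
partition_lobules <- function(spec, rows, cols) {
  cp <- spec$cystic_partition
  ppm <- spec$calibration$pixels_per_mm
  les <- spec$lesion
  a_px <- les$semi_axes_mm[1] * ppm # rows
  b_px <- les$semi_axes_mm[2] * ppm # cols
  nr <- (rows - les$center[1]) / a_px
  nc <- (cols - les$center[2]) / b_px
  k <- as.integer(cp$k)
  # partition along the longer pixel axis
  along_cols <- b_px >= a_px
  coord <- if (along_cols) nc else nr
  axis_px <- if (along_cols) b_px else a_px
  # linear scale of the cystic similar ellipse, inflated so the net fraction
  # after removing the septa strips is cp$fraction: with mean septum chord
  # ~ (pi/2) s P, solving s^2 - c s - fraction = 0, c = (k-1) w / (2 L)
  cc <- (k - 1) * (cp$septum_mm * ppm) / (2 * axis_px)
  scale <- min((cc + sqrt(cc^2 + 4 * cp$fraction)) / 2, 0.98)
  extent <- nr^2 + nc^2 <= scale^2
  hw <- (cp$septum_mm * ppm / 2) / axis_px # septum half-width, normalized
  cuts <- seq(-scale, scale, length.out = k + 1L)
  masks <- vector("list", k)
  seed_rc <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    lo <- cuts[i] + if (i > 1L) hw else 0
    hi <- cuts[i + 1L] - if (i < k) hw else 0
    masks[[i]] <- extent & coord > lo & coord < hi
    mid <- (lo + hi) / 2
    seed_rc[i, ] <- if (along_cols) {
      c(les$center[1], les$center[2] + mid * b_px)
    } else {
      c(les$center[1] + mid * a_px, les$center[2])
    }
  }
  keep <- vapply(masks, any, logical(1))
  list(masks = masks[keep], seed_rc = seed_rc[keep, , drop = FALSE])
}

#' Render a phantom image with ground truth
#'
#' Assigns each pixel a region by ellipse membership (priority cyst > wall >
#' solid > background), draws its gray value from the region's moment-matched
#' truncated normal, and records the truth: per-region masks, realized
#' (post-noise) statistics computed directly on the truth masks, and the
#' annotation a perfect annotator would produce (72-vertex polygon on the
#' lesion boundary, one seed per lobule with tolerance = half the solid-cystic
#' mean gap, three 5-mm parenchyma circles). Rendering is deterministic:
#' identical spec and seed give a byte-identical image.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [calibrated_image()]) and `truth` (masks,
#'   realized statistics, annotation, spec).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  H <- spec$height
  W <- spec$width
  ppm <- spec$calibration$pixels_per_mm
  rows <- matrix(rep(0:(H - 1L), W), nrow = H)
  cols <- matrix(rep(0:(W - 1L), each = H), nrow = H)

  lesion_mask <- ellipse_member(rows, cols, spec$lesion, ppm)
  wall_mask <- matrix(FALSE, H, W)
  if (!is.null(spec$wall)) {
    inner <- spec$lesion
    inner$semi_axes_mm <- pmax(inner$semi_axes_mm - spec$wall$thickness_mm, 0)
    wall_mask <- lesion_mask & !ellipse_member(rows, cols, inner, ppm)
  }

  seed_rc <- NULL
  if (!is.null(spec$cystic_partition)) {
    part <- partition_lobules(spec, rows, cols)
    lobule_masks <- part$masks
    lobule_stats <- replicate(length(lobule_masks),
                              c(spec$cystic_partition$mean, spec$cystic_partition$sd),
                              simplify = FALSE)
    seed_rc <- part$seed_rc
  } else {
    lobule_masks <- lapply(spec$lobules, function(lb) ellipse_member(rows, cols, lb, ppm))
    lobule_stats <- lapply(spec$lobules, function(lb) c(lb$mean, lb$sd))
    if (length(spec$lobules)) {
      seed_rc <- do.call(rbind, lapply(spec$lobules, function(lb) {
        c(round(lb$center[1]), round(lb$center[2]))
      }))
    }
  }
  cystic_mask <- if (length(lobule_masks)) union_masks(lobule_masks) else matrix(FALSE, H, W)
  wall_mask <- wall_mask & !cystic_mask
  solid_mask <- lesion_mask & !cystic_mask & !wall_mask
  bg_mask <- !lesion_mask

  gray <- matrix(0L, H, W)
  gray[bg_mask] <- rtrunc8(sum(bg_mask), spec$background[1], spec$background[2])
  gray[solid_mask] <- rtrunc8(sum(solid_mask), spec$lesion$mean, spec$lesion$sd)
  if (any(wall_mask)) {
    gray[wall_mask] <- rtrunc8(sum(wall_mask), spec$wall$mean, spec$wall$sd)
  }
  for (i in seq_along(lobule_masks)) {
    lm <- lobule_masks[[i]] # explicit lobules may overlap: later wins
    gray[lm] <- rtrunc8(sum(lm), lobule_stats[[i]][1], lobule_stats[[i]][2])
  }
  image <- calibrated_image(gray, spec$calibration)

  realized <- function(mask) {
    if (!any(mask)) return(c(n = 0, mean = NA_real_, sd = NA_real_))
    m <- compute_moments(image, mask)
    c(n = m$n, mean = mean_gray(m), sd = if (m$n >= 2) sd_gray(m) else NA_real_)
  }
  stats_df <- rbind(
    parenchyma = realized(bg_mask),
    whole = realized(lesion_mask),
    cystic = realized(cystic_mask),
    solid = realized(solid_mask | wall_mask)
  )

  circles <- spec$parenchyma_circles
  if (is.null(circles)) circles <- place_parenchyma_circles(spec)
  solid_means <- c(spec$lesion$mean, if (!is.null(spec$wall)) spec$wall$mean)
  seeds <- NULL
  if (!is.null(seed_rc) && nrow(seed_rc)) {
    seeds <- do.call(rbind, lapply(seq_len(nrow(seed_rc)), function(i) {
      cy_mean <- lobule_stats[[i]][1]
      # a careful annotator seeds on a pixel representative of the lobule:
      # among lobule pixels, take the one closest in gray to the lobule mean,
      # breaking ties by distance to the lobule's reference point
      lm <- lobule_masks[[i]]
      idx <- which(lm)
      rr <- (idx - 1L) %% H
      cc2 <- (idx - 1L) %/% H
      dg <- abs(as.numeric(gray[idx]) - cy_mean)
      dd <- (rr - seed_rc[i, 1])^2 + (cc2 - seed_rc[i, 2])^2
      best <- idx[order(dg, dd)][1L]
      tol <- max(1L, as.integer(round((min(solid_means) - cy_mean) / 2)))
      data.frame(row = (best - 1L) %% H, col = (best - 1L) %/% H,
                 tolerance = min(max(tol, 1L), 255L))
    }))
  }
  annotation <- lesion_annotation(
    image_id = sprintf("phantom_seed%d", spec$seed),
    lesion_polygon = ellipse_polygon(spec$lesion, ppm),
    cystic_seeds = seeds,
    parenchyma_circles = circles,
    calibration = spec$calibration
  )

  list(
    image = image,
    truth = list(
      masks = list(parenchyma = bg_mask, whole = lesion_mask,
                   cystic = cystic_mask, solid = solid_mask | wall_mask,
                   lobules = lobule_masks),
      realized = as.data.frame(stats_df),
      annotation = annotation,
      spec = spec
    )
  )
}

#' Group-level phantom parameterizations from the study's group table
#'
#' Returns the three diagnosis-group parameterizations, every number traceable
#' to a cell of the source group table:
#' \itemize{
#'   \item per-group image counts 30 (SCN), 81 (Non-SCN), 59 (Pseudocyst);
#'   \item parenchyma pixel noise: mean 68.9/68.3/69.4, SD 10.4/11.3/11.1
#'     (the parenchyma `+/-` entries are labelled SD and read as within-region
#'     pixel SD);
#'   \item cystic-part pixel statistics: mean 9.7/11.1/7.5, SD 7.1/6.9/7.1
#'     (echogenicity and inhomogeneity rows);
#'   \item solid-part pixel statistics: mean 31.4/39.0/40.7, SD
#'     16.1/21.1/24.3;
#'   \item whole-lesion area (mm^2): mean 415.8/433.2/590.4, between-image SD
#'     read from the printed `+/-` (64.2/47.4/77.6);
#'   \item cystic/whole area-ratio targets 0.57/0.39/0.61, jittered between
#'     images with SD 0.15 (the table prints only group means; see the
#'     methods vignette);
#'   \item mean lobule counts 2.1/2.4/1.2;
#'   \item between-image jitter SD of the cystic/solid region means = printed
#'     `+/-` (read as SEM) times `sqrt(n)`.
#' }
#'
#' @return Named list (`SCN`, `Non-SCN`, `Pseudocyst`) of group spec lists.
#' @export
default_group_specs <- function() {
  mk <- function(n, parenchyma, cystic, solid, area, ratio, lobules,
                 cystic_sem, solid_sem) {
    list(
      n_images = n,
      parenchyma = parenchyma,           # c(pixel mean, pixel sd)
      cystic = cystic,                   # c(pixel mean, pixel sd)
      solid = solid,                     # c(pixel mean, pixel sd)
      area_mm2 = area,                   # c(mean, between-image sd)
      area_ratio = ratio,                # group-mean cystic fraction
      area_ratio_sd = 0.15,
      lobule_mean = lobules,
      cystic_mean_sd = cystic_sem * sqrt(n),  # between-image SD of region means
      solid_mean_sd = solid_sem * sqrt(n)
    )
  }
  list(
    "SCN" = mk(30, c(68.9, 10.4), c(9.7, 7.1), c(31.4, 16.1),
               c(415.8, 64.2), 0.57, 2.1, 0.7, 1.2),
    "Non-SCN" = mk(81, c(68.3, 11.3), c(11.1, 6.9), c(39.0, 21.1),
                   c(433.2, 47.4), 0.39, 2.4, 0.4, 1.2),
    "Pseudocyst" = mk(59, c(69.4, 11.1), c(7.5, 7.1), c(40.7, 24.3),
                      c(590.4, 77.6), 0.61, 1.2, 0.7, 1.6)
  )
}

# draw one per-image phantom_spec from a group parameterization; consumes the
# caller's RNG stream, `seed` only stamps the rendering seed
draw_image_spec <- function(gspec, width, height, calibration, seed) {
  ppm <- calibration$pixels_per_mm
  area <- max(stats::rnorm(1, gspec$area_mm2[1], gspec$area_mm2[2]), 40)
  ratio <- min(max(stats::rnorm(1, gspec$area_ratio, gspec$area_ratio_sd), 0.05), 0.95)
  k <- 1L + stats::rpois(1, max(gspec$lobule_mean - 1, 0))
  cy_mean <- min(max(stats::rnorm(1, gspec$cystic[1], gspec$cystic_mean_sd), 1), 254)
  so_mean <- min(max(stats::rnorm(1, gspec$solid[1], gspec$solid_mean_sd), 1), 254)

  aspect <- stats::runif(1, 0.6, 1)
  a_mm <- sqrt(area / (pi * aspect)) # along columns
  b_mm <- a_mm * aspect              # along rows
  # keep the lesion inside the frame with room for the parenchyma circles
  max_a <- min(width, height) / (2 * ppm) - 3
  if (a_mm > max_a) {
    b_mm <- b_mm * max_a / a_mm
    a_mm <- max_a
  }
  lesion <- list(center = c(height / 2, width / 2),
                 semi_axes_mm = c(b_mm, a_mm),
                 mean = so_mean, sd = gspec$solid[2])
  phantom_spec(
    width = width, height = height, calibration = calibration,
    background = gspec$parenchyma, lesion = lesion,
    cystic_partition = list(fraction = ratio, k = k,
                            mean = cy_mean, sd = gspec$cystic[2]),
    seed = seed
  )
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-image phantom specifications from the group-level
#' parameterizations (region means jittered between images, lobule counts and
#' cystic fractions per group), renders each phantom, and either writes the
#' cohort to disk (PNG image + JSON annotation per frame + a manifest CSV
#' with columns `image_path, annotation_path, group`) or returns it in
#' memory. Fully reproducible from `seed`.
#'
#' @param group_specs See [default_group_specs()].
#' @param n_images Named integer vector of images per group; defaults to each
#'   group's `n_images` (30/81/59, the study's cohort of 170 frames).
#' @param seed Master seed.
#' @param out_dir Output directory; `NULL` keeps the cohort in memory.
#' @param width,height,pixels_per_mm Image geometry; defaults are the source
#'   frames' 1280 x 960 at 12.2674 px/mm. A smaller calibration and frame
#'   give scaled-down cohorts with identical gray statistics and mm^2 areas.
#' @return List with `manifest` (one row per image) plus `manifest_path` when
#'   writing, or `images`, `annotations` and `truths` lists when in memory.
#' @export
generate_cohort <- function(group_specs = default_group_specs(),
                            n_images = NULL, seed = 1L, out_dir = NULL,
                            width = 1280L, height = 960L,
                            pixels_per_mm = 12.2674) {
  if (is.null(n_images)) {
    n_images <- vapply(group_specs, `[[`, numeric(1), "n_images")
  }
  if (any(n_images < 1)) stop("need at least one image per group", call. = FALSE)
  stopifnot(!is.null(names(n_images)), all(names(n_images) %in% names(group_specs)))
  calibration <- calibration_spec(pixels_per_mm)
  set.seed(seed)
  image_seeds <- sample.int(2^31 - 1, sum(n_images))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # draw every per-image spec from the master stream first: rendering
  # re-seeds the RNG with the per-image seed
  specs <- list()
  idx <- 0L
  for (g in names(n_images)) {
    for (i in seq_len(n_images[[g]])) {
      idx <- idx + 1L
      specs[[idx]] <- list(
        group = g, i = i,
        spec = draw_image_spec(group_specs[[g]], width, height, calibration,
                               seed = image_seeds[idx])
      )
    }
  }

  manifest <- NULL
  images <- list()
  annotations <- list()
  truths <- list()
  for (entry in specs) {
    {
      g <- entry$group
      rendered <- render_phantom(entry$spec)
      id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "", g), entry$i)
      rendered$truth$annotation$image_id <- id
      if (!is.null(out_dir)) {
        img_path <- file.path(out_dir, paste0(id, ".png"))
        ann_path <- file.path(out_dir, paste0(id, ".json"))
        png::writePNG(rendered$image$gray / 255, target = img_path)
        write_annotation(rendered$truth$annotation, ann_path)
        manifest <- rbind(manifest, data.frame(
          image_path = img_path, annotation_path = ann_path, group = g
        ))
      } else {
        images[[id]] <- rendered$image
        annotations[[id]] <- rendered$truth$annotation
        truths[[id]] <- rendered$truth
        manifest <- rbind(manifest, data.frame(
          image_path = id, annotation_path = id, group = g
        ))
      }
    }
  }
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.csv")
    utf8_write_csv(manifest, manifest_path)
    list(manifest = manifest, manifest_path = manifest_path)
  } else {
    list(manifest = manifest, images = images, annotations = annotations,
         truths = truths)
  }
}
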