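# Region masks are logical matrices (height x width) aligned with the parent
# image; mask[r + 1, c + 1] is pixel (row = r, col = c) in the 0-based
# pixel-center frame.

new_mask <- function(width, height) {
  matrix(FALSE, nrow = height, ncol = width)
}

check_same_dim <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched dimensions (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
}

#' Rasterize a polygon to a pixel mask
#'
#' Emulates the free-hand selection of a lesion outline: a pixel is a member
#' iff its center lies inside the polygon under the even-odd rule; centers
#' exactly on an edge are resolved by the half-open boundary of the crossing
#' test (adjacent polygons tile the grid without double-counting). The mask is
#' clipped to the image bounds.
#'
#' @param polygon Numeric matrix of `(row, col)` vertices, >= 3, simple,
#'   non-zero area.
#' @param width,height Image dimensions in pixels.
#' @return Logical `height x width` mask matrix.
#' @export
rasterize_polygon <- function(polygon, width, height) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs >= 3 vertices", call. = FALSE)
  if (abs(polygon_area_signed(polygon)) <= 0) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }
  mask <- new_mask(width, height)
  r0 <- max(0L, as.integer(ceiling(min(polygon[, 1]))))
  r1 <- min(height - 1L, as.integer(floor(max(polygon[, 1]))))
  c0 <- max(0L, as.integer(ceiling(min(polygon[, 2]))))
  c1 <- min(width - 1L, as.integer(floor(max(polygon[, 2]))))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1
  cols <- c0:c1
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  inside <- point_in_polygon(pr, pc, polygon)
  mask[cbind(pr + 1L, pc + 1L)] <- inside
  mask
}

#' Rasterize a calibrated circle to a pixel mask
#'
#' A pixel is a member iff the Euclidean distance from its center to the
#' circle center is at most `diameter_mm / 2 * pixels_per_mm`. Used for the
#' three 5-mm reference circles over healthy parenchyma; a circle that would
#' lie entirely outside the image is rejected (a clipped reference area
#' defeats standardization).
#'
#' @param center Numeric `(row, col)` circle center in pixel coordinates.
#' @param diameter_mm Circle diameter in millimetres, > 0.
#' @param calibration A [calibration_spec()].
#' @param width,height Image dimensions in pixels.
#' @return Logical mask matrix.
#' @export
rasterize_circle <- function(center, diameter_mm, calibration, width, height) {
  stopifnot(inherits(calibration, "calibration_spec"), length(center) == 2L)
  if (!is.numeric(diameter_mm) || diameter_mm <= 0) {
    stop("diameter_mm must be > 0", call. = FALSE)
  }
  radius <- diameter_mm / 2 * calibration$pixels_per_mm
  mask <- new_mask(width, height)
  r0 <- max(0L, as.integer(ceiling(center[1] - radius)))
  r1 <- min(height - 1L, as.integer(floor(center[1] + radius)))
  c0 <- max(0L, as.integer(ceiling(center[2] - radius)))
  c1 <- min(width - 1L, as.integer(floor(center[2] + radius)))
  if (r0 > r1 || c0 > c1) {
    stop("circle lies entirely outside the image", call. = FALSE)
  }
  rows <- r0:r1
  cols <- c0:c1
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  member <- (pr - center[1])^2 + (pc - center[2])^2 <= radius^2
  if (!any(member)) stop("circle lies entirely outside the image", call. = FALSE)
  mask[cbind(pr + 1L, pc + 1L)] <- member
  mask
}

# neighbor indices of a frontier (column-major linear indices) under 4- or
# 8-connectivity, with image-border guards
neighbor_indices <- function(frontier, height, width, connectivity = 4L) {
  r <- (frontier - 1L) %% height   # 0-based row
  cc <- (frontier - 1L) %/% height # 0-based col
  nb <- c(
    frontier[r > 0L] - 1L,
    frontier[r < height - 1L] + 1L,
    frontier[cc > 0L] - height,
    frontier[cc < width - 1L] + height
  )
  if (connectivity == 8L) {
    ul <- r > 0L & cc > 0L
    ur <- r > 0L & cc < width - 1L
    dl <- r < height - 1L & cc > 0L
    dr <- r < height - 1L & cc < width - 1L
    nb <- c(nb,
            frontier[ul] - 1L - height, frontier[ur] - 1L + height,
            frontier[dl] + 1L - height, frontier[dr] + 1L + height)
  }
  nb
}

# connected component of `admissible` containing linear index `seed_idx`
flood_component <- function(admissible, seed_idx, connectivity = 4L) {
  height <- nrow(admissible)
  width <- ncol(admissible)
  visited <- matrix(FALSE, height, width)
  frontier <- seed_idx
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nb <- neighbor_indices(frontier, height, width, connectivity)
    nb <- nb[admissible[nb] & !visited[nb]]
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Tolerance-based seeded region growing
#'
#' Reimplements the tracing-tool semantics of the analysis protocol: starting
#' from a user-chosen pixel inside a cystic (anechoic) compartment, grow the
#' maximal connected set of pixels whose gray value differs from the *seed*
#' pixel's gray value by at most `tolerance`. The admissible band is anchored
#' to the seed (not a running mean), so the result is independent of visit
#' order. Growth may be restricted to a constraint mask (typically the lesion
#' polygon).
#'
#' @param image A [calibrated_image()].
#' @param seed Numeric `(row, col)` pixel position (0-based, integer-valued).
#' @param tolerance Integer gray-level tolerance in `[0, 255]`.
#' @param constraint Optional logical mask; when given, the seed must be a
#'   member and growth never leaves it.
#' @param connectivity 4 (default) or 8.
#' @return Logical mask matrix containing the seed.
#' @export
grow_region <- function(image, seed, tolerance, constraint = NULL, connectivity = 4L) {
  stopifnot(inherits(image, "calibrated_image"))
  connectivity <- match.arg(as.character(connectivity), c("4", "8"))
  connectivity <- as.integer(connectivity)
  if (tolerance != as.integer(tolerance) || tolerance < 0 || tolerance > 255) {
    stop("tolerance must be an integer in [0, 255]", call. = FALSE)
  }
  r <- as.integer(round(seed[1]))
  cc <- as.integer(round(seed[2]))
  if (r < 0L || r >= image$height || cc < 0L || cc >= image$width) {
    stop(sprintf("seed (%d, %d) is out of image bounds", r, cc), call. = FALSE)
  }
  seed_idx <- cc * image$height + r + 1L
  g0 <- image$gray[seed_idx]
  admissible <- abs(image$gray - as.integer(g0)) <= tolerance
  if (!is.null(constraint)) {
    check_same_dim(admissible, constraint, "image and constraint mask")
    if (!constraint[seed_idx]) {
      stop(sprintf("seed (%d, %d) lies outside the constraint mask", r, cc), call. = FALSE)
    }
    admissible <- admissible & constraint
  }
  flood_component(admissible, seed_idx, connectivity)
}

#' Union of region masks
#'
#' Pixelwise logical OR; merging the grown regions of several cystic seeds
#' before measurement prevents double counting of overlapping selections.
#'
#' @param masks List of logical mask matrices of identical dimensions.
#' @return Logical mask matrix (all-`FALSE` of the first mask's dimensions if
#'   the list is empty is not representable; the list must be non-empty).
#' @export
union_masks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  out <- masks[[1]]
  for (m in masks[-1]) {
    check_same_dim(out, m)
    out <- out | m
  }
  out
}

#' Set difference of region masks
#'
#' Members of `a` that are not members of `b`; the mask-level support of the
#' whole-minus-cystic solid-part subtraction. `b` is expected to be a subset
#' of `a`; stray members of `b` outside `a` are tolerated as annotation noise
#' (warned about, with the discarded pixel count) and intersected away.
#'
#' @param a,b Logical mask matrices of identical dimensions.
#' @return Logical mask matrix.
#' @export
subtract_mask <- function(a, b) {
  check_same_dim(a, b)
  stray <- sum(b & !a)
  if (stray > 0L) {
    warning(sprintf("%d pixel(s) of the subtrahend lie outside the minuend and were discarded", stray),
            call. = FALSE)
  }
  a & !b
}

# all connected components of a logical mask; returns a list of masks
connected_components <- function(mask, connectivity = 4L) {
  comps <- list()
  remaining <- mask
  repeat {
    idx <- which(remaining)
    if (!length(idx)) break
    comp <- flood_component(remaining, idx[1L], connectivity)
    comps[[length(comps) + 1L]] <- comp
    remaining <- remaining & !comp
  }
  comps
}

#' Count cystic lobules
#'
#' Number of connected components of the union of the grown cystic masks; two
#' seeds whose regions touch count as one lobule.
#'
#' @param cystic_masks List of logical mask matrices (may be empty).
#' @param connectivity 4 (default) or 8.
#' @return Integer component count (0 for an empty list or all-empty masks).
#' @export
count_lobules <- function(cystic_masks, connectivity = 4L) {
  if (!length(cystic_masks)) return(0L)
  u <- union_masks(cystic_masks)
  length(connected_components(u, connectivity))
}
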