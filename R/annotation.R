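# Polygon geometry helpers shared by annotation validation and rasterization.
# Coordinates are (row, col), 0-based, pixel centers at integers.

# Even-odd crossing test, vectorized over query points. Points exactly on an
# edge fall on one consistent side of the half-open boundary (adjacent
# polygons tile without overlap).
point_in_polygon <- function(prow, pcol, poly) {
  vr <- poly[, 1]
  vc <- poly[, 2]
  n <- length(vr)
  inside <- rep(FALSE, length(prow))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > prow) != (vr[j] > prow))
    if (any(crosses)) {
      xi <- (vc[j] - vc[i]) * (prow[crosses] - vr[i]) / (vr[j] - vr[i]) + vc[i]
      hit <- pcol[crosses] < xi
      inside[crosses] <- xor(inside[crosses], hit)
    }
    j <- i
  }
  inside
}

polygon_area_signed <- function(poly) {
  r <- poly[, 1]
  c <- poly[, 2]
  rn <- c(r[-1], r[1])
  cn <- c(c[-1], c[1])
  sum(c * rn - cn * r) / 2
}

# proper/improper intersection of two closed segments
segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  d1 <- orient(q1, q2, p1)
  d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1)
  d4 <- orient(p1, p2, q2)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_seg(q1, q2, p1)) || (d2 == 0 && on_seg(q1, q2, p2)) ||
    (d3 == 0 && on_seg(p1, p2, q1)) || (d4 == 0 && on_seg(p1, p2, q2))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  seg <- function(i) list(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    si <- seg(i)
    for (k in seq(i + 1L, n)) {
      # skip edges sharing a vertex (consecutive, incl. the closing edge)
      if (k == i + 1L || (i == 1L && k == n)) next
      sk <- seg(k)
      if (segments_intersect(si[[1]], si[[2]], sk[[1]], sk[[2]])) return(FALSE)
    }
  }
  TRUE
}

#' Per-image lesion annotation
#'
#' Persists the interactive selections of the analysis protocol for one frame:
#' the free-hand whole-lesion outline as a polygon, one seed point with a gray
#' tolerance per cystic lobule (the tracing-tool "wand" input), and an
#' optional block of exactly three 5-mm reference circles over healthy
#' pancreatic parenchyma.
#'
#' @param image_id Identifier string for the frame.
#' @param lesion_polygon Numeric matrix with columns `(row, col)` (0-based
#'   pixel-center coordinates), at least 3 vertices, simple and of non-zero
#'   area.
#' @param cystic_seeds Data frame with columns `row`, `col`, `tolerance`
#'   (integer gray levels in `[0, 255]`); may have zero rows.
#' @param parenchyma_circles Optional data frame with columns `row`, `col`,
#'   `diameter_mm`; when present must have exactly 3 rows of diameter 5 mm.
#' @param calibration A [calibration_spec()].
#' @return Object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(image_id, lesion_polygon, cystic_seeds = NULL,
                              parenchyma_circles = NULL,
                              calibration = calibration_spec()) {
  stopifnot(is.character(image_id), length(image_id) == 1L,
            inherits(calibration, "calibration_spec"))
  lesion_polygon <- as.matrix(lesion_polygon)
  if (ncol(lesion_polygon) != 2L || nrow(lesion_polygon) < 3L) {
    stop("lesion_polygon must have >= 3 vertices with (row, col) columns", call. = FALSE)
  }
  if (!polygon_is_simple(lesion_polygon)) {
    stop("lesion_polygon must be simple (non-self-intersecting)", call. = FALSE)
  }
  if (abs(polygon_area_signed(lesion_polygon)) <= 0) {
    stop("lesion_polygon has zero area", call. = FALSE)
  }
  if (is.null(cystic_seeds)) {
    cystic_seeds <- data.frame(row = numeric(0), col = numeric(0), tolerance = integer(0))
  }
  cystic_seeds <- as.data.frame(cystic_seeds)
  stopifnot(all(c("row", "col", "tolerance") %in% names(cystic_seeds)))
  if (nrow(cystic_seeds)) {
    tol <- cystic_seeds$tolerance
    if (any(tol != as.integer(tol)) || any(tol < 0) || any(tol > 255)) {
      stop("seed tolerance must be an integer in [0, 255]", call. = FALSE)
    }
    inside <- point_in_polygon(cystic_seeds$row, cystic_seeds$col, lesion_polygon)
    if (!all(inside)) {
      stop(sprintf("cystic seed(s) %s lie outside the lesion polygon",
                   paste(which(!inside), collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(parenchyma_circles)) {
    parenchyma_circles <- as.data.frame(parenchyma_circles)
    stopifnot(all(c("row", "col", "diameter_mm") %in% names(parenchyma_circles)))
    if (nrow(parenchyma_circles) != 3L) {
      stop(sprintf("parenchyma block requires exactly 3 circles, got %d",
                   nrow(parenchyma_circles)), call. = FALSE)
    }
    if (any(parenchyma_circles$diameter_mm != 5)) {
      stop("parenchyma reference circles must have diameter 5 mm", call. = FALSE)
    }
  }
  structure(
    list(
      image_id = image_id,
      lesion_polygon = lesion_polygon,
      cystic_seeds = cystic_seeds,
      parenchyma_circles = parenchyma_circles,
      calibration = calibration
    ),
    class = "lesion_annotation"
  )
}

#' @export
print.lesion_annotation <- function(x, ...) {
  cat(sprintf(
    "Lesion annotation '%s': %d polygon vertices, %d cystic seed(s), %s parenchyma block, %.6g px/mm\n",
    x$image_id, nrow(x$lesion_polygon), nrow(x$cystic_seeds),
    if (is.null(x$parenchyma_circles)) "no" else "3-circle", x$calibration$pixels_per_mm
  ))
  invisible(x)
}

#' Read a lesion annotation from JSON
#'
#' The file schema is documented in the package README: fields `image_id`,
#' `pixels_per_mm` (default 12.2674 when absent), `lesion_polygon` (list of
#' `[row, col]`), `cystic_seeds` (list of `{row, col, tolerance}`) and the
#' optional `parenchyma_circles` (list of `{row, col, diameter_mm}`). All
#' invariants of [lesion_annotation()] are validated, with violations reported
#' by field.
#'
#' @param path Path to the JSON annotation file.
#' @return A [lesion_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation not found: '%s'", path), call. = FALSE)
  }
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$image_id) || is.null(x$lesion_polygon)) {
    stop(sprintf("annotation '%s' lacks image_id or lesion_polygon", path), call. = FALSE)
  }
  ppm <- if (is.null(x$pixels_per_mm)) 12.2674 else x$pixels_per_mm
  poly <- x$lesion_polygon
  if (is.list(poly)) poly <- do.call(rbind, poly)
  seeds <- x$cystic_seeds
  if (!is.null(seeds) && !is.data.frame(seeds)) seeds <- as.data.frame(seeds)
  if (!is.null(seeds) && nrow(seeds) == 0L) seeds <- NULL
  circles <- x$parenchyma_circles
  if (!is.null(circles) && !is.data.frame(circles)) circles <- as.data.frame(circles)
  lesion_annotation(
    image_id = as.character(x$image_id),
    lesion_polygon = poly,
    cystic_seeds = seeds,
    parenchyma_circles = circles,
    calibration = calibration_spec(ppm)
  )
}

#' Write a lesion annotation to JSON
#'
#' @param annotation A [lesion_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "lesion_annotation"))
  obj <- list(
    image_id = annotation$image_id,
    pixels_per_mm = annotation$calibration$pixels_per_mm,
    lesion_polygon = unname(apply(annotation$lesion_polygon, 1L, function(v) c(v[1], v[2]),
                                  simplify = FALSE)),
    cystic_seeds = annotation$cystic_seeds
  )
  if (!is.null(annotation$parenchyma_circles)) {
    obj$parenchyma_circles <- annotation$parenchyma_circles
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
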