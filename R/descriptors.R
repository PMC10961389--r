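#' Ellipse of equivalent second central moments
#'
#' Fits the ellipse with the same normalized second central area moments as
#' the filled polygon. Moments are computed exactly from the polygon (no
#' rasterization), so the fit is deterministic and resolution-free.
#'
#' @param c a [contour()].
#' @return A list with `major` and `minor` (full axis lengths, `major >=
#'   minor`) and `angle`, the major-axis orientation in (-pi/2, pi/2].
#' @export
fit_ellipse_moments <- function(c) {
  mu <- polygon_central_moments(c)
  m00 <- mu[1L, 1L]
  if (m00 <= 0) stop("degenerate contour: zero area")
  cxx <- mu[3L, 1L] / m00
  cyy <- mu[1L, 3L] / m00
  cxy <- mu[2L, 2L] / m00
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  angle <- if (abs(cxy) < 1e-300 && cxx >= cyy) 0 else atan2(2 * cxy, cxx - cyy) / 2
  if (angle <= -pi / 2) angle <- angle + pi
  if (angle > pi / 2) angle <- angle - pi
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2), angle = angle)
}

#' Feret (caliper) diameters
#'
#' Maximum and minimum caliper widths of a contour, computed exactly on its
#' convex hull: the maximum is the hull diameter; the minimum is the smallest
#' width over directions perpendicular to hull edges (rotating calipers).
#'
#' @param c a [contour()].
#' @return A list with `feret_max` and `feret_min`.
#' @export
feret_diameters <- function(c) {
  pts <- as_points(c)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3L) stop("degenerate contour: collinear points, no caliper width")
  d2 <- as.matrix(stats::dist(hp))
  feret_max <- max(d2)
  nxt <- hp[c(2:nh, 1L), , drop = FALSE]
  e <- nxt - hp
  elen <- sqrt(rowSums(e^2))
  widths <- vapply(seq_len(nh), function(i) {
    if (elen[i] <= 0) return(Inf)
    # distance of all hull points from the line through edge i
    v <- sweep(hp, 2L, hp[i, ])
    max(abs(v[, 1L] * e[i, 2L] - v[, 2L] * e[i, 1L]) / elen[i])
  }, 0)
  list(feret_max = feret_max, feret_min = min(widths))
}

convex_hull_area <- function(c) {
  pts <- as_points(c)
  h <- grDevices::chull(pts)
  abs(signed_area(pts[h, , drop = FALSE]))
}

#' General morphological descriptors (GMDs)
#'
#' Computes the eight scalar descriptors used throughout the package for one
#' outline: area (shoelace), perimeter (polygon arc length), length and
#' width (Feret max/min calipers), circularity `4*pi*area/perimeter^2`
#' (clamped at 1, as digital contours can exceed it by discretization),
#' aspect ratio (major/minor axis of the moment-equivalent ellipse),
#' roundness `4*area/(pi*major^2)` and solidity (area / convex hull area).
#'
#' Length and width follow the particle-analysis caliper convention; the
#' aspect ratio uses the moments ellipse, which diverges from the Feret
#' ratio for lobed shapes.
#'
#' @param c a [contour()].
#' @param pixel_size physical length per pixel; area scales with its square.
#' @param group optional genotype/group label carried into the record.
#' @return A one-row data.frame with `contour_id`, `group`, `view`, the
#'   eight descriptors, and `border`.
#' @export
compute_gmd <- function(c, pixel_size = 1, group = NA_character_) {
  stopifnot(is_contour(c))
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  area <- polygon_area(c) * pixel_size^2
  perim <- contour_perimeter(c) * pixel_size
  fer <- feret_diameters(c)
  ell <- fit_ellipse_moments(c)
  hull_area <- convex_hull_area(c) * pixel_size^2
  data.frame(
    contour_id = c$id,
    group = group,
    view = c$view,
    area = area,
    perimeter = perim,
    length = fer$feret_max * pixel_size,
    width = fer$feret_min * pixel_size,
    circularity = min(4 * pi * area / perim^2, 1),
    aspect_ratio = ell$major / ell$minor,
    roundness = 4 * area / (pi * (ell$major * pixel_size)^2),
    solidity = area / hull_area,
    border = c$border,
    stringsAsFactors = FALSE
  )
}

#' @rdname compute_gmd
#' @param cs list of contours.
#' @param groups optional vector of group labels, one per contour.
#' @export
gmd_table <- function(cs, pixel_size = 1, groups = NULL) {
  if (is_contour(cs)) cs <- list(cs)
  if (is.null(groups)) groups <- rep(NA_character_, length(cs))
  if (length(groups) != length(cs))
    stop("`groups` must have one label per contour")
  do.call(rbind, Map(function(c, g) compute_gmd(c, pixel_size, g), cs, groups))
}

gmd_names <- c("area", "perimeter", "length", "width",
               "circularity", "aspect_ratio", "roundness", "solidity")
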