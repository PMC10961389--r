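#' Closed outline (contour) objects
#'
#' A `seed_contour` is the universal shape carrier of the package: an ordered,
#' implicitly closed polygon of vertex coordinates in a y-up frame. Contours
#' are stored counterclockwise (positive signed area); the constructor flips
#' clockwise input, removes consecutive duplicate vertices and validates
#' non-degeneracy.
#'
#' @param points two-column numeric matrix (or data.frame) of x, y vertex
#'   coordinates. The polygon is implicitly closed (last vertex connects to
#'   the first); a duplicated closing vertex is dropped.
#' @param id character label for the contour.
#' @param view one of `"lateral"`, `"dorsal"`, `"cell"`.
#' @param border logical; `TRUE` flags an object that touched the image
#'   border during extraction (partial silhouettes corrupt descriptors).
#' @return An object of class `seed_contour`: a list with elements `points`
#'   (n x 2 matrix, counterclockwise), `id`, `view`, `border`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 257)[-257]
#' circ <- contour(cbind(cos(th), sin(th)), id = "circle")
#' polygon_area(circ)
#' @export
contour <- function(points, id = "contour", view = c("lateral", "dorsal", "cell"),
                    border = FALSE) {
  view <- match.arg(view)
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop("`points` must be a two-column numeric matrix of x, y coordinates")
  if (anyNA(pts)) stop("contour coordinates contain missing values")
  # drop explicit closing vertex and consecutive duplicates
  n <- nrow(pts)
  if (n >= 2L && all(pts[1L, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("degenerate contour: fewer than 3 distinct vertices")
  a <- signed_area(pts)
  if (abs(a) < .Machine$double.eps * 100)
    stop("degenerate contour: zero area")
  if (a < 0) pts <- pts[nrow(pts):1L, , drop = FALSE]
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(list(points = pts, id = as.character(id), view = view,
                 border = isTRUE(border)),
            class = "seed_contour")
}

#' @export
print.seed_contour <- function(x, ...) {
  cat(sprintf("<seed_contour> '%s' (%s view): %d vertices, area %.4g%s\n",
              x$id, x$view, nrow(x$points), polygon_area(x),
              if (x$border) ", touches border" else ""))
  invisible(x)
}

#' @export
plot.seed_contour <- function(x, add = FALSE, ...) {
  p <- rbind(x$points, x$points[1L, ])
  if (add) graphics::lines(p, ...)
  else graphics::plot(p, type = "l", asp = 1, xlab = "x", ylab = "y",
                      main = x$id, ...)
  invisible(x)
}

is_contour <- function(x) inherits(x, "seed_contour")

as_points <- function(c) {
  if (is_contour(c)) c$points else as.matrix(c)
}

signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area, perimeter and centroid
#'
#' Shoelace area, polygonal arc length and area centroid of a closed contour.
#'
#' @param c a [contour()] or a two-column coordinate matrix.
#' @return `polygon_area` and `contour_perimeter` return a scalar;
#'   `contour_centroid` a length-2 vector.
#' @export
polygon_area <- function(c) abs(signed_area(as_points(c)))

#' @rdname polygon_area
#' @export
contour_perimeter <- function(c) {
  pts <- as_points(c)
  d <- diff(rbind(pts, pts[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' @rdname polygon_area
#' @export
contour_centroid <- function(c) {
  pts <- as_points(c)
  x <- pts[, 1L]; y <- pts[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(x = sum((x + x2) * cr) / (6 * a), y = sum((y + y2) * cr) / (6 * a))
}

# Raw area moments m[p+1, q+1] = integral of x^p y^q over the polygon
# interior, p + q <= 3, via signed triangle fans to the origin.
polygon_moments <- function(pts) {
  pts <- as_points(pts)
  x <- pts[, 1L]; y <- pts[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  M <- matrix(0, 4L, 4L)
  fct <- factorial(0:7)
  for (p in 0:3) for (q in 0:(3 - p)) {
    s <- 0
    for (i in 0:p) for (j in 0:q) {
      coef <- choose(p, i) * choose(q, j) *
        fct[i + j + 1L] * fct[p + q - i - j + 1L] / fct[p + q + 3L]
      s <- s + coef * sum(cr * x^i * x2^(p - i) * y^j * y2^(q - j))
    }
    M[p + 1L, q + 1L] <- s
  }
  if (M[1L, 1L] < 0) M <- -M  # clockwise input
  M
}

# Central moments mu[p+1, q+1] about the area centroid.
polygon_central_moments <- function(pts) {
  pts <- as_points(pts)
  ctr <- contour_centroid(pts)
  polygon_moments(sweep(pts, 2L, ctr))
}

#' Resample a contour to equally spaced vertices
#'
#' Linear interpolation along the polygon at `n_points` positions equally
#' spaced by arc length, starting from the original first vertex. Perimeter
#' and enclosed area are preserved to well under 0.1\% at the sampling
#' densities used in practice.
#'
#' @param c a [contour()].
#' @param n_points number of output vertices (>= 16).
#' @return A resampled [contour()] with the same `id` and `view`.
#' @export
resample_contour <- function(c, n_points) {
  stopifnot(is_contour(c))
  if (n_points < 16L) stop("`n_points` must be at least 16")
  pts <- rbind(c$points, c$points[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  len <- c(0, cumsum(seg))
  total <- len[length(len)]
  if (total <= 0) stop("degenerate contour: zero perimeter")
  s <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  out <- cbind(stats::approx(len, pts[, 1L], xout = s)$y,
               stats::approx(len, pts[, 2L], xout = s)$y)
  contour(out, id = c$id, view = c$view, border = c$border)
}

#' Stack outlines: centre and scale to unit centroid size
#'
#' Translates each contour to centroid origin and scales it so the root mean
#' squared distance of its vertices to the centroid (centroid size) is 1.
#' This is the standard superposition for landmark-free outline stacks.
#'
#' @param cs a list of [contour()] objects (a single contour is accepted).
#' @return A list of stacked contours in input order.
#' @export
stack_outlines <- function(cs) {
  if (is_contour(cs)) cs <- list(cs)
  if (length(cs) < 1L) stop("at least one contour is required")
  lapply(cs, function(c) {
    stopifnot(is_contour(c))
    pts <- sweep(c$points, 2L, contour_centroid(c))
    size <- sqrt(mean(rowSums(pts^2)))
    if (size <= 0) stop("degenerate contour: zero centroid size")
    contour(pts / size, id = c$id, view = c$view, border = c$border)
  })
}

centroid_size <- function(c) {
  pts <- sweep(as_points(c), 2L, contour_centroid(c))
  sqrt(mean(rowSums(pts^2)))
}

# Chaikin corner cutting; smooths the staircase of rasterized boundaries.
chaikin_smooth <- function(pts, iterations = 2L) {
  for (k in seq_len(iterations)) {
    nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
    q <- 0.75 * pts + 0.25 * nxt
    r <- 0.25 * pts + 0.75 * nxt
    pts <- matrix(rbind(t(q), t(r)), ncol = 2L, byrow = TRUE)
  }
  pts
}

rotate_points <- function(pts, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  pts %*% t(R)
}

#' @rdname polygon_area
#' @export
is_convex_contour <- function(c) {
  pts <- as_points(c)
  n <- nrow(pts)
  a <- pts[c(2:n, 1L), ] - pts
  b <- a[c(2:n, 1L), ]
  cr <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  all(cr >= -1e-12 * max(abs(cr)))
}
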