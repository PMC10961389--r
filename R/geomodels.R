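#' Cardioid-derived lateral seed model
#'
#' Polar curve `r(theta) = a (1 + cos theta)` sampled on `[0, 2*pi)`, rotated
#' so the cusp points down (symmetry axis vertical) and then scaled by `k`
#' along the symmetry axis; `k = 1` gives the plain cardioid. The result is
#' resampled to uniform arc length.
#'
#' @param a base scale (> 0); the plain cardioid has area `3*pi*a^2/2`.
#' @param k axis-scaling factor (> 0) applied along the symmetry axis.
#' @param n_points sampling density of the returned contour (>= 64).
#' @param id,view passed to [contour()].
#' @return A [contour()].
#' @export
cardioid_contour <- function(a = 1, k = 1, n_points = 360L,
                             id = "cardioid", view = "lateral") {
  if (a <= 0 || k <= 0) stop("cardioid parameters `a` and `k` must be positive")
  if (n_points < 64L) stop("`n_points` must be at least 64")
  th <- seq(0, 2 * pi, length.out = 4L * n_points + 1L)[-(4L * n_points + 1L)]
  r <- a * (1 + cos(th))
  # curve in canonical pose: cusp at the left; rotate +90 deg -> cusp down
  x0 <- r * cos(th); y0 <- r * sin(th)
  pts <- cbind(-y0, x0 * k)
  resample_contour(contour(pts, id = id, view = view), n_points)
}

#' Modified-ellipse dorsal seed model
#'
#' Ellipse `(a cos t, b sin t)` with a symmetric radial modification
#' `r -> r * (1 + m cos 2t)`, producing the flattened/ovate dorsal outline
#' family; `m = 0` returns the exact ellipse. The symmetry axis (the `a`
#' axis) is rotated to vertical so all registry models share a pose, and the
#' contour is resampled to uniform arc length.
#'
#' @param a,b semi-axes, `a >= b > 0`.
#' @param m modification amplitude, `|m| < 0.5`.
#' @param n_points sampling density (>= 64).
#' @param id,view passed to [contour()].
#' @return A [contour()].
#' @export
modified_ellipse_contour <- function(a = 1.5, b = 1, m = 0.1, n_points = 360L,
                                     id = "modified_ellipse", view = "dorsal") {
  if (!(a >= b && b > 0)) stop("modified ellipse requires a >= b > 0")
  if (abs(m) >= 0.5) stop("modification amplitude must satisfy |m| < 0.5")
  if (n_points < 64L) stop("`n_points` must be at least 64")
  t <- seq(0, 2 * pi, length.out = 4L * n_points + 1L)[-(4L * n_points + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  f <- 1 + m * cos(2 * t)
  if (any(f <= 0)) stop("parameters produce a self-intersecting contour")
  pts <- cbind(-y * f, x * f)  # symmetry axis vertical
  cc <- contour(pts, id = id, view = view)
  if (!is_simple_polygon(cc$points))
    stop("parameters produce a self-intersecting contour")
  resample_contour(cc, n_points)
}

# Registry of shipped model parameterizations. The published LM/DM curves
# are defined in external sources; these defaults preserve the family and
# methodology and are fully overridable (see `get_model(overrides = )`).
model_registry <- function() {
  list(
    LM1 = list(family = "cardioid_derived",
               params = list(a = 1, k = 1)),
    LM2 = list(family = "cardioid_derived",
               params = list(a = 1, k = 1.2)),
    DM2 = list(family = "modified_ellipse",
               params = list(a = 1.5, b = 1, m = 0.10)),
    DM3 = list(family = "modified_ellipse",
               params = list(a = 1.7, b = 1, m = 0.15))
  )
}

#' Look up a geometric seed model
#'
#' Returns a registered parametric model (lateral cardioid-derived LM1/LM2
#' or dorsal modified-ellipse DM2/DM3) together with its contour. Registry
#' defaults are placeholders for the published curves, which users can
#' reproduce by overriding parameters.
#'
#' @param name `"LM1"`, `"LM2"`, `"DM2"`, `"DM3"`, or `"custom"` (requires
#'   `family` and a full `overrides` list).
#' @param overrides named list of parameter overrides.
#' @param family model family, only used with `name = "custom"`.
#' @param n_points sampling density of the returned contour.
#' @return A list of class `geometric_model` with `name`, `family`,
#'   `params` and `contour`.
#' @examples
#' m <- get_model("LM1")
#' m$family
#' @export
get_model <- function(name, overrides = NULL,
                      family = c("cardioid_derived", "modified_ellipse"),
                      n_points = 360L) {
  reg <- model_registry()
  if (identical(name, "custom")) {
    family <- match.arg(family)
    params <- overrides
    if (is.null(params)) stop("custom models require a full `overrides` list")
  } else {
    if (!name %in% names(reg))
      stop("unknown model '", name, "'; registry: ",
           paste(names(reg), collapse = ", "), ", custom")
    family <- reg[[name]]$family
    params <- utils::modifyList(reg[[name]]$params, as.list(overrides))
  }
  cont <- if (family == "cardioid_derived") {
    cardioid_contour(a = params$a, k = params$k, n_points = n_points,
                     id = name, view = "lateral")
  } else {
    modified_ellipse_contour(a = params$a, b = params$b, m = params$m,
                             n_points = n_points, id = name, view = "dorsal")
  }
  structure(list(name = name, family = family, params = params,
                 contour = cont),
            class = "geometric_model")
}

#' @export
print.geometric_model <- function(x, ...) {
  cat(sprintf("<geometric_model> %s (%s): %s\n", x$name, x$family,
              paste(names(x$params), unlist(x$params),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

# Simplicity test: O(n^2) segment-pair intersection scan over non-adjacent
# edges. Used for model validation at moderate n.
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  p1 <- pts
  p2 <- pts[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    j <- j[!(i == 1L & j == n)]
    if (length(j) == 0L) next
    if (any(segments_intersect(p1[i, ], p2[i, ],
                               p1[j, , drop = FALSE], p2[j, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- orient2d(b1, b2, matrix(a1, nrow(b1), 2L, byrow = TRUE))
  d2 <- orient2d(b1, b2, matrix(a2, nrow(b1), 2L, byrow = TRUE))
  a1m <- matrix(a1, nrow(b1), 2L, byrow = TRUE)
  a2m <- matrix(a2, nrow(b1), 2L, byrow = TRUE)
  d3 <- orient2d(a1m, a2m, b1)
  d4 <- orient2d(a1m, a2m, b2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

orient2d <- function(a, b, c) {
  if (is.null(dim(a))) a <- matrix(a, 1L, 2L)
  if (is.null(dim(b))) b <- matrix(b, 1L, 2L)
  if (is.null(dim(c))) c <- matrix(c, 1L, 2L)
  (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
    (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
}
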