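# shared shape builders and independent oracles (test-side implementations,
# deliberately separate from the package's code paths)

circle_contour <- function(r = 1, n = 1024, center = c(0, 0), id = "circle") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)), id = id)
}

ellipse_contour <- function(a = 2, b = 1, n = 1024, angle = 0, id = "ellipse") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- cbind(a * cos(th), b * sin(th))
  if (angle != 0) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
    p <- p %*% t(R)
  }
  contour(p, id = id)
}

square_contour <- function(side = 1, per_side = 100, origin = c(0, 0), id = "square") {
  s <- seq(0, side, length.out = per_side + 1)[-(per_side + 1)]
  p <- rbind(cbind(s, 0), cbind(side, s), cbind(side - s, side), cbind(0, side - s))
  contour(sweep(p, 2, origin, "+"), id = id)
}

star_contour <- function(outer = 1, inner = 0.4, points = 5, id = "star") {
  th <- seq(0, 2 * pi, length.out = 2 * points + 1)[-(2 * points + 1)]
  r <- rep(c(outer, inner), points)
  contour(cbind(r * cos(th), r * sin(th)), id = id)
}

random_blob <- function(n = 300, id = "blob") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1
  for (k in 2:5) r <- r + runif(1, 0, 0.3 / k) * cos(k * th + runif(1, 0, 2 * pi))
  contour(cbind(r * cos(th), r * sin(th)), id = id)
}

rigid_transform <- function(pts, angle, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(pts %*% t(R) * scale, 2, shift, "+")
}

# independent convex hull area: Andrew's monotone chain (not grDevices::chull)
hull_area_oracle <- function(pts) {
  p <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(p) {
    h <- list()
    for (i in seq_len(nrow(p))) {
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p[i, ]) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- p[i, ]
    }
    h
  }
  lower <- build(p)
  upper <- build(p[nrow(p):1, , drop = FALSE])
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  x <- hull[, 1]; y <- hull[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# independent EFD oracle: dense arc-length resampling + trapezoid quadrature
# of the defining Fourier integrals
efd_quadrature_oracle <- function(c, n_harmonics, n_steps = 1e5) {
  pts <- rbind(c$points, c$points[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg)); Tt <- s[length(s)]
  ss <- seq(0, Tt, length.out = n_steps + 1)
  x <- approx(s, pts[, 1], xout = ss)$y
  y <- approx(s, pts[, 2], xout = ss)$y
  trap <- function(f) sum((f[-1] + f[-length(f)]) / 2 * diff(ss))
  t(vapply(seq_len(n_harmonics), function(n) {
    w <- 2 * pi * n * ss / Tt
    c(A = 2 / Tt * trap(x * cos(w)), B = 2 / Tt * trap(x * sin(w)),
      C = 2 / Tt * trap(y * cos(w)), D = 2 / Tt * trap(y * sin(w)))
  }, numeric(4)))
}

# raster oracle for area moments: fill the polygon on a fine grid and sum
moments_raster_oracle <- function(c, res = 1024) {
  pts <- c$points
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  span <- max(hi - lo)
  sc <- (res - 4) / span
  p <- sweep(sweep(pts, 2, lo), 2, c(sc, sc), "*") + 2.5
  m <- seedshape:::cpp_fill_polygon(p[, 1], p[, 2], res, res)
  idx <- which(m, arr.ind = TRUE)
  xs <- (idx[, 2] - 2.5) / sc + lo[1]
  ys <- (idx[, 1] - 2.5) / sc + lo[2]
  px <- 1 / sc^2
  list(m00 = length(xs) * px,
       cx = mean(xs), cy = mean(ys),
       cxx = mean((xs - mean(xs))^2), cyy = mean((ys - mean(ys))^2),
       cxy = mean((xs - mean(xs)) * (ys - mean(ys))))
}

# rasterize a contour into a binary matrix image (white on black, y-up rows
# flipped to image convention)
rasterize_contour <- function(c, size = 256) {
  pts <- sweep(c$points, 2, contour_centroid(c))
  half <- size / 2
  pts <- pts * (0.9 * half / max(abs(pts)))  # fill the canvas
  pts <- sweep(pts, 2, c(half + 0.5, half + 0.5), "+")
  m <- seedshape:::cpp_fill_polygon(pts[, 1], pts[, 2], size, size)
  m[size:1, , drop = FALSE] * 1
}
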