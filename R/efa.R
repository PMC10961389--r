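#' Elliptic Fourier descriptors of a closed contour
#'
#' Computes the Kuhl-Giardina closed-form elliptic Fourier coefficients of
#' the piecewise-linear arc-length parameterization of a polygon. For each
#' harmonic `n` the quadruple `(A_n, B_n, C_n, D_n)` describes
#' `x(t) = a0 + sum A_n cos(2 pi n t / T) + B_n sin(...)` and
#' `y(t) = c0 + sum C_n cos(...) + D_n sin(...)`.
#'
#' @param c a [contour()] (counterclockwise; enforced by the constructor).
#' @param n_harmonics number of harmonics to extract. At least 3 vertices
#'   per harmonic are recommended; fewer triggers a warning.
#' @return An object of class `efd_set`: list with `coefficients`
#'   (`n_harmonics` x 4 matrix, columns `A`, `B`, `C`, `D`), `offset`
#'   (`a0`, `c0`), `n_harmonics`, `normalized` (flag), `size` (semi-major
#'   length of the first-harmonic ellipse before any size removal) and
#'   `contour_id`.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 513)[-513]
#' ell <- contour(cbind(2 * cos(t), sin(t)))
#' round(efd_from_contour(ell, 2)$coefficients, 4)
#' @export
efd_from_contour <- function(c, n_harmonics = 10L) {
  stopifnot(is_contour(c))
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("`n_harmonics` must be >= 1")
  pts <- c$points
  if (nrow(pts) < 3L * n_harmonics)
    warning("contour has fewer than 3 vertices per harmonic; ",
            "consider resampling more densely")
  d <- diff(rbind(pts, pts[1L, , drop = FALSE]))
  dt <- sqrt(rowSums(d^2))
  ok <- dt > 0
  d <- d[ok, , drop = FALSE]; dt <- dt[ok]
  tt <- c(0, cumsum(dt))
  Tt <- tt[length(tt)]
  t0 <- tt[-length(tt)]; t1 <- tt[-1L]
  n <- seq_len(n_harmonics)
  # phase matrices: rows = harmonics, cols = segments
  w <- 2 * pi / Tt
  cos1 <- cos(outer(n, t1, function(nn, t) nn * w * t))
  cos0 <- cos(outer(n, t0, function(nn, t) nn * w * t))
  sin1 <- sin(outer(n, t1, function(nn, t) nn * w * t))
  sin0 <- sin(outer(n, t0, function(nn, t) nn * w * t))
  const <- Tt / (2 * pi^2 * n^2)
  dxdt <- d[, 1L] / dt
  dydt <- d[, 2L] / dt
  A <- const * as.vector((cos1 - cos0) %*% dxdt)
  B <- const * as.vector((sin1 - sin0) %*% dxdt)
  C <- const * as.vector((cos1 - cos0) %*% dydt)
  D <- const * as.vector((sin1 - sin0) %*% dydt)
  # DC offsets
  xi <- cumsum(d[, 1L]) - d[, 1L] / dt * t1
  delta <- cumsum(d[, 2L]) - d[, 2L] / dt * t1
  a0 <- unname(pts[1L, 1L]) +
    sum(d[, 1L] / (2 * dt) * (t1^2 - t0^2) + xi * dt) / Tt
  c0 <- unname(pts[1L, 2L]) +
    sum(d[, 2L] / (2 * dt) * (t1^2 - t0^2) + delta * dt) / Tt
  coeff <- cbind(A = A, B = B, C = C, D = D)
  structure(list(coefficients = coeff, offset = c(a0 = a0, c0 = c0),
                 n_harmonics = n_harmonics, normalized = "none",
                 size = sqrt(A[1L]^2 + C[1L]^2 + B[1L]^2 + D[1L]^2),
                 contour_id = c$id),
            class = "efd_set")
}

#' Construct an EFD set directly from coefficients
#'
#' Mostly useful for tests and worked examples; [efd_from_contour()] is the
#' usual entry point.
#'
#' @param coefficients n x 4 matrix with columns `A`, `B`, `C`, `D`.
#' @param offset centroid terms `(a0, c0)`.
#' @param normalized normalization tag (`"none"` or `"full"`).
#' @param contour_id label.
#' @return An `efd_set`.
#' @export
efd_set <- function(coefficients, offset = c(a0 = 0, c0 = 0),
                    normalized = "none", contour_id = "efd") {
  coefficients <- as.matrix(coefficients)
  if (ncol(coefficients) != 4L) stop("`coefficients` must have 4 columns")
  colnames(coefficients) <- c("A", "B", "C", "D")
  e1 <- coefficients[1L, ]
  structure(list(coefficients = coefficients,
                 offset = offset, n_harmonics = nrow(coefficients),
                 normalized = normalized,
                 size = sqrt(sum(e1^2)),
                 contour_id = contour_id),
            class = "efd_set")
}

#' @export
print.efd_set <- function(x, ...) {
  cat(sprintf("<efd_set> '%s': %d harmonics, normalized = %s\n",
              x$contour_id, x$n_harmonics, x$normalized))
  invisible(x)
}

# rotate harmonic phases: coefficients of t -> t + theta*T/(2*pi)
efd_phase_rotate <- function(coeff, theta) {
  n <- nrow(coeff)
  out <- coeff
  for (i in seq_len(n)) {
    ct <- cos(i * theta); st <- sin(i * theta)
    M <- matrix(coeff[i, ], 2L, 2L, byrow = TRUE)  # [A B; C D]
    M <- M %*% matrix(c(ct, st, -st, ct), 2L, 2L)
    out[i, ] <- c(M[1L, ], M[2L, ])
  }
  out
}

# spatial rotation of the outline by -psi
efd_spatial_rotate <- function(coeff, psi) {
  R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2L, 2L, byrow = TRUE)
  n <- nrow(coeff)
  out <- coeff
  for (i in seq_len(n)) {
    M <- matrix(coeff[i, ], 2L, 2L, byrow = TRUE)
    M <- R %*% M
    out[i, ] <- c(M[1L, ], M[2L, ])
  }
  out
}

#' Normalize elliptic Fourier descriptors
#'
#' Standard first-harmonic normalization: the starting point is rotated to
#' the end of the first-harmonic semi-major axis and the outline is rotated
#' so that axis lies along x; optionally size is removed by dividing all
#' coefficients by the semi-major length. Afterwards `A_1 > 0` and
#' `B_1 = C_1 = 0` (and `A_1 = 1` when size is removed), making the
#' coefficients invariant to rotation, translation, scaling and starting
#' point. The residual 180-degree ambiguity is resolved deterministically
#' by the sign of the first significant higher-harmonic coefficient.
#'
#' @param e an `efd_set`.
#' @param mode `"full"` (default) or `"none"` (identity).
#' @param size_invariant remove size by the first-harmonic semi-major
#'   length (default `TRUE`).
#' @return A normalized `efd_set` (offset terms are zeroed in mode
#'   `"full"`).
#' @export
normalize_efd <- function(e, mode = c("full", "none"), size_invariant = TRUE) {
  stopifnot(inherits(e, "efd_set"))
  mode <- match.arg(mode)
  if (mode == "none") return(e)
  coeff <- e$coefficients
  a1 <- coeff[1L, 1L]; b1 <- coeff[1L, 2L]
  c1 <- coeff[1L, 3L]; d1 <- coeff[1L, 4L]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-300)
    stop("zero first harmonic: cannot normalize")
  theta0 <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                        a1^2 + c1^2 - b1^2 - d1^2)
  # theta is determined up to quarter turns: k = 1, 3 swap the first-harmonic
  # semi-axes, k = 2 restarts half a period later. Keep the major-axis
  # branches, then fix the residual 180-degree ambiguity deterministically.
  cands <- lapply(theta0 + (0:3) * (pi / 2), function(th) {
    cf <- efd_phase_rotate(coeff, th)
    psi <- atan2(cf[1L, 3L], cf[1L, 1L])
    efd_spatial_rotate(cf, psi)
  })
  major <- vapply(cands, function(cf) abs(cf[1L, 1L]), 0)
  keep <- which(major >= max(major) * (1 - 1e-12))
  cands <- cands[keep]
  # lexicographically largest higher-harmonic vector: invariant because the
  # candidate set itself is invariant under similarity transforms
  cf <- cands[[1L]]
  if (e$n_harmonics > 1L && length(cands) > 1L) {
    tol <- 1e-9 * abs(cf[1L, 1L])
    vbest <- as.vector(t(cf[-1L, , drop = FALSE]))
    for (i in 2:length(cands)) {
      v <- as.vector(t(cands[[i]][-1L, , drop = FALSE]))
      k <- which(abs(v - vbest) > tol)
      if (length(k) > 0L && v[k[1L]] > vbest[k[1L]]) {
        cf <- cands[[i]]; vbest <- v
      }
    }
  }
  semi_major <- cf[1L, 1L]
  if (size_invariant) cf <- cf / semi_major
  structure(list(coefficients = cf, offset = c(a0 = 0, c0 = 0),
                 n_harmonics = e$n_harmonics,
                 normalized = if (size_invariant) "full" else "full_sized",
                 size = semi_major, contour_id = e$contour_id),
            class = "efd_set")
}

#' Reconstruct a contour from elliptic Fourier descriptors
#'
#' Evaluates the truncated Fourier series at `n_points` uniform parameter
#' values.
#'
#' @param e an `efd_set`.
#' @param n_points number of output vertices (>= 32).
#' @param n_harmonics optionally reconstruct from the first harmonics only.
#' @return A [contour()].
#' @export
reconstruct_contour <- function(e, n_points = 300L, n_harmonics = NULL) {
  stopifnot(inherits(e, "efd_set"))
  if (n_points < 32L) stop("`n_points` must be at least 32")
  N <- if (is.null(n_harmonics)) e$n_harmonics else min(n_harmonics, e$n_harmonics)
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  co <- e$coefficients
  x <- rep(e$offset[["a0"]], n_points)
  y <- rep(e$offset[["c0"]], n_points)
  for (n in seq_len(N)) {
    cn <- cos(n * t); sn <- sin(n * t)
    x <- x + co[n, 1L] * cn + co[n, 2L] * sn
    y <- y + co[n, 3L] * cn + co[n, 4L] * sn
  }
  contour(cbind(x, y), id = e$contour_id)
}

#' Harmonic power spectrum
#'
#' Power of harmonic `n` is `(A_n^2 + B_n^2 + C_n^2 + D_n^2) / 2`.
#'
#' @param e an `efd_set`.
#' @return Numeric vector of per-harmonic powers.
#' @export
harmonic_power <- function(e) {
  stopifnot(inherits(e, "efd_set"))
  rowSums(e$coefficients^2) / 2
}

#' Select the number of harmonics retaining a power fraction
#'
#' Computes per-contour cumulative harmonic power fractions up to `cap`
#' harmonics and returns the smallest `N` whose mean cumulative fraction
#' across contours exceeds `power_threshold`. One `N` per analysis set, as
#' is usual for the >99\% rule; per-contour maxima would be noise-driven.
#'
#' With `drop_first = TRUE` the first harmonic — the fitting ellipse, which
#' trivially dominates the spectrum of any seed-like outline — is excluded
#' from both numerator and denominator, the convention of standard outline
#' software; the resulting counts are on the scale needed to capture actual
#' shape detail. `drop_first = FALSE` includes harmonic 1, under which any
#' near-elliptic population selects `N = 1`.
#'
#' @param cs list of [contour()] objects.
#' @param power_threshold fraction in (0, 1); default 0.99.
#' @param cap maximum harmonic count considered.
#' @param drop_first exclude harmonic 1 from the power fractions.
#' @return Integer `N`. If the threshold is unreachable at `cap`, returns
#'   `cap` with a warning.
#' @export
select_harmonic_count <- function(cs, power_threshold = 0.99, cap = 64L,
                                  drop_first = FALSE) {
  if (is_contour(cs)) cs <- list(cs)
  if (length(cs) < 1L) stop("at least one contour is required")
  if (!(power_threshold > 0 && power_threshold < 1))
    stop("`power_threshold` must be in (0, 1)")
  cap <- as.integer(cap)
  fracs <- vapply(cs, function(c) {
    if (nrow(c$points) < 3L * cap) c <- resample_contour(c, 3L * cap)
    p <- harmonic_power(efd_from_contour(c, cap))
    if (drop_first) p[1L] <- 0
    cumsum(p) / sum(p)
  }, numeric(cap))
  mean_frac <- rowMeans(matrix(fracs, nrow = cap))
  hit <- which(mean_frac > power_threshold)
  if (drop_first) hit <- hit[hit >= 2L]
  if (length(hit) == 0L) {
    warning("power threshold ", power_threshold,
            " not reached at cap = ", cap, " harmonics")
    return(cap)
  }
  as.integer(hit[1L])
}

#' Bilateral symmetry coefficient from EFDs
#'
#' The AD/amp ratio: sum of the absolute values of the `A` and `D` columns
#' over the sum of the absolute values of all four coefficient columns.
#' For outlines mirror-symmetric about their first-harmonic major axis the
#' `B` and `C` columns vanish after normalization and the coefficient is 1;
#' asymmetry moves power into `B`/`C` and lowers it towards 0. The input
#' must be normalized (mode `"full"`), otherwise an arbitrary rotation
#' would move power between the columns; unnormalized sets are normalized
#' internally. A bilateral symmetry axis can be either of the two
#' first-harmonic axes (for a plain cardioid it is the short one), so the
#' ratio is evaluated with the outline aligned to each axis in turn and the
#' larger value is returned.
#'
#' @param e an `efd_set`.
#' @param group optional group label.
#' @return A one-row data.frame: `contour_id`, `sym` in \[0, 1\], `group`.
#' @export
symmetry_index <- function(e, group = NA_character_) {
  stopifnot(inherits(e, "efd_set"))
  if (!startsWith(e$normalized, "full")) e <- normalize_efd(e)
  ad_amp <- function(cf) {
    co <- abs(cf)
    amp <- sum(co)
    if (amp <= 0) stop("all-zero coefficients: symmetry undefined")
    (sum(co[, 1L]) + sum(co[, 4L])) / amp
  }
  cf <- e$coefficients
  # quarter-turn sibling: outline aligned to the other first-harmonic axis
  cf2 <- efd_phase_rotate(cf, pi / 2)
  cf2 <- efd_spatial_rotate(cf2, atan2(cf2[1L, 3L], cf2[1L, 1L]))
  sym <- max(ad_amp(cf), ad_amp(cf2))
  data.frame(contour_id = e$contour_id, sym = sym, group = group,
             stringsAsFactors = FALSE)
}

#' EFD feature matrix for a set of contours
#'
#' Extracts `N`-harmonic descriptors for each contour (all of the same
#' view) and assembles the specimen-by-coefficient matrix used by the
#' multivariate layer. Columns are laid out in blocks
#' `A_1..A_N, B_1..B_N, C_1..C_N, D_1..D_N`.
#'
#' @param cs list of [contour()] objects, all with the same `view`.
#' @param N harmonic count (e.g. from [select_harmonic_count()]).
#' @param normalize_mode `"full"` (default) or `"none"`.
#' @param groups optional group labels returned alongside.
#' @return A list with `matrix` (rows = contours, in input order), `groups`
#'   and `view`.
#' @export
efd_feature_matrix <- function(cs, N, normalize_mode = c("full", "none"),
                               groups = NULL) {
  if (is_contour(cs)) cs <- list(cs)
  normalize_mode <- match.arg(normalize_mode)
  views <- unique(vapply(cs, function(c) c$view, ""))
  if (length(views) > 1L)
    stop("mixed views in feature matrix: ", paste(views, collapse = ", "))
  if (is.null(groups)) groups <- rep(NA_character_, length(cs))
  rows <- t(vapply(cs, function(c) {
    if (nrow(c$points) < 3L * N) c <- resample_contour(c, max(3L * N, 64L))
    e <- efd_from_contour(c, N)
    if (normalize_mode == "full") e <- normalize_efd(e)
    as.vector(e$coefficients)   # column-major: A block, B block, C block, D
  }, numeric(4L * N)))
  colnames(rows) <- c(paste0("A", 1:N), paste0("B", 1:N),
                      paste0("C", 1:N), paste0("D", 1:N))
  rownames(rows) <- vapply(cs, function(c) c$id, "")
  list(matrix = rows, groups = groups, view = views)
}

#' Per-group min-max rescaling of an index distribution
#'
#' Affinely rescales values within each group onto `[lo, hi]`; used to
#' overlay symmetry-index distributions of different genotypes on a common
#' (-1.5, 1.5) axis for density plots.
#'
#' @param values numeric vector.
#' @param groups group label per value (a single group if omitted).
#' @param lo,hi target range.
#' @return Numeric vector of rescaled values in input order.
#' @export
normalize_index_distribution <- function(values, groups = NULL,
                                         lo = -1.5, hi = 1.5) {
  if (is.null(groups)) groups <- rep("all", length(values))
  groups <- as.character(groups)
  out <- numeric(length(values))
  for (g in unique(groups)) {
    idx <- groups == g
    rng <- range(values[idx])
    if (diff(rng) <= 0)
      stop("constant values in group '", g, "': cannot rescale")
    out[idx] <- lo + (values[idx] - rng[1L]) / diff(rng) * (hi - lo)
  }
  out
}
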