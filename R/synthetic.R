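#' Specification of a synthetic outline population
#'
#' Describes one genotype-like group of synthetic seed (or seed-coat cell)
#' outlines: base geometric model, size scale, elongation, lobe structure,
#' asymmetry regime and roughness. Identical spec + seed always generates
#' the identical population (Mersenne-Twister RNG).
#'
#' @param group group label.
#' @param n number of specimens (>= 1).
#' @param base_shape registry model name ([get_model()]) for seeds, or
#'   `"cell"` for lobed cell outlines.
#' @param size_scale mean centroid size in pixels.
#' @param size_cv coefficient of variation of the lognormal size draw.
#' @param elongation mean multiplier applied along the symmetry axis.
#' @param elongation_cv CV of the (truncated at 3 SD) normal elongation
#'   draw.
#' @param lobe_count,lobe_amplitude sinusoidal lobe structure for cell
#'   outlines (`lobe_count >= 3`, `lobe_amplitude < 0.5`).
#' @param asymmetry_regime `"none"`, `"directional"`, `"anti"` or
#'   `"fluctuating"`.
#' @param asymmetry_delta magnitude `delta >= 0` of the lateral skew;
#'   signed per specimen by the regime (directional: always `+delta`
#'   -- use a negative `asymmetry_delta` for left-directional; anti:
#'   `+delta` or `-delta` with equal probability; fluctuating:
#'   `N(0, |delta|/3)`).
#' @param noise_sd relative amplitude of smooth radial roughness.
#' @param view view label for the generated contours.
#' @param seed RNG seed of the population.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(group, n, base_shape = "LM1",
                            size_scale = 120, size_cv = 0.08,
                            elongation = 1, elongation_cv = 0.03,
                            lobe_count = 12L, lobe_amplitude = 0,
                            asymmetry_regime = c("none", "directional",
                                                 "anti", "fluctuating"),
                            asymmetry_delta = 0, noise_sd = 0.01,
                            view = "lateral", seed = 1L) {
  asymmetry_regime <- match.arg(asymmetry_regime)
  if (n < 1L) stop("`n` must be >= 1")
  if (size_cv < 0 || elongation_cv < 0) stop("CVs must be >= 0")
  if (lobe_amplitude >= 0.5) stop("`lobe_amplitude` must be < 0.5")
  if (lobe_count < 3L) stop("`lobe_count` must be >= 3")
  structure(list(group = group, n = as.integer(n), base_shape = base_shape,
                 size_scale = size_scale, size_cv = size_cv,
                 elongation = elongation, elongation_cv = elongation_cv,
                 lobe_count = as.integer(lobe_count),
                 lobe_amplitude = lobe_amplitude,
                 asymmetry_regime = asymmetry_regime,
                 asymmetry_delta = asymmetry_delta,
                 noise_sd = noise_sd, view = view, seed = as.integer(seed)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(paste0("<population_spec> '%s': n = %d, base = %s, size = %g ",
                     "(CV %g), elongation = %g, asymmetry = %s (%g), ",
                     "noise = %g, seed = %d\n"),
              x$group, x$n, x$base_shape, x$size_scale, x$size_cv,
              x$elongation, x$asymmetry_regime, x$asymmetry_delta,
              x$noise_sd, x$seed))
  invisible(x)
}

# draw the signed skew amplitude for one specimen
draw_signed_delta <- function(regime, delta) {
  switch(regime,
         none = 0,
         directional = delta,
         anti = sample(c(-1, 1), 1L) * abs(delta),
         fluctuating = stats::rnorm(1L, 0, abs(delta) / 3))
}

# truncated normal multiplier (mean 1 * m, truncation at +/- 3 SD)
draw_truncnorm <- function(mean, cv) {
  if (cv <= 0) return(mean)
  sd <- mean * cv
  repeat {
    v <- stats::rnorm(1L, mean, sd)
    if (abs(v - mean) <= 3 * sd && v > 0) return(v)
  }
}

# Deform a unit-size contour (axis vertical, centroid at origin):
# elongation stretch along y, quadratic lateral skew of signed amplitude
# delta, smooth radial roughness.
deform_outline <- function(pts, elong, delta, noise_sd) {
  pts[, 2L] <- pts[, 2L] * elong
  size <- sqrt(mean(rowSums(pts^2)))
  pts <- pts / size
  if (delta != 0) {
    h <- max(abs(pts[, 2L]))
    pts[, 1L] <- pts[, 1L] + delta * (pts[, 2L] / h)^2
  }
  if (noise_sd > 0) {
    th <- atan2(pts[, 2L], pts[, 1L])
    # roughness spans low undulations through tubercle-scale bumps; seed
    # coats are not convex, so the spectrum must reach high enough
    # frequencies to put genuine variation into solidity
    harm <- 2:16
    amp <- stats::rnorm(length(harm), 0, noise_sd / sqrt(length(harm)))
    phs <- stats::runif(length(harm), 0, 2 * pi)
    f <- 1 + as.vector(cos(outer(th, harm) +
                           matrix(phs, nrow(pts), length(harm), byrow = TRUE)) %*% amp)
    pts <- pts * f
  }
  pts
}

#' Generate one synthetic seed outline
#'
#' Takes the spec's base model contour in canonical pose (symmetry axis
#' vertical), applies a lognormal size draw, an elongation draw, the
#' regime-signed lateral skew (a quadratic shear along the axis, which is
#' what loads the B/C columns of the EFDs that the symmetry coefficient
#' measures), smooth radial roughness and a small placement tilt, then
#' resamples the result.
#'
#' The caller controls the RNG state (`set.seed`); [generate_population()]
#' seeds it from the spec.
#'
#' @param spec a [population_spec()].
#' @param id contour id.
#' @param n_points output sampling density.
#' @return A list: `contour` and `truth` (one-row data.frame with `group`,
#'   `size`, `area`, `elongation`, `signed_asymmetry`).
#' @export
generate_seed_outline <- function(spec, id = spec$group, n_points = 300L) {
  stopifnot(inherits(spec, "population_spec"))
  base <- if (identical(spec$base_shape, "cell")) {
    stop("use generate_cell_outline() for cell populations")
  } else {
    get_model(spec$base_shape, n_points = 360L)$contour
  }
  pts0 <- sweep(base$points, 2L, contour_centroid(base))
  pts0 <- pts0 / sqrt(mean(rowSums(pts0^2)))
  for (try in 1:50) {
    size <- spec$size_scale *
      stats::rlnorm(1L, -0.5 * log(1 + spec$size_cv^2),
                    sqrt(log(1 + spec$size_cv^2)))
    elong <- draw_truncnorm(spec$elongation, spec$elongation_cv)
    delta <- draw_signed_delta(spec$asymmetry_regime, spec$asymmetry_delta)
    pts <- deform_outline(pts0, elong, delta, spec$noise_sd)
    tilt <- stats::rnorm(1L, 0, 2 * pi / 180)
    pts <- rotate_points(pts, tilt) * size
    cc <- tryCatch(contour(pts, id = id, view = spec$view),
                   error = function(e) NULL)
    if (!is.null(cc) && is_simple_polygon(cc$points)) {
      cc <- resample_contour(cc, n_points)
      truth <- data.frame(contour_id = id, group = spec$group,
                          size = size, area = polygon_area(cc),
                          elongation = elong, signed_asymmetry = delta,
                          stringsAsFactors = FALSE)
      return(list(contour = cc, truth = truth))
    }
  }
  stop("could not generate a simple outline in 50 tries; ",
       "check spec parameters for group '", spec$group, "'")
}

#' Generate one synthetic seed-coat cell outline
#'
#' Ellipse perturbed by sinusoidal lobes
#' `r -> r * (1 + amplitude * sin(count * t + phase))` plus roughness;
#' higher lobe amplitude yields lower solidity, emulating rugose to
#' papillose seed-coat cell sculpture.
#'
#' @inheritParams generate_seed_outline
#' @return As [generate_seed_outline()]; truth stores the lobe amplitude
#'   as `signed_asymmetry = 0` and an extra `lobe_amplitude` column.
#' @export
generate_cell_outline <- function(spec, id = spec$group, n_points = 300L) {
  stopifnot(inherits(spec, "population_spec"))
  for (try in 1:50) {
    size <- spec$size_scale *
      stats::rlnorm(1L, -0.5 * log(1 + spec$size_cv^2),
                    sqrt(log(1 + spec$size_cv^2)))
    elong <- draw_truncnorm(spec$elongation, spec$elongation_cv)
    t <- seq(0, 2 * pi, length.out = 4L * n_points + 1L)[-(4L * n_points + 1L)]
    phase <- stats::runif(1L, 0, 2 * pi)
    f <- 1 + spec$lobe_amplitude * sin(spec$lobe_count * t + phase)
    pts <- cbind(cos(t) * f, elong * sin(t) * f)
    pts <- deform_outline(pts, 1, 0, spec$noise_sd)
    pts <- rotate_points(pts, stats::runif(1L, 0, 2 * pi)) * size
    cc <- tryCatch(contour(pts, id = id, view = "cell"),
                   error = function(e) NULL)
    if (!is.null(cc) && is_simple_polygon(cc$points)) {
      cc <- resample_contour(cc, n_points)
      truth <- data.frame(contour_id = id, group = spec$group,
                          size = size, area = polygon_area(cc),
                          elongation = elong, signed_asymmetry = 0,
                          lobe_amplitude = spec$lobe_amplitude,
                          stringsAsFactors = FALSE)
      return(list(contour = cc, truth = truth))
    }
  }
  stop("could not generate a simple cell outline in 50 tries")
}

#' Generate populations of outlines (and optionally raster images)
#'
#' Generates every specimen of each [population_spec()], deterministic
#' given the per-spec seeds. If `out_dir` is given, each outline is filled
#' into an 8-bit PNG (white silhouette on black) and a truth CSV is
#' written.
#'
#' @param specs a [population_spec()] or list of them.
#' @param out_dir optional output directory for images + `truth.csv`.
#' @param raster_size image side in pixels.
#' @param n_points outline sampling density.
#' @return A list with `contours` (flat list) and `truth` (data.frame; one
#'   row per specimen, with `file` if images were written).
#' @export
generate_population <- function(specs, out_dir = NULL, raster_size = 512L,
                                n_points = 300L) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  contours <- list()
  truth <- list()
  for (spec in specs) {
    set.seed(spec$seed, kind = "Mersenne-Twister")
    is_cell <- identical(spec$base_shape, "cell")
    for (i in seq_len(spec$n)) {
      id <- sprintf("%s_%03d", spec$group, i)
      g <- if (is_cell) generate_cell_outline(spec, id, n_points)
           else generate_seed_outline(spec, id, n_points)
      row <- g$truth
      if (!is.null(out_dir)) {
        # store the path relative to out_dir so truth tables are
        # byte-reproducible across runs and machines
        file <- paste0(id, ".png")
        write_outline_image(g$contour, file.path(out_dir, file), raster_size)
        row$file <- file
      }
      contours[[length(contours) + 1L]] <- g$contour
      truth[[length(truth) + 1L]] <- row
    }
  }
  truth <- do.call(rbind, lapply(truth, function(r) {
    # pad cell rows so seed and cell specs can mix
    if (!"lobe_amplitude" %in% names(r)) r$lobe_amplitude <- NA_real_
    r
  }))
  if (!is.null(out_dir)) {
    tf <- file.path(out_dir, "truth.csv")
    utils::write.csv(format(truth, digits = 15, trim = TRUE), tf,
                     row.names = FALSE, quote = TRUE)
  }
  list(contours = contours, truth = truth)
}

# rasterize an outline centred on a raster_size^2 8-bit PNG
write_outline_image <- function(c, path, raster_size = 512L) {
  pts <- sweep(c$points, 2L, contour_centroid(c))
  half <- raster_size / 2
  ext <- max(abs(pts))
  if (ext > 0.94 * half)
    stop("outline '", c$id, "' (extent ", round(2 * ext), " px) exceeds the ",
         raster_size, " px canvas; increase raster_size or reduce size_scale")
  pts <- sweep(pts, 2L, c(half + 0.5, half + 0.5), "+")
  mask <- cpp_fill_polygon(pts[, 1L], pts[, 2L], raster_size, raster_size)
  # mask rows follow y (1 = bottom); PNG rows run top to bottom
  img <- mask[raster_size:1L, , drop = FALSE] * 1
  png::writePNG(img, path)
  invisible(path)
}

#' Measured signed asymmetry of an outline
#'
#' Standardized third central moment of the filled outline across its
#' principal axis, after rotating the major axis to x and resolving the
#' 180-degree ambiguity by the sign of the along-axis skewness (the
#' cusp/point of seed outlines makes this robust; for outlines with two
#' identical ends the sign is not identifiable). Positive values mean the
#' outline bulges toward the regime's "+" side.
#'
#' @param c a [contour()].
#' @return Scalar signed asymmetry (dimensionless).
#' @export
signed_asymmetry <- function(c) {
  pts <- sweep(as_points(c), 2L, contour_centroid(c))
  ang <- fit_ellipse_moments(contour(pts))$angle
  pts <- rotate_points(pts, -ang)
  mu <- polygon_moments(pts)
  if (mu[4L, 1L] < 0) {  # flip so along-axis skewness is positive
    pts <- -pts
    mu <- polygon_moments(pts)
  }
  m00 <- mu[1L, 1L]
  sig_y <- sqrt(mu[1L, 3L] / m00)
  # sign: positive = bulge toward the "+delta" side of the generator's skew
  -mu[1L, 4L] / (m00 * sig_y^3)
}

#' Scenario presets mirroring the study designs
#'
#' Returns the population specs of four canned scenarios:
#' \describe{
#'   \item{`ploidy`}{two groups with identical shape parameters and size
#'     scale x1 vs x1.3 (diploid vs tetraploid): size differs, shape does
#'     not.}
#'   \item{`sex_symmetry`}{male-like directional-left, tetraploid-like
#'     directional-right and female-like antisymmetric groups on the
#'     cardioid base (the cusp makes the asymmetry sign identifiable).}
#'   \item{`hybrid_maternal`}{four reciprocal-cross groups whose
#'     elongation follows the maternal label (maternal latifolia-like
#'     crosses are more elongated, maternal dioica-like rounder and the
#'     latifolia-mother crosses smaller).}
#'   \item{`cells`}{two seed-coat cell groups differing in lobe
#'     amplitude (smooth vs rugose), hence in solidity.}
#' }
#' Default group sizes mirror the study's populations; pass `n_per_group`
#' to override (e.g. for quick runs).
#'
#' @param name scenario name.
#' @param seed base RNG seed; per-group seeds are derived from it.
#' @param n_per_group optional common group size override.
#' @return A list of [population_spec()] objects.
#' @export
scenario_presets <- function(name = c("ploidy", "sex_symmetry",
                                      "hybrid_maternal", "cells"),
                             seed = 1L, n_per_group = NULL) {
  name <- match.arg(name)
  seed <- as.integer(seed) %% 100000L
  sd_i <- function(i) seed * 13L + i
  nn <- function(default) if (is.null(n_per_group)) default else n_per_group
  specs <- switch(name,
    ploidy = list(
      population_spec("Sl2x", nn(100L), base_shape = "DM2", size_scale = 90,
                      size_cv = 0.08, asymmetry_regime = "fluctuating",
                      asymmetry_delta = 0.05, noise_sd = 0.01,
                      view = "dorsal", seed = sd_i(1L)),
      population_spec("Sl4x", nn(80L), base_shape = "DM2",
                      size_scale = 90 * 1.3,
                      size_cv = 0.08, asymmetry_regime = "fluctuating",
                      asymmetry_delta = 0.05, noise_sd = 0.01,
                      view = "dorsal", seed = sd_i(2L))
    ),
    sex_symmetry = list(
      population_spec("male", nn(31L), base_shape = "LM1",
                      asymmetry_regime = "directional",
                      asymmetry_delta = -0.12, seed = sd_i(1L)),
      population_spec("tetraploid", nn(80L), base_shape = "LM1",
                      asymmetry_regime = "directional",
                      asymmetry_delta = 0.12, seed = sd_i(2L)),
      population_spec("female", nn(34L), base_shape = "LM1",
                      asymmetry_regime = "anti",
                      asymmetry_delta = 0.12, seed = sd_i(3L))
    ),
    hybrid_maternal = list(
      population_spec("SlF_SdM_1", nn(16L), base_shape = "LM1",
                      size_scale = 102, elongation = 1.25,
                      asymmetry_regime = "fluctuating",
                      asymmetry_delta = 0.05, seed = sd_i(1L)),
      population_spec("SlF_SdM_2", nn(16L), base_shape = "LM1",
                      size_scale = 102, elongation = 1.25,
                      asymmetry_regime = "fluctuating",
                      asymmetry_delta = 0.05, seed = sd_i(2L)),
      population_spec("SdF_SlM_1", nn(18L), base_shape = "LM1",
                      size_scale = 120, elongation = 1.0,
                      asymmetry_regime = "fluctuating",
                      asymmetry_delta = 0.05, seed = sd_i(3L)),
      population_spec("SdF_SlM_2", nn(20L), base_shape = "LM1",
                      size_scale = 120, elongation = 1.0,
                      asymmetry_regime = "fluctuating",
                      asymmetry_delta = 0.05, seed = sd_i(4L))
    ),
    cells = list(
      population_spec("smooth", nn(40L), base_shape = "cell",
                      size_scale = 60, elongation = 1.3,
                      lobe_count = 12L, lobe_amplitude = 0.05,
                      noise_sd = 0.01, view = "cell", seed = sd_i(1L)),
      population_spec("rugose", nn(40L), base_shape = "cell",
                      size_scale = 60, elongation = 1.3,
                      lobe_count = 12L, lobe_amplitude = 0.22,
                      noise_sd = 0.01, view = "cell", seed = sd_i(2L))
    )
  )
  specs
}
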