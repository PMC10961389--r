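#' Align a seed contour to a geometric model
#'
#' Similarity alignment: the seed is translated to the model centroid,
#' uniformly scaled to equal area and rotated so the principal (moment)
#' axes coincide. The principal axis leaves a four-fold ambiguity (180
#' degree rotation x mirror); all four branches are evaluated and the one
#' maximizing the J index is returned.
#'
#' @param seed,model [contour()] objects (both simple and closed).
#' @param method,raster_resolution passed to [j_index()] for branch scoring.
#' @return A list with `contour` (the aligned seed), `branch` (one of
#'   `"principal"`, `"flipped"`, `"mirror"`, `"mirror_flipped"`) and `J`
#'   (the J index of the winning branch).
#' @export
align_to_model <- function(seed, model, method = c("polygon", "raster"),
                           raster_resolution = 1024L) {
  stopifnot(is_contour(seed), is_contour(model))
  method <- match.arg(method)
  m_ctr <- contour_centroid(model)
  m_area <- polygon_area(model)
  m_ang <- fit_ellipse_moments(model)$angle
  s_pts <- sweep(seed$points, 2L, contour_centroid(seed))
  s_pts <- s_pts * sqrt(m_area / polygon_area(seed))
  s_ang <- fit_ellipse_moments(contour(s_pts, id = seed$id))$angle
  branches <- list(
    principal      = c(mirror = FALSE, extra = 0),
    flipped        = c(mirror = FALSE, extra = pi),
    mirror         = c(mirror = TRUE,  extra = 0),
    mirror_flipped = c(mirror = TRUE,  extra = pi)
  )
  best <- NULL
  for (nm in names(branches)) {
    b <- branches[[nm]]
    pts <- s_pts
    ang <- s_ang
    if (b[["mirror"]]) {
      pts <- cbind(pts[, 1L], -pts[, 2L])  # reflect across x axis
      ang <- -ang
    }
    pts <- rotate_points(pts, m_ang - ang + b[["extra"]])
    pts <- sweep(pts, 2L, m_ctr, "+")
    cand <- contour(pts, id = seed$id, view = seed$view, border = seed$border)
    jj <- j_index(cand, model, method = method,
                  raster_resolution = raster_resolution, align = FALSE)$J
    if (is.null(best) || jj > best$J)
      best <- list(contour = cand, branch = nm, J = jj)
  }
  best
}

#' J index: percentage similarity to a geometric model
#'
#' The J index is the percentage of shared area between a seed silhouette
#' and a geometric model after superposition: `J = 100 * area(intersection)
#' / area(total)`. By default "total" is the area of the union, which makes
#' J symmetric in its arguments and bounded by 100; `denominator = "model"`
#' is available for the alternative reading.
#'
#' @param seed,model [contour()] objects.
#' @param method `"polygon"` for exact polygon clipping (default) or
#'   `"raster"` for pixel counting at `raster_resolution^2`. If polygon
#'   clipping fails on near-degenerate geometry the raster method is used
#'   with a warning.
#' @param raster_resolution grid side used by the raster method.
#' @param align if `TRUE` (default), [align_to_model()] is applied first.
#' @param denominator `"union"` (default) or `"model"`.
#' @return A one-row data.frame of class `j_result`: `contour_id`,
#'   `model_name`, `J`, `alignment`, `method`.
#' @examples
#' m <- get_model("LM1")$contour
#' j_index(m, m, align = FALSE)$J
#' @export
j_index <- function(seed, model, method = c("polygon", "raster"),
                    raster_resolution = 1024L, align = TRUE,
                    denominator = c("union", "model")) {
  stopifnot(is_contour(seed), is_contour(model))
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  branch <- "none"
  if (align) {
    al <- align_to_model(seed, model, method = method,
                         raster_resolution = raster_resolution)
    seed <- al$contour
    branch <- al$branch
  }
  areas <- tryCatch(
    overlap_areas(seed, model, method, raster_resolution),
    error = function(e) {
      if (method == "polygon") {
        warning("polygon clipping failed (", conditionMessage(e),
                "); falling back to raster method")
        overlap_areas(seed, model, "raster", raster_resolution)
      } else stop(e)
    }
  )
  inter <- areas$inter
  denom <- if (denominator == "union") {
    areas$a_seed + areas$a_model - inter
  } else {
    areas$a_model
  }
  J <- 100 * inter / denom
  structure(data.frame(contour_id = seed$id, model_name = model$id,
                       J = min(max(J, 0), 100),
                       alignment = branch, method = method,
                       stringsAsFactors = FALSE),
            class = c("j_result", "data.frame"))
}

overlap_areas <- function(seed, model, method, raster_resolution) {
  if (method == "polygon") {
    inter <- cpp_intersection_area(seed$points, model$points)
    list(inter = max(inter, 0),
         a_seed = polygon_area(seed), a_model = polygon_area(model))
  } else {
    res <- as.integer(raster_resolution)
    allp <- rbind(seed$points, model$points)
    lo <- apply(allp, 2L, min)
    hi <- apply(allp, 2L, max)
    span <- max(hi - lo)
    scale <- (res - 4L) / span
    tr <- function(p) sweep(sweep(p, 2L, lo), 2L, c(scale, scale), "*") + 2.5
    ms <- cpp_fill_polygon(tr(seed$points)[, 1L], tr(seed$points)[, 2L], res, res)
    mm <- cpp_fill_polygon(tr(model$points)[, 1L], tr(model$points)[, 2L], res, res)
    px <- 1 / scale^2
    list(inter = sum(ms & mm) * px,
         a_seed = sum(ms) * px, a_model = sum(mm) * px)
  }
}

#' J index of many outlines against registry models
#'
#' Convenience wrapper: computes the J index of each contour against each
#' named model (or each model assigned to the contour's view).
#'
#' @param cs list of [contour()] objects.
#' @param models character vector of registry model names, or a named list
#'   mapping views to model-name vectors (e.g.
#'   `list(lateral = c("LM1", "LM2"), dorsal = c("DM2", "DM3"))`).
#' @param ... passed to [j_index()].
#' @return A data.frame with one row per contour x model.
#' @export
j_index_table <- function(cs, models, ...) {
  if (is_contour(cs)) cs <- list(cs)
  rows <- list()
  for (c in cs) {
    mnames <- if (is.list(models)) models[[c$view]] else models
    for (mn in mnames) {
      mod <- get_model(mn)$contour
      rows[[length(rows) + 1L]] <- as.data.frame(j_index(c, mod, ...))
    }
  }
  do.call(rbind, rows)
}
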