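#' Read a silhouette image as a grayscale intensity matrix
#'
#' Reads an 8-bit PNG or TIFF image and returns a single-channel matrix with
#' intensities in \[0, 1\] (multi-channel images are averaged).
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix, rows = image rows (top to bottom).
#' @export
read_silhouette <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: '", ext, "' (use PNG or TIFF)")
  }
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  img
}

# Otsu threshold on intensities in [0, 1].
otsu_threshold <- function(img, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(img * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / n_bins
}

#' Extract closed outlines from a binary silhouette image
#'
#' Thresholds a single-channel image, labels 8-connected foreground
#' components and traces the outer boundary of each as a closed polygon.
#' Boundaries follow the 0.5 isoline of the binary mask (marching squares),
#' so the polygon area matches the component pixel count closely. The pixel
#' staircase is then removed by a corner-cutting pass plus Fourier low-pass
#' smoothing (truncation at `smooth_harmonics`); because the truncation
#' error depends only on the shape (not on its size in pixels), descriptors
#' of objects rasterized at different scales stay comparable. Coordinates
#' are y-up (row 1 of the image is the top), so downstream geometry and
#' images share orientation; all contours are counterclockwise. Interior
#' holes are ignored: only silhouettes are analyzed.
#'
#' @param image numeric matrix of intensities in \[0, 1\] (see
#'   [read_silhouette()]), or a logical mask.
#' @param polarity `"white_on_black"` (default) if the foreground is bright,
#'   `"black_on_white"` if dark.
#' @param threshold binarization threshold; the default 0.5 is the midpoint
#'   of the intensity range (inputs are expected to be binary already).
#'   Use `"otsu"` for automatic histogram thresholding.
#' @param min_object_area minimum component size in pixels; smaller specks
#'   are dropped.
#' @param smooth_iterations Chaikin corner-cutting passes applied to each
#'   traced boundary (0 keeps the raw staircase polygon).
#' @param smooth_harmonics harmonic count of the Fourier low-pass applied
#'   after corner cutting; `NULL` disables it. The default 24 keeps lobed
#'   cell outlines intact while removing quantization roughness.
#' @param n_points vertices per emitted contour (equally spaced by arc
#'   length); `NULL` keeps the full traced resolution.
#' @param view view label attached to the extracted contours.
#' @param id_prefix prefix used to build contour ids (`prefix_1`, ...).
#' @return A list of [contour()] objects, one per retained component, in
#'   label order. Components touching the image border have `border = TRUE`.
#' @export
extract_outlines <- function(image,
                             polarity = c("white_on_black", "black_on_white"),
                             threshold = 0.5,
                             min_object_area = 20,
                             smooth_iterations = 1L,
                             smooth_harmonics = 24L,
                             n_points = 400L,
                             view = c("lateral", "dorsal", "cell"),
                             id_prefix = "outline") {
  polarity <- match.arg(polarity)
  view <- match.arg(view)
  if (length(dim(image)) != 2L)
    stop("`image` must be a 2-D single-channel matrix")
  if (min_object_area < 1) stop("`min_object_area` must be >= 1")
  img <- if (is.logical(image)) image * 1 else image
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(img)
  mask <- img > threshold
  if (polarity == "black_on_white") mask <- !mask
  lab <- cpp_label_components(mask)
  k <- max(lab)
  if (k == 0L) stop("empty image: no foreground object above threshold")
  sizes <- tabulate(lab[lab > 0L], k)
  keep <- which(sizes >= min_object_area)
  if (length(keep) == 0L)
    stop("empty image: no object reaches min_object_area = ", min_object_area)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- vector("list", length(length(keep)))
  out <- list()
  for (idx in seq_along(keep)) {
    comp <- keep[idx]
    ij <- which(lab == comp, arr.ind = TRUE)
    touches <- any(ij[, 1L] == 1L | ij[, 1L] == nr |
                   ij[, 2L] == 1L | ij[, 2L] == nc)
    r0 <- min(ij[, 1L]); r1 <- max(ij[, 1L])
    c0 <- min(ij[, 2L]); c1 <- max(ij[, 2L])
    # padded sub-mask so the isoline closes even at the image border
    sub <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)
    sel <- lab[r0:r1, c0:c1, drop = FALSE] == comp
    sub[2:(nrow(sub) - 1L), 2:(ncol(sub) - 1L)] <- sel * 1
    # grid in y-up frame: x = column, y = nr + 1 - row
    xg <- (c0 - 1L):(c1 + 1L)
    yg <- (nr + 1L) - ((r0 - 1L):(r1 + 1L))   # decreasing
    cl <- grDevices::contourLines(x = xg, y = rev(yg),
                                  z = t(sub[nrow(sub):1L, , drop = FALSE]),
                                  levels = 0.5)
    if (length(cl) == 0L) next
    areas <- vapply(cl, function(l) abs(signed_area(cbind(l$x, l$y))), 0)
    best <- cl[[which.max(areas)]]
    pts <- cbind(best$x, best$y)
    n <- nrow(pts)
    if (all(pts[1L, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
    if (smooth_iterations > 0L) pts <- chaikin_smooth(pts, smooth_iterations)
    cc <- contour(pts, id = sprintf("%s_%d", id_prefix, idx),
                  view = view, border = touches)
    if (!is.null(smooth_harmonics)) {
      nh <- min(as.integer(smooth_harmonics), nrow(cc$points) %/% 3L)
      if (nh >= 2L) {
        rec <- reconstruct_contour(
          suppressWarnings(efd_from_contour(cc, nh)),
          n_points = max(if (is.null(n_points)) 0L else n_points,
                         32L, min(nrow(cc$points), 1000L)))
        cc <- contour(rec$points, id = cc$id, view = view, border = touches)
      }
    }
    if (!is.null(n_points) && nrow(cc$points) > n_points)
      cc <- resample_contour(cc, n_points)
    out[[length(out) + 1L]] <- cc
  }
  if (length(out) == 0L) stop("no valid outline could be traced")
  out
}

#' Write and read outline tables
#'
#' Outline tables are plain CSV with columns `contour_id`, `view`,
#' `vertex_index`, `x`, `y` (or an equivalent JSON array). Coordinates are
#' written with 17 significant digits so a write/read roundtrip reproduces
#' them exactly.
#'
#' @param cs list of [contour()] objects.
#' @param path output (input) file path; format chosen by extension
#'   (`.csv` or `.json`).
#' @return `read_outline_table` returns a list of contours ordered by
#'   `contour_id` appearance; `write_outline_table` returns `path`
#'   invisibly.
#' @export
write_outline_table <- function(cs, path) {
  if (is_contour(cs)) cs <- list(cs)
  rows <- lapply(cs, function(c) {
    data.frame(contour_id = c$id, view = c$view,
               vertex_index = seq_len(nrow(c$points)),
               x = sprintf("%.17g", c$points[, 1L]),
               y = sprintf("%.17g", c$points[, 2L]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @rdname write_outline_table
#' @export
read_outline_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(x = "character", y = "character"))
  }
  required <- c("contour_id", "view", "vertex_index", "x", "y")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("malformed outline table: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  tab$x <- as.numeric(tab$x)
  tab$y <- as.numeric(tab$y)
  tab <- tab[order(match(tab$contour_id, unique(tab$contour_id)),
                   tab$vertex_index), , drop = FALSE]
  split_rows <- split(tab, factor(tab$contour_id, levels = unique(tab$contour_id)))
  lapply(split_rows, function(d) {
    vi <- d$vertex_index
    if (any(diff(vi) != 1L) || vi[1L] != 1L)
      stop("malformed outline table: non-monotone vertex_index for contour '",
           d$contour_id[1L], "' near row ", which(diff(vi) != 1L)[1L])
    contour(cbind(d$x, d$y), id = d$contour_id[1L], view = d$view[1L])
  })
}
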