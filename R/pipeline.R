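#' Configuration for an end-to-end run
#'
#' @param input either a directory of silhouette images (PNG/TIFF), the
#'   path of an outline table (`.csv`/`.json`), or a list of [contour()]
#'   objects.
#' @param groups group labels: a named character vector / data.frame
#'   (`contour_id`, `group`) mapping contour ids (for image input: file
#'   names without extension) to groups. Every extracted outline must be
#'   mapped.
#' @param view view label applied to image-extracted outlines.
#' @param models named list assigning registry models to views.
#' @param threshold cumulative harmonic power fraction for
#'   [select_harmonic_count()].
#' @param alpha significance level of the statistical layer.
#' @param pixel_size physical length per pixel for the GMDs.
#' @param min_object_area,polarity extraction settings
#'   ([extract_outlines()]).
#' @param exclude_border drop outlines flagged as touching the image
#'   border (partial silhouettes corrupt descriptors).
#' @param out_dir output directory for the stage artifacts.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, groups, view = "lateral",
                       models = list(lateral = c("LM1", "LM2"),
                                     dorsal = c("DM2", "DM3")),
                       threshold = 0.99, alpha = 0.05, pixel_size = 1,
                       min_object_area = 50, polarity = "white_on_black",
                       exclude_border = TRUE, out_dir = tempfile("seedshape_run"),
                       seed = 1L) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  if (is.character(input) && !file.exists(input) && !dir.exists(input))
    stop("input path does not exist: ", input)
  structure(list(input = input, groups = groups, view = view,
                 models = models, threshold = threshold, alpha = alpha,
                 pixel_size = pixel_size, min_object_area = min_object_area,
                 polarity = polarity, exclude_border = exclude_border,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

load_input_contours <- function(cfg) {
  input <- cfg$input
  if (is.list(input)) return(input)
  if (dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF images found in ", input)
    cs <- list()
    for (f in files) {
      img <- read_silhouette(f)
      stem <- tools::file_path_sans_ext(basename(f))
      found <- extract_outlines(img, polarity = cfg$polarity,
                                min_object_area = cfg$min_object_area,
                                view = cfg$view, id_prefix = stem)
      if (length(found) == 1L) found[[1L]]$id <- stem
      cs <- c(cs, found)
    }
    cs
  } else {
    read_outline_table(input)
  }
}

lookup_groups <- function(cs, groups) {
  ids <- vapply(cs, function(c) c$id, "")
  map <- if (is.data.frame(groups)) {
    stats::setNames(as.character(groups$group), groups$contour_id)
  } else {
    groups
  }
  g <- unname(map[ids])
  if (anyNA(g))
    stop("group map is missing entries for: ",
         paste(utils::head(ids[is.na(g)], 5L), collapse = ", "))
  g
}

#' Run the full morphometric pipeline
#'
#' Images (or outline tables) to statistics: extraction, general
#' morphological descriptors, J index against view-assigned models,
#' elliptic Fourier analysis with harmonic selection, symmetry
#' coefficients, and the statistical layer (ANOVA + Tukey letters per
#' descriptor, MANOVA, PCA with group centroids, pairwise KS on symmetry,
#' assumption checks). Stage artifacts are plain CSV/JSON files so each
#' stage is independently inspectable and the run is reproducible; a
#' manifest records the configuration hash.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with `report` (the statistics report),
#'   `files` (paths of all artifacts) and `n_harmonics`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  cs <- load_input_contours(cfg)
  groups <- lookup_groups(cs, cfg$groups)
  if (cfg$exclude_border) {
    keep <- !vapply(cs, function(c) c$border, TRUE)
    cs <- cs[keep]; groups <- groups[keep]
  }
  if (length(cs) == 0L) stop("stage outlines: no usable outlines")
  write_outline_table(cs, out("outlines.csv"))

  gmd <- gmd_table(cs, pixel_size = cfg$pixel_size, groups = groups)
  write_csv_stable(gmd, out("gmd.csv"))

  jt <- j_index_table(cs, cfg$models)
  jt$group <- groups[match(jt$contour_id,
                           vapply(cs, function(c) c$id, ""))]
  write_csv_stable(jt, out("jindex.csv"))

  views <- vapply(cs, function(c) c$view, "")
  report <- list(alpha = cfg$alpha, views = list())
  nh_all <- list()
  sym_all <- list()
  for (v in unique(views)) {
    idx <- which(views == v)
    N <- select_harmonic_count(cs[idx], power_threshold = cfg$threshold,
                               drop_first = TRUE)
    nh_all[[v]] <- N
    fm <- efd_feature_matrix(cs[idx], N, groups = groups[idx])
    sym <- do.call(rbind, Map(function(c, g) {
      e <- normalize_efd(efd_from_contour(
        if (nrow(c$points) < 3L * N) resample_contour(c, 3L * N) else c, N))
      symmetry_index(e, group = g)
    }, cs[idx], groups[idx]))
    sym_all[[v]] <- sym
    report$views[[v]] <- stats_stage(gmd[idx, , drop = FALSE], fm, sym,
                                     groups[idx], cfg$alpha)
    report$views[[v]]$n_harmonics <- N
  }
  efd_rows <- lapply(unique(views), function(v) {
    idx <- which(views == v)
    fm <- efd_feature_matrix(cs[idx], nh_all[[v]], groups = groups[idx])
    data.frame(contour_id = rownames(fm$matrix), view = v,
               group = fm$groups, fm$matrix, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  # views may have different harmonic counts; write one file per view
  for (d in efd_rows)
    write_csv_stable(d, out(sprintf("efd_%s.csv", d$view[1L])))
  write_csv_stable(do.call(rbind, sym_all), out("sym.csv"))

  report_path <- out("report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  manifest <- list(
    package = "seedshape",
    version = as.character(utils::packageVersion("seedshape")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    n_outlines = length(cs),
    n_harmonics = nh_all,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(report = report, n_harmonics = nh_all,
                 files = list.files(cfg$out_dir, full.names = TRUE)))
}

write_csv_stable <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) sprintf("%.15g", x))
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
}

config_hash <- function(cfg) {
  x <- cfg
  x$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    x[order(names(x))], tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

stats_stage <- function(gmd, fm, sym, groups, alpha) {
  res <- list()
  k <- length(unique(groups))
  res$n_groups <- k
  res$gmd_anova <- lapply(stats::setNames(gmd_names, gmd_names), function(d) {
    if (k < 2L) return(list(note = "n/a: single group"))
    tst <- anova_tukey_cld(gmd[[d]], groups, alpha)
    list(F = tst$statistic, df = tst$df, p_value = tst$p_value,
         letters = as.list(tst$letters))
  })
  if (k >= 2L) {
    res$gmd_manova <- unclass(manova_wilks(gmd[, gmd_names], groups))
    X <- fm$matrix
    # keep the MANOVA well-posed: cap EFD dimension below the residual df
    max_p <- max(2L, min(ncol(X), nrow(X) - k - 2L))
    if (ncol(X) > max_p) {
      keep_n <- max(1L, floor(max_p / 4L))
      X <- X[, c(outer(c(0L, fm_block(ncol(X))), seq_len(keep_n),
                       function(b, i) b + i)), drop = FALSE]
    }
    X <- X[, apply(X, 2L, stats::sd) > 1e-12, drop = FALSE]
    res$efd_manova <- tryCatch(unclass(manova_wilks(X, groups)),
                               error = function(e) list(note = conditionMessage(e)))
    gs <- unique(groups)
    ks_rows <- list()
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (j <= i) next
      t <- ks_two_sample(sym$sym[groups == gs[i]], sym$sym[groups == gs[j]])
      ks_rows[[length(ks_rows) + 1L]] <-
        list(group_1 = gs[i], group_2 = gs[j], D = t$statistic,
             p_value = t$p_value)
    }
    res$symmetry_ks <- ks_rows
    res$assumptions <- lapply(stats::setNames(gmd_names, gmd_names),
      function(d) {
        a <- assumption_checks(gmd[[d]], groups, alpha)
        list(levene_p = a$levene$p_value,
             shapiro = as.list(stats::setNames(a$shapiro$p_value, a$shapiro$group)),
             violations = a$violations)
      })
  }
  pca_in <- gmd[, gmd_names]
  ok_cols <- vapply(pca_in, function(x) stats::sd(x) > 0, TRUE)
  res$pca <- tryCatch({
    p <- pca_with_centroids(pca_in[, ok_cols, drop = FALSE],
                            groups = if (k >= 2L) groups else NULL)
    list(explained = p$explained,
         centroids = if (!is.null(p$centroids))
           as.data.frame(p$centroids[, 1:2, drop = FALSE]),
         contributions = as.data.frame(round(p$contributions[, 1:2, drop = FALSE], 3)))
  }, error = function(e) list(note = conditionMessage(e)))
  res$symmetry_summary <- lapply(split(sym$sym, groups), function(v)
    list(mean = mean(v), sd = stats::sd(v), n = length(v)))
  res
}

fm_block <- function(ncols) {
  n <- ncols / 4L
  c(n, 2L * n, 3L * n)
}

#' Summarize a pipeline report as tables
#'
#' Flattens the JSON report bundle of [run_pipeline()] into human-readable
#' data.frames: per-descriptor group means with Tukey letters, PCA
#' variance, and symmetry distribution summaries.
#'
#' @param report the `report` element returned by [run_pipeline()], or the
#'   path of a written `report.json`.
#' @param gmd optionally the matching GMD table (data.frame or path of
#'   `gmd.csv`) to add group means and SDs.
#' @return A list of data.frames: `tests`, `pca_variance`, `symmetry`.
#' @export
summarize_report <- function(report, gmd = NULL) {
  if (is.character(report)) report <- jsonlite::read_json(report, simplifyVector = FALSE)
  if (is.character(gmd)) gmd <- utils::read.csv(gmd)
  tests <- list(); pcav <- list(); symm <- list()
  for (v in names(report$views)) {
    rv <- report$views[[v]]
    for (d in names(rv$gmd_anova)) {
      t <- rv$gmd_anova[[d]]
      if (!is.null(t$note)) {
        tests[[length(tests) + 1L]] <- data.frame(
          view = v, descriptor = d, F = NA_real_, p_value = NA_real_,
          letters = "n/a", stringsAsFactors = FALSE)
        next
      }
      lt <- unlist(t$letters)
      row <- data.frame(view = v, descriptor = d,
                        F = as.numeric(t$F), p_value = as.numeric(t$p_value),
                        letters = paste(names(lt), lt, sep = "=",
                                        collapse = ", "),
                        stringsAsFactors = FALSE)
      if (!is.null(gmd)) {
        m <- tapply(gmd[[d]][gmd$view == v], gmd$group[gmd$view == v], mean)
        s <- tapply(gmd[[d]][gmd$view == v], gmd$group[gmd$view == v], stats::sd)
        row$means <- paste(names(m), sprintf("%.4g +/- %.3g", m, s),
                           sep = ": ", collapse = "; ")
      }
      tests[[length(tests) + 1L]] <- row
    }
    if (!is.null(rv$pca$explained)) {
      ev <- unlist(rv$pca$explained)
      pcav[[length(pcav) + 1L]] <- data.frame(
        view = v, pc = seq_along(ev), explained = ev,
        stringsAsFactors = FALSE)
    }
    for (g in names(rv$symmetry_summary)) {
      s <- rv$symmetry_summary[[g]]
      symm[[length(symm) + 1L]] <- data.frame(
        view = v, group = g, mean_sym = as.numeric(s$mean),
        sd_sym = as.numeric(s$sd), n = as.integer(s$n),
        stringsAsFactors = FALSE)
    }
  }
  list(tests = if (length(tests)) do.call(rbind, tests) else data.frame(),
       pca_variance = if (length(pcav)) do.call(rbind, pcav) else data.frame(),
       symmetry = if (length(symm)) do.call(rbind, symm) else data.frame())
}
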