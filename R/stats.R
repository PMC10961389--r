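#' PCA with group centroids
#'
#' Principal component analysis of a specimen-by-descriptor matrix with
#' per-group centroids overlaid, the layout used for genotype comparisons.
#' Columns are centered (and scaled to unit variance if `standardize`);
#' each loading vector is sign-fixed so its largest-magnitude element is
#' positive.
#'
#' @param x numeric matrix or data.frame (rows = specimens).
#' @param groups group label per row (optional; centroids skipped if
#'   absent).
#' @param standardize scale columns to unit variance (default `TRUE`).
#' @return A list of class `seed_pca`: `scores`, `loadings`, `explained`
#'   (variance proportions), `centroids` (group x PC matrix),
#'   `contributions` (percent contribution of each variable per PC).
#' @export
pca_with_centroids <- function(x, groups = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 rows")
  if (ncol(x) < 2L) stop("PCA needs at least 2 columns")
  sds <- apply(x, 2L, stats::sd)
  if (standardize && any(sds == 0))
    stop("constant column(s) under standardization: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2L, flip, "*")
  scores <- sweep(p$x, 2L, flip, "*")
  expl <- p$sdev^2 / sum(p$sdev^2)
  centroids <- NULL
  if (!is.null(groups)) {
    centroids <- do.call(rbind, lapply(split(seq_len(nrow(scores)),
                                             as.character(groups)),
                                       function(i) colMeans(scores[i, , drop = FALSE])))
  }
  contrib <- sweep(rot^2, 2L, colSums(rot^2), "/") * 100
  structure(list(scores = scores, loadings = rot, explained = expl,
                 centroids = centroids, contributions = contrib,
                 standardized = standardize),
            class = "seed_pca")
}

#' @export
print.seed_pca <- function(x, ...) {
  cat("<seed_pca>\n  explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained[seq_len(min(5, length(x$explained)))]),
             collapse = ", "), "\n")
  if (!is.null(x$centroids)) {
    cat("  group centroids (PC1, PC2):\n")
    print(round(x$centroids[, seq_len(min(2L, ncol(x$centroids))), drop = FALSE], 3))
  }
  invisible(x)
}

# compact letter display by insert-and-absorb on the significant-pair list
cld_insert_absorb <- function(levels, sig_pairs) {
  cols <- list(levels)
  if (nrow(sig_pairs) > 0L) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[r, 1L]; b <- sig_pairs[r, 2L]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
        if (i != j && keep[i] && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            !(all(new_cols[[j]] %in% new_cols[[i]]) && i < j))
          keep[i] <- FALSE
      }
      cols <- new_cols[keep]
    }
  }
  letters_vec <- vapply(levels, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, TRUE))],
           collapse = "")
  }, "")
  letters_vec
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA, runs Tukey's honestly-significant-difference test
#' on all group pairs (studentized-range distribution) and assigns compact
#' letters by insert-and-absorb so that groups sharing a letter do not
#' differ at `alpha`. The letters are verified against the pairwise
#' p-value matrix on every call.
#'
#' @param values numeric response vector.
#' @param groups group label per value; at least 2 groups with n >= 2 each.
#' @param alpha significance level for the letter display.
#' @return A list of class `seed_test`: `test`, `statistic` (F), `df`,
#'   `p_value`, `pairs` (Tukey table), `letters` (named by group),
#'   `alpha`.
#' @export
anova_tukey_cld <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  ns <- table(g)
  if (any(ns < 2L))
    stop("every group needs n >= 2 (offending: ",
         paste(names(ns)[ns < 2L], collapse = ", "), ")")
  # safe internal level codes so pair labels split cleanly on "-"
  orig_levels <- levels(g)
  levels(g) <- sprintf("L%03d", seq_along(orig_levels))
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$g
  decode <- function(code) orig_levels[match(code, sprintf("L%03d", seq_along(orig_levels)))]
  pair_names <- lapply(strsplit(rownames(tk), "-", fixed = TRUE), decode)
  rownames(tk) <- vapply(pair_names, paste, "", collapse = "-")
  levels(g) <- orig_levels
  sig <- tk[, "p adj"] < alpha
  sig_pairs <- do.call(rbind, pair_names[sig])
  if (is.null(sig_pairs)) sig_pairs <- matrix(character(), 0L, 2L)
  # order levels by decreasing mean for conventional lettering
  means <- tapply(values, g, mean)
  lvl <- names(sort(means, decreasing = TRUE))
  letters_vec <- cld_insert_absorb(lvl, sig_pairs)
  names(letters_vec) <- lvl
  letters_vec <- letters_vec[levels(g)]
  # consistency check: shared letter <=> p >= alpha
  for (r in seq_len(nrow(tk))) {
    ab <- pair_names[[r]]
    shared <- length(intersect(strsplit(letters_vec[ab[1L]], "")[[1L]],
                               strsplit(letters_vec[ab[2L]], "")[[1L]])) > 0L
    if (shared == (tk[r, "p adj"] < alpha))
      stop("internal error: letter display inconsistent with Tukey pairs")
  }
  structure(list(test = "anova_tukey",
                 statistic = an[["F value"]][1L],
                 df = c(an[["Df"]][1L], an[["Df"]][2L]),
                 p_value = an[["Pr(>F)"]][1L],
                 pairs = data.frame(pair = rownames(tk), tk,
                                    row.names = NULL, check.names = FALSE),
                 letters = letters_vec, alpha = alpha),
            class = "seed_test")
}

#' @export
print.seed_test <- function(x, ...) {
  cat(sprintf("<seed_test> %s: statistic = %.4g, df = %s, p = %.3g\n",
              x$test, x$statistic, paste(signif(x$df, 4), collapse = "/"),
              x$p_value))
  if (!is.null(x$letters)) {
    cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' MANOVA with Wilks' lambda (Rao's F approximation)
#'
#' One-way multivariate analysis of variance. Wilks' lambda
#' `det(W) / det(W + B)` is transformed to an F statistic by Rao's
#' approximation; with a single response it reduces exactly to the one-way
#' ANOVA F. Pillai's trace is available as an alternative.
#'
#' @param x numeric matrix or data.frame of responses (rows = specimens).
#' @param groups group label per row.
#' @param statistic `"wilks"` (default) or `"pillai"`.
#' @return A `seed_test` list: `test`, `statistic` (lambda or Pillai V),
#'   `approx_f`, `df` (df1, df2), `p_value`.
#' @export
manova_wilks <- function(x, groups, statistic = c("wilks", "pillai")) {
  statistic <- match.arg(statistic)
  x <- as.matrix(x)
  g <- factor(groups)
  N <- nrow(x); p <- ncol(x); k <- nlevels(g)
  if (k < 2L) stop("at least 2 groups are required")
  if (N <= p + k)
    stop("too few specimens for ", p, " responses and ", k,
         " groups; reduce dimension first")
  gm <- rowsum(x, g) / as.vector(table(g))
  W <- crossprod(x - gm[g, , drop = FALSE])
  Tm <- crossprod(sweep(x, 2L, colMeans(x)))
  B <- Tm - W
  q <- k - 1L; v <- N - k
  if (abs(det(W)) < 1e-300)
    stop("singular within-group covariance; reduce dimension ",
         "(fewer descriptors or harmonics) and retry")
  if (statistic == "wilks") {
    lambda <- det(W) / det(W + B)
    tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
    w <- v + q - (p + q + 1) / 2
    df1 <- p * q
    df2 <- w * tt - (p * q - 2) / 2
    lam_t <- lambda^(1 / tt)
    Fstat <- (1 - lam_t) / lam_t * df2 / df1
    pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    stat <- lambda
    test <- "manova_wilks"
  } else {
    V <- sum(diag(B %*% solve(B + W)))
    s <- min(p, q)
    m <- (abs(p - q) - 1) / 2
    nn <- (v - p - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- s * (2 * nn + s + 1)
    Fstat <- (2 * nn + s + 1) / (2 * m + s + 1) * V / (s - V)
    pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    stat <- V
    test <- "manova_pillai"
  }
  structure(list(test = test, statistic = stat, approx_f = Fstat,
                 df = c(df1, df2), p_value = pval),
            class = "seed_test")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic Kolmogorov p-value at
#' the effective sample size. Used to compare symmetry-index distributions
#' between genotypes. Ties (common after min-max rescaling) only affect
#' the p-value approximation and trigger no more than a warning upstream;
#' D itself is always returned.
#'
#' @param x,y numeric samples, each with n >= 5.
#' @return A `seed_test` list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 5L || length(y) < 5L)
    stop("both samples need n >= 5")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(test = "ks_two_sample", statistic = unname(res$statistic),
                 df = c(length(x), length(y)),
                 p_value = res$p.value),
            class = "seed_test")
}

#' ANOVA assumption checks
#'
#' Levene's test in the Brown-Forsythe (median-centered) variant for
#' homogeneity of variance, and Shapiro-Wilk normality per group. Groups
#' with n < 3 are skipped for Shapiro-Wilk with a note.
#'
#' @param values numeric response vector.
#' @param groups group label per value.
#' @param alpha level at which violations are flagged.
#' @return A list of class `assumption_report`: `levene` (`seed_test`),
#'   `shapiro` (data.frame per group), `violations` (character vector).
#' @export
assumption_checks <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  lev <- car::leveneTest(values ~ g, center = stats::median)
  levene <- structure(list(test = "levene_brown_forsythe",
                           statistic = lev[["F value"]][1L],
                           df = c(lev[["Df"]][1L], lev[["Df"]][2L]),
                           p_value = lev[["Pr(>F)"]][1L]),
                      class = "seed_test")
  sw <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv]
    if (length(v) < 3L) {
      data.frame(group = lv, W = NA_real_, p_value = NA_real_,
                 note = "skipped: n < 3", stringsAsFactors = FALSE)
    } else {
      s <- stats::shapiro.test(v)
      data.frame(group = lv, W = unname(s$statistic), p_value = s$p.value,
                 note = "", stringsAsFactors = FALSE)
    }
  }))
  viol <- character()
  if (!is.na(levene$p_value) && levene$p_value < alpha)
    viol <- c(viol, "heterogeneous variances (Levene)")
  bad <- sw$group[!is.na(sw$p_value) & sw$p_value < alpha]
  if (length(bad) > 0L)
    viol <- c(viol, paste0("non-normal group(s): ", paste(bad, collapse = ", ")))
  structure(list(levene = levene, shapiro = sw, violations = viol,
                 alpha = alpha),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("<assumption_report> Levene p = %.3g; Shapiro-Wilk per group:\n",
              x$levene$p_value))
  print(x$shapiro, row.names = FALSE)
  if (length(x$violations)) cat("  flagged:", paste(x$violations, collapse = "; "), "\n")
  invisible(x)
}
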