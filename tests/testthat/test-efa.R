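# Frozen oracle values: arc-length EFD of the ellipse (2 cos t, sin t),
# start (2, 0), counterclockwise, computed by dense trapezoid quadrature of
# the defining Fourier integrals (helper efd_quadrature_oracle at 2e5 steps).
ellipse_efd_h1 <- c(A = 1.828373, B = 0, C = 0, D = 1.072997)
ellipse_efd_h3 <- c(A = 0.128907, B = 0, C = 0, D = 0.089282)

test_that("EFDs of canonical shapes match the quadrature oracle", {
  ell <- ellipse_contour(2, 1, 512)
  e <- efd_from_contour(ell, 5)
  expect_equal(unname(e$coefficients[1, ]), unname(ellipse_efd_h1),
               tolerance = 1e-3)
  expect_equal(unname(e$coefficients[3, ]), unname(ellipse_efd_h3),
               tolerance = 1e-3)
  expect_lt(max(abs(e$coefficients[c(2, 4), ])), 1e-6)  # even harmonics vanish
  expect_lt(max(abs(e$offset)), 1e-9)
  # circle: harmonic 1 carries essentially all power
  pc <- harmonic_power(efd_from_contour(circle_contour(1, 512), 10))
  expect_gte(pc[1] / sum(pc), 0.9999)
  # unit square vs quadrature at 1e5 steps; even harmonics vanish
  sq <- square_contour(1, 128)
  esq <- efd_from_contour(sq, 8)
  osq <- efd_quadrature_oracle(sq, 8)
  expect_lt(max(abs(esq$coefficients - osq)), 1e-6)
  expect_lt(max(abs(esq$coefficients[c(2, 4, 6, 8), ])), 1e-9)
})

test_that("normalized EFDs are invariant to similarity transforms and start point", {
  set.seed(201)
  blob <- random_blob(256)
  ne0 <- normalize_efd(efd_from_contour(blob, 12))
  expect_gt(ne0$coefficients[1, 1], 0)
  expect_lt(max(abs(ne0$coefficients[1, 2:3])), 1e-9)
  expect_equal(unname(ne0$coefficients[1, 1]), 1, tolerance = 1e-12)  # size removed
  for (i in 1:100) {
    a <- runif(1, 0, 2 * pi); s <- exp(runif(1, -2, 2)); sh <- rnorm(2, 0, 10)
    k <- sample(nrow(blob$points), 1)
    p <- blob$points[c(k:nrow(blob$points), seq_len(k - 1)), ]
    ne <- normalize_efd(efd_from_contour(contour(rigid_transform(p, a, s, sh)), 12))
    expect_lt(max(abs(ne$coefficients - ne0$coefficients)), 1e-6)
  }
  # start shift by a third of the perimeter
  k <- round(nrow(blob$points) / 3)
  p3 <- blob$points[c(k:nrow(blob$points), seq_len(k - 1)), ]
  ne3 <- normalize_efd(efd_from_contour(contour(p3), 12))
  expect_lt(max(abs(ne3$coefficients - ne0$coefficients)), 1e-6)
  # size kept on request
  nsz <- normalize_efd(efd_from_contour(blob, 12), size_invariant = FALSE)
  expect_gt(nsz$coefficients[1, 1], 0.5)
  expect_error(normalize_efd(efd_set(matrix(0, 2, 4))), "zero first harmonic")
})

test_that("reconstruction converges with the harmonic count", {
  ell <- ellipse_contour(2, 1, 512)
  rec <- reconstruct_contour(efd_from_contour(ell, 12), 600)
  # RMS nearest-point distance below 1e-3 of the perimeter
  nn <- vapply(seq_len(nrow(rec$points)), function(i) {
    min(sqrt(rowSums(sweep(ell$points, 2, rec$points[i, ])^2)))
  }, 0)
  expect_lt(sqrt(mean(nn^2)), 1e-3 * contour_perimeter(ell))
  # square: N = 1 reconstruction is an ellipse (J < 100 vs the square),
  # and error decreases monotonically in N
  sq <- resample_contour(square_contour(1, 128), 400)
  err_at <- function(N) {
    rc <- reconstruct_contour(efd_from_contour(sq, N), 400)
    sqrt(mean(vapply(seq_len(400), function(i) {
      min(rowSums(sweep(sq$points, 2, rc$points[i, ])^2))
    }, 0)))
  }
  e1 <- err_at(1); e5 <- err_at(5); e20 <- err_at(20)
  expect_gt(e1, e5); expect_gt(e5, e20)
  j1 <- j_index(reconstruct_contour(efd_from_contour(sq, 1), 200), sq,
                align = FALSE)$J
  expect_lt(j1, 100 - 1)
})

test_that("Parseval-style power is stable under resampling density", {
  set.seed(211)
  blob <- random_blob(300)
  p1 <- sum(harmonic_power(efd_from_contour(resample_contour(blob, 400), 20)))
  p2 <- sum(harmonic_power(efd_from_contour(resample_contour(blob, 800), 20)))
  expect_lt(abs(p2 - p1) / p1, 0.001)
})

test_that("harmonic selection finds the power threshold", {
  set.seed(221)
  ells <- lapply(1:8, function(i)
    ellipse_contour(runif(1, 1.2, 2.5), 1, 256, id = paste0("e", i)))
  expect_equal(select_harmonic_count(ells), 1L)
  # a 7-lobed radial ripple whose power exceeds 1% of the total forces the
  # selection past the ripple band (power scales with amplitude squared, so
  # the amplitude must be substantial)
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  ripple <- lapply(1:6, function(i) {
    r <- 1 + 0.3 * cos(7 * th)
    contour(cbind(r * cos(th), r * sin(th)))
  })
  expect_gte(select_harmonic_count(ripple), 7L)
  # random smooth blobs: equals a direct scan of the cumulative power table
  blobs <- lapply(1:5, function(i) random_blob(300))
  thr <- 0.999
  got <- select_harmonic_count(blobs, thr, cap = 32)
  fr <- sapply(blobs, function(c) {
    p <- harmonic_power(efd_from_contour(c, 32))
    cumsum(p) / sum(p)
  })
  expect_equal(got, which(rowMeans(fr) > thr)[1])
  # drop-first convention needs more harmonics on noisy outlines
  set.seed(222)
  rough <- lapply(1:5, function(i) {
    r <- 1 + 0.01 * rnorm(300)
    contour(cbind((1.5 + r * 0) * cos(seq(0, 2 * pi, length.out = 301)[-301]) * r,
                  sin(seq(0, 2 * pi, length.out = 301)[-301]) * r))
  })
  expect_gt(select_harmonic_count(rough, drop_first = TRUE),
            select_harmonic_count(rough, drop_first = FALSE))
  expect_error(select_harmonic_count(ells, power_threshold = 1.2), "0, 1")
})

test_that("symmetry index is 1 for mirror-symmetric outlines and 0.8 on the worked example", {
  for (c in list(ellipse_contour(2, 1, 256), cardioid_contour(1, 1, 256),
                 get_model("DM3", n_points = 256)$contour)) {
    e <- normalize_efd(efd_from_contour(c, 20))
    expect_equal(symmetry_index(e)$sym, 1, tolerance = 1e-6)
  }
  # |A| sums 1.0, |B| 0.5, |C| 0, |D| 1.0 -> (1 + 1) / 2.5 = 0.8
  hb <- efd_set(rbind(c(0.6, 0.3, 0, 0.7), c(0.4, 0.2, 0, 0.3)),
                normalized = "full")
  expect_equal(symmetry_index(hb)$sym, 0.8, tolerance = 1e-12)
  # asymmetric bumps of growing amplitude decrease the index strictly
  cd <- cardioid_contour(1, 1, 360)
  sym_at <- vapply(c(0, 0.05, 0.1, 0.2), function(d) {
    p <- cd$points
    p[, 1] <- p[, 1] + d * (p[, 2] - mean(p[, 2]))^2
    symmetry_index(normalize_efd(efd_from_contour(contour(p), 20)))$sym
  }, 0)
  expect_true(all(diff(sym_at) < 0))
})

test_that("feature matrices keep order, block layout and carry the shape signal", {
  set.seed(231)
  ells <- lapply(1:10, function(i)
    ellipse_contour(1 + 0.05 * i, 1, 128, id = sprintf("c%02d", i)))
  fm <- efd_feature_matrix(ells, 2, groups = rep(c("g1", "g2"), 5))
  expect_equal(dim(fm$matrix), c(10, 8))
  expect_equal(colnames(fm$matrix),
               c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"))
  expect_equal(rownames(fm$matrix), sprintf("c%02d", 1:10))
  # identical contours give zero row variance
  same <- lapply(1:4, function(i) ellipse_contour(1.5, 1, 128, id = paste0("s", i)))
  fs <- efd_feature_matrix(same, 3)
  expect_lt(max(apply(fs$matrix, 2, sd)), 1e-9)
  # aspect-ratio gradient dominates PC1 of the size-kept coefficients
  ar <- seq(1, 3, length.out = 20)
  grad <- lapply(ar, function(a) ellipse_contour(a, 1, 128))
  fg <- efd_feature_matrix(grad, 2, normalize_mode = "none")
  keep <- apply(fg$matrix, 2, sd) > 1e-9
  sc <- pca_with_centroids(fg$matrix[, keep], standardize = FALSE)$scores
  expect_gt(abs(cor(sc[, 1], ar)), 0.95)
  mixed <- list(ellipse_contour(2, 1, 128), cardioid_contour(1, 1, 128))
  mixed[[2]]$view <- "dorsal"
  expect_error(efd_feature_matrix(mixed, 2), "mixed views")
})

test_that("index distributions rescale per group onto the target range", {
  expect_equal(normalize_index_distribution(c(0.90, 0.95, 1.00)),
               c(-1.5, 0, 1.5))
  v <- c(0.90, 0.95, 1.00, 0.2, 0.6)
  g <- c("a", "a", "a", "b", "b")
  out <- normalize_index_distribution(v, g)
  expect_equal(range(out[g == "a"]), c(-1.5, 1.5))
  expect_equal(range(out[g == "b"]), c(-1.5, 1.5))
  # idempotent once spanning
  expect_equal(normalize_index_distribution(out, g), out)
  expect_error(normalize_index_distribution(c(1, 1, 2), c("a", "a", "b")),
               "constant.*'a'")
})
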