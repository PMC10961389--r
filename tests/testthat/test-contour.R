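test_that("contour construction enforces orientation and rejects degenerate input", {
  sq <- square_contour(2, per_side = 4)
  expect_gt(seedshape:::signed_area(sq$points), 0)
  # clockwise input is flipped to counterclockwise
  cw <- contour(sq$points[nrow(sq$points):1, ])
  expect_gt(seedshape:::signed_area(cw$points), 0)
  # consecutive duplicates are dropped
  dup <- contour(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(dup$points), 4)
  expect_error(contour(cbind(c(0, 1), c(0, 1))), "degenerate")
  expect_error(contour(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
})

test_that("resampling preserves perimeter and area and is idempotent", {
  circ <- circle_contour(n = 1024)
  rc <- resample_contour(circ, 256)
  expect_equal(nrow(rc$points), 256)
  expect_lt(abs(contour_perimeter(rc) - 2 * pi) / (2 * pi), 1e-3)
  # square: 400 points, ~100 per side
  sq <- square_contour(1, per_side = 64)
  rs <- resample_contour(sq, 400)
  expect_equal(nrow(rs$points), 400)
  on_side <- function(p) sum(abs(p[, 2]) < 1e-9)  # bottom side vertex count
  expect_lte(abs(on_side(rs$points) - 100), 1)
  # random blob: resample to 300 then 1200 changes area < 0.5%
  set.seed(101)
  blob <- random_blob()
  a1 <- polygon_area(blob)
  a2 <- polygon_area(resample_contour(resample_contour(blob, 300), 1200))
  expect_lt(abs(a2 - a1) / a1, 0.005)
  # re-resampling at fixed n contracts fast to a fixed point: one pass moves
  # vertices by far less than a vertex spacing, the next by ~100x less again
  r1 <- resample_contour(blob, 300)
  r2 <- resample_contour(r1, 300)
  r3 <- resample_contour(r2, 300)
  spacing <- contour_perimeter(r1) / 300
  d12 <- max(abs(r1$points - r2$points))
  d23 <- max(abs(r2$points - r3$points))
  expect_lt(d12, 0.01 * spacing)
  expect_lt(d23, d12 / 10)
  expect_error(resample_contour(blob, 8), "at least 16")
})

test_that("stacking centres outlines and removes scale", {
  set.seed(7)
  blob <- random_blob()
  st <- stack_outlines(list(blob))[[1]]
  expect_lt(max(abs(contour_centroid(st))), 1e-9)
  expect_equal(sqrt(mean(rowSums(st$points^2))), 1, tolerance = 1e-12)
  # scale invariance
  big <- contour(blob$points * 5, id = blob$id)
  st5 <- stack_outlines(list(big))[[1]]
  expect_lt(max(abs(st$points - st5$points)), 1e-9)
  # shape is preserved: distinct ellipses stay distinct
  e2 <- stack_outlines(list(ellipse_contour(2, 1)))[[1]]
  e3 <- stack_outlines(list(ellipse_contour(3, 1)))[[1]]
  expect_gt(max(abs(e2$points - e3$points)), 0.05)
})

test_that("outline tables roundtrip exactly and survive row shuffles", {
  set.seed(11)
  cs <- list(random_blob(120, id = "b1"), random_blob(150, id = "b2"),
             circle_contour(2, 64, id = "b3"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_outline_table(cs, path)
  tab <- utils::read.csv(path)
  expect_equal(length(unique(tab$contour_id)), 3)
  back <- read_outline_table(path)
  expect_equal(length(back), 3)
  for (i in 1:3) expect_identical(back[[i]]$points, cs[[i]]$points)
  # shuffled rows recover the same contours
  raw <- utils::read.csv(path, colClasses = "character")
  set.seed(1)
  shuf <- raw[sample(nrow(raw)), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(shuf, path2, row.names = FALSE)
  back2 <- read_outline_table(path2)
  for (i in 1:3) expect_identical(back2[[cs[[i]]$id]]$points, cs[[i]]$points)
  # JSON alternative
  pj <- withr::local_tempfile(fileext = ".json")
  write_outline_table(cs, pj)
  backj <- read_outline_table(pj)
  for (i in 1:3)
    expect_lt(max(abs(backj[[i]]$points - cs[[i]]$points)), 1e-12)
  # malformed tables are rejected with a useful message
  bad <- raw; bad$vertex_index <- NULL
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_outline_table(pb), "missing column")
  bad2 <- raw[-5, ]
  pb2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad2, pb2, row.names = FALSE)
  expect_error(read_outline_table(pb2), "non-monotone")
})

test_that("extraction recovers objects from rasterized images", {
  # centred disk r = 30 in a 100x100 image
  xy <- expand.grid(r = 1:100, c = 1:100)
  img <- matrix(0, 100, 100)
  img[as.matrix(xy[(xy$r - 50)^2 + (xy$c - 50)^2 <= 900, ])] <- 1
  cs <- extract_outlines(img)
  expect_length(cs, 1)
  expect_lt(abs(polygon_area(cs[[1]]) - pi * 900) / (pi * 900), 0.01)
  expect_false(cs[[1]]$border)
  # two disjoint disks and a 3-px speck at min_object_area = 20
  xy2 <- expand.grid(r = 1:120, c = 1:200)
  img2 <- matrix(0, 120, 200)
  img2[as.matrix(xy2[(xy2$r - 60)^2 + (xy2$c - 50)^2 <= 225, ])] <- 1
  img2[as.matrix(xy2[(xy2$r - 60)^2 + (xy2$c - 150)^2 <= 400, ])] <- 1
  img2[60, 100] <- 1; img2[60, 101] <- 1; img2[61, 100] <- 1
  expect_length(extract_outlines(img2, min_object_area = 20), 2)
  # rectangle: polygon area matches foreground pixel count within half the
  # perimeter (pixel-count oracle on the same mask)
  img3 <- matrix(0, 80, 100); img3[20:60, 30:90] <- 1
  r3 <- extract_outlines(img3)[[1]]
  expect_lt(abs(polygon_area(r3) - sum(img3)), contour_perimeter(r3) / 2)
  # border-touching objects are flagged
  img4 <- matrix(0, 50, 50); img4[1:20, 10:30] <- 1
  expect_true(extract_outlines(img4)[[1]]$border)
  # polarity inversion
  expect_length(extract_outlines(1 - img, polarity = "black_on_white"), 1)
  # errors
  expect_error(extract_outlines(matrix(0, 20, 20)), "empty image")
  expect_error(extract_outlines(array(0, c(4, 4, 2))), "2-D")
  img5 <- matrix(0, 30, 30); img5[10:12, 10:12] <- 1
  expect_error(extract_outlines(img5, min_object_area = 50), "min_object_area")
})

test_that("extraction area matches pixel counts for random convex shapes", {
  set.seed(23)
  for (i in 1:5) {
    a <- runif(1, 15, 35); b <- runif(1, 10, a)
    ang <- runif(1, 0, pi)
    ell <- ellipse_contour(a, b, 512, angle = ang)
    img <- rasterize_contour(ell, 128)
    got <- extract_outlines(img)[[1]]
    expect_gt(seedshape:::signed_area(got$points), 0)  # orientation invariant
    expect_lt(abs(polygon_area(got) - sum(img)),
              contour_perimeter(got) / 2 + 1)
  }
})

test_that("silhouette images written by the generator read back losslessly", {
  set.seed(3)
  blob <- contour(random_blob(200)$points * 40)
  f <- withr::local_tempfile(fileext = ".png")
  seedshape:::write_outline_image(blob, f, 256)
  img <- read_silhouette(f)
  expect_equal(dim(img), c(256, 256))
  got <- extract_outlines(img)[[1]]
  expect_lt(abs(polygon_area(got) - polygon_area(blob)) / polygon_area(blob),
            0.02)
})
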