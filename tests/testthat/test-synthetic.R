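test_that("population specs validate their parameters", {
  expect_s3_class(population_spec("g", 5), "population_spec")
  expect_error(population_spec("g", 0), "n")
  expect_error(population_spec("g", 5, lobe_amplitude = 0.6), "0.5")
  expect_error(population_spec("g", 5, size_cv = -1), "CV")
})

test_that("generation is deterministic under a fixed spec and seed", {
  sp <- population_spec("g", 8, size_scale = 30,
                        asymmetry_regime = "fluctuating",
                        asymmetry_delta = 0.08, seed = 42)
  p1 <- generate_population(sp)
  p2 <- generate_population(sp)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$contours[[3]]$points, p2$contours[[3]]$points)
  # and the written artifacts are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_population(sp, out_dir = d1, raster_size = 128)
  generate_population(sp, out_dir = d2, raster_size = 128)
  # outlines that cannot fit the canvas are refused, not silently shrunk
  expect_error(generate_population(population_spec("big", 1, seed = 1),
                                   out_dir = withr::local_tempdir(),
                                   raster_size = 128),
               "canvas")
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  f <- list.files(d1, pattern = "png$")[1]
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  expect_equal(nrow(p1$truth), 8)
})

test_that("asymmetry regimes produce their signatures", {
  # no asymmetry, no noise: perfectly symmetric outlines
  sp0 <- population_spec("g0", 3, asymmetry_regime = "none", noise_sd = 0,
                         elongation_cv = 0, seed = 5)
  for (c in generate_population(sp0)$contours) {
    e <- normalize_efd(efd_from_contour(c, 20))
    expect_equal(symmetry_index(e)$sym, 1, tolerance = 1e-6)
  }
  # directional: positive mean measured asymmetry
  spd <- population_spec("gd", 50, asymmetry_regime = "directional",
                         asymmetry_delta = 0.1, seed = 6)
  sa <- vapply(generate_population(spd)$contours, signed_asymmetry, 0)
  expect_lt(stats::t.test(sa, alternative = "greater")$p.value, 0.01)
  # left-directional mirrors the sign
  spl <- population_spec("gl", 50, asymmetry_regime = "directional",
                         asymmetry_delta = -0.1, seed = 7)
  sal <- vapply(generate_population(spl)$contours, signed_asymmetry, 0)
  expect_lt(stats::t.test(sal, alternative = "less")$p.value, 0.01)
  # antisymmetry: near-zero mean, large spread (bimodal mixture moments)
  spa <- population_spec("ga", 200, asymmetry_regime = "anti",
                         asymmetry_delta = 0.1, seed = 8)
  pa <- generate_population(spa)
  expect_lt(abs(mean(pa$truth$signed_asymmetry)), 0.1 / 4)
  expect_gt(sd(pa$truth$signed_asymmetry), 0.1 / 2)
  saa <- vapply(pa$contours, signed_asymmetry, 0)
  expect_lt(abs(mean(saa)), sd(saa))  # measured distribution centred near 0
  # symmetry index decreases monotonically with directional amplitude
  mean_sym <- vapply(c(0, 0.06, 0.12, 0.2), function(d) {
    sp <- population_spec("m", 12, asymmetry_regime = "directional",
                          asymmetry_delta = d, noise_sd = 0, seed = 9)
    mean(vapply(generate_population(sp)$contours, function(c)
      symmetry_index(normalize_efd(efd_from_contour(c, 20)))$sym, 0))
  }, 0)
  expect_true(all(diff(mean_sym) < 0))
})

test_that("cell outlines lose solidity as lobe amplitude grows", {
  sp0 <- population_spec("c0", 5, base_shape = "cell", lobe_amplitude = 0,
                         noise_sd = 0, view = "cell", seed = 10)
  sol0 <- vapply(generate_population(sp0)$contours,
                 function(c) compute_gmd(c)$solidity, 0)
  expect_true(all(sol0 >= 0.999))
  spl <- population_spec("cl", 8, base_shape = "cell", lobe_count = 12,
                         lobe_amplitude = 0.25, noise_sd = 0.005,
                         view = "cell", seed = 11)
  soll <- vapply(generate_population(spl)$contours,
                 function(c) compute_gmd(c)$solidity, 0)
  expect_lt(mean(soll), 0.95)
  mean_sol <- vapply(c(0, 0.1, 0.2, 0.3), function(a) {
    sp <- population_spec("cm", 8, base_shape = "cell", lobe_amplitude = a,
                          noise_sd = 0.005, view = "cell", seed = 12)
    mean(vapply(generate_population(sp)$contours,
                function(c) compute_gmd(c)$solidity, 0))
  }, 0)
  expect_true(all(diff(mean_sol) < 0))
})

test_that("images plus truth tables round-trip through extraction", {
  sp <- population_spec("rt", 10, base_shape = "DM2", view = "dorsal",
                        seed = 13)
  d <- withr::local_tempdir()
  pop <- generate_population(sp, out_dir = d)
  files <- list.files(d, pattern = "png$", full.names = TRUE)
  expect_length(files, 10)
  expect_equal(nrow(pop$truth), 10)
  areas <- vapply(files, function(f)
    polygon_area(extract_outlines(read_silhouette(f))[[1]]), 0)
  expect_lt(abs(mean(areas) - mean(pop$truth$area)) / mean(pop$truth$area),
            0.03)
})

test_that("scenario presets encode the study designs", {
  pl <- scenario_presets("ploidy", seed = 3)
  expect_length(pl, 2)
  expect_equal(pl[[2]]$size_scale / pl[[1]]$size_scale, 1.3)
  same <- setdiff(names(pl[[1]]), c("group", "n", "size_scale", "seed"))
  expect_equal(pl[[1]][same], pl[[2]][same])  # equal shape parameters
  expect_equal(pl[[1]]$n, 100L)  # study-sized populations by default
  expect_equal(pl[[2]]$n, 80L)
  sx <- scenario_presets("sex_symmetry", seed = 3)
  expect_setequal(vapply(sx, function(s) s$asymmetry_regime, ""),
                  c("directional", "directional", "anti"))
  deltas <- vapply(sx, function(s) s$asymmetry_delta, 0)
  expect_equal(sort(sign(deltas[vapply(sx, function(s)
    s$asymmetry_regime, "") == "directional"])), c(-1, 1))
  hy <- scenario_presets("hybrid_maternal", seed = 3)
  expect_length(hy, 4)
  el <- vapply(hy, function(s) s$elongation, 0)
  maternal <- substr(vapply(hy, function(s) s$group, ""), 1, 2)
  expect_true(all(el[maternal == "Sl"] > el[maternal == "Sd"]))
  ce <- scenario_presets("cells", seed = 3)
  expect_length(unique(vapply(ce, function(s) s$lobe_amplitude, 0)), 2)
  expect_error(scenario_presets("nope"), "arg")
  # n override applies everywhere
  expect_true(all(vapply(scenario_presets("ploidy", n_per_group = 7),
                         function(s) s$n, 0L) == 7L))
})
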