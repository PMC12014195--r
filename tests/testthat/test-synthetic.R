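test_that("noiseless scenes render exact palette colours and fractions", {
  pal <- default_fst_palette()
  sc <- render_scene(scene_spec(tibble::tibble(fst = 4, fraction = 1),
                                width = 40, height = 30, noise_sigma = 0,
                                seed = 2), pal)
  lab <- srgb_to_lab(sc$image)
  px <- matrix(as.numeric(unclass(lab)), ncol = 3)
  d <- delta_e_cie76(px, unlist(pal[4, c("L", "a", "b")]))
  expect_lt(max(d), 0.01)
  # constructed geometry gives exact fractions (width divisible)
  sc2 <- render_scene(scene_spec(tibble::tibble(fst = c(3, 4),
                                                fraction = c(0.75, 0.25)),
                                 width = 80, height = 20, noise_sigma = 0,
                                 seed = 2), pal)
  expect_equal(unname(sc2$truth_fractions), c(0, 0, 0.75, 0.25, 0, 0))
  expect_identical(sc2$dominant_fst, 3L)
})

test_that("rendering is deterministic given the seed", {
  spec <- scene_spec(tibble::tibble(fst = c(2, 3), fraction = c(0.6, 0.4)),
                     width = 48, height = 36, noise_sigma = 2,
                     lighting_gradient = 4, seed = 33)
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("malformed scene specs are rejected", {
  expect_error(scene_spec(tibble::tibble(fst = c(3, 4),
                                         fraction = c(0.8, 0.3))),
               "sum to 1")
  expect_error(scene_spec(tibble::tibble(fst = 9, fraction = 1)), "1..6")
  tiny <- scene_spec(tibble::tibble(fst = c(3, 4),
                                    fraction = c(0.999, 0.001)),
                     width = 20, height = 10)
  expect_error(render_scene(tiny), "rounds to zero")
})

test_that("background bands are near-black and excluded from truth", {
  sc <- render_scene(scene_spec(tibble::tibble(fst = 3, fraction = 1),
                                width = 40, height = 20, noise_sigma = 0,
                                background_fraction = 0.25, seed = 5))
  expect_equal(sum(sc$truth == 0), 20 * 10)
  lab <- srgb_to_lab(sc$image)
  bg_l <- unclass(lab)[, 1:10, 1]
  expect_lt(max(bg_l), 10)
  expect_equal(unname(sc$truth_fractions), c(0, 0, 1, 0, 0, 0))
})

test_that("region mean colour converges to the palette colour", {
  pal <- default_fst_palette()
  target <- unlist(pal[5, c("L", "a", "b")])
  for (sigma in c(2, 0.5)) {
    sc <- render_scene(scene_spec(tibble::tibble(fst = 5, fraction = 1),
                                  width = 60, height = 40,
                                  noise_sigma = sigma, seed = 8), pal)
    px <- matrix(as.numeric(unclass(srgb_to_lab(sc$image))), ncol = 3)
    expect_lt(max(abs(colMeans(px) - target)), 4 * sigma / sqrt(nrow(px)) + 0.05)
  }
})

test_that("lighting gradients tilt only the lightness channel", {
  base <- scene_spec(tibble::tibble(fst = 3, fraction = 1),
                     width = 30, height = 50, noise_sigma = 0, seed = 3)
  lit <- base
  lit$lighting_gradient <- 10
  a <- srgb_to_lab(render_scene(base)$image)
  b <- srgb_to_lab(render_scene(lit)$image)
  dl <- unclass(b)[, , 1] - unclass(a)[, , 1]
  expect_equal(dl[1, 1], -5, tolerance = 0.05)
  expect_equal(dl[50, 1], 5, tolerance = 0.05)
  expect_lt(max(abs(unclass(b)[, , 2:3] - unclass(a)[, , 2:3])), 0.05)
})

test_that("cohorts honour the class mix and per-image determinism", {
  one_hot <- c(0, 1, 0, 0, 0, 0)
  co <- generate_cohort(n = 6, class_mix = one_hot, seed = 4,
                        width = 24, height = 18)
  expect_true(all(co$true_fst == 2L))
  again <- generate_cohort(n = 6, class_mix = one_hot, seed = 4,
                           width = 24, height = 18)
  expect_identical(co$scene[[3]]$image, again$scene[[3]]$image)
  expect_error(generate_cohort(4, class_mix = rep(0.3, 6)), "summing to 1")
})

test_that("large-cohort class frequencies sit inside binomial 99% bounds", {
  co <- generate_cohort(n = 1000, seed = 9, width = 18, height = 12,
                        noise_sigma = 0, lighting_gradient = 0)
  counts <- tabulate(co$true_fst, 6)
  lo <- qbinom(0.005, 1000, 1 / 6)
  hi <- qbinom(0.995, 1000, 1 / 6)
  expect_true(all(counts >= lo & counts <= hi))
})
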