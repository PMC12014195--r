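test_that("centres match their nearest palette entry with light-class ties", {
  pal <- default_fst_palette()
  palm <- as.matrix(pal[, c("L", "a", "b")])
  exact <- match_clusters(palm[3, , drop = FALSE], pal)
  expect_equal(exact$fst, 3L)
  expect_equal(exact$delta_e, 0)
  # centre equidistant between FST II and III goes to II
  mid <- (palm[2, ] + palm[3, ]) / 2
  expect_equal(match_clusters(rbind(mid), pal)$fst, 2L)
  # seeded random centres equal the exhaustive 6-way scan
  set.seed(8)
  centers <- cbind(runif(20, 0, 100), runif(20, -20, 40), runif(20, -20, 40))
  got <- match_clusters(centers, pal)
  for (i in 1:20) {
    d <- sqrt(colSums((t(palm) - centers[i, ])^2))
    expect_equal(got$fst[i], pal$fst[which.min(d)])
    expect_equal(got$delta_e[i], min(d), tolerance = 1e-12)
  }
})

test_that("cluster fractions are exact tallies", {
  labels <- c(rep(1L, 756), rep(2L, 244))
  expect_equal(cluster_fractions(labels, 2), c(0.756, 0.244))
  expect_equal(cluster_fractions(rep(1L, 10), 3), c(1, 0, 0))
  set.seed(4)
  lab <- sample(1:5, 500, replace = TRUE)
  fr <- cluster_fractions(lab, 5)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(fr, as.numeric(table(factor(lab, 1:5))) / 500)
  expect_error(cluster_fractions(integer(0), 2), "empty")
  expect_error(cluster_fractions(c(1L, 7L), 2), "1..k")
})

test_that("a single-tone image is classified as its generating class", {
  sc <- render_scene(scene_spec(tibble::tibble(fst = 4, fraction = 1),
                                width = 80, height = 60, noise_sigma = 1,
                                seed = 13))
  res <- classify_image(sc$image, k = 2, seed = 3)
  expect_identical(res$dominant_fst, 4L)
  expect_equal(sum(res$matches$fraction), 1, tolerance = 1e-9)
})

test_that("a 75/25 two-region image recovers fractions and dominant class", {
  sc <- two_region_scene(seed = 11)
  res <- classify_image(sc$image, k = 2, seed = 5)
  td <- tidy(res)
  expect_identical(res$dominant_fst, 3L)
  got <- sort(td$fraction, decreasing = TRUE)
  expect_lt(max(abs(got - c(0.75, 0.25))), 0.02)
  # every reported delta_e is minimal over the palette (brute force)
  palm <- as.matrix(res$palette[, c("L", "a", "b")])
  for (i in seq_len(nrow(td))) {
    expect_equal(td$delta_e[i],
                 min(sqrt(colSums((t(palm) - res$centers[i, ])^2))),
                 tolerance = 1e-9)
  }
})

test_that("classification is deterministic and orientation-invariant", {
  sc <- two_region_scene(width = 80, height = 60, seed = 19)
  r1 <- classify_image(sc$image, k = 2, seed = 7)
  r2 <- classify_image(sc$image, k = 2, seed = 7)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))
  # rotating or flipping permutes pixels only: same fractions and class
  img <- unclass(sc$image)
  rot <- array(c(apply(img[, , 1], 1, rev), apply(img[, , 2], 1, rev),
                 apply(img[, , 3], 1, rev)),
               dim = c(dim(img)[2], dim(img)[1], 3))
  class(rot) <- "rgb_image"
  flip <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  class(flip) <- "rgb_image"
  for (other in list(rot, flip)) {
    ro <- classify_image(other, k = 2, seed = 7)
    expect_identical(ro$dominant_fst, r1$dominant_fst)
    expect_equal(sort(tidy(ro)$fraction), sort(tidy(r1)$fraction),
                 tolerance = 1e-12)
  }
})

test_that("masks exclude background and empty masks fail", {
  sc <- two_region_scene(width = 80, height = 60, seed = 23,
                         background_fraction = 0.3)
  mask <- sc$truth > 0
  res <- expect_silent(classify_image(sc$image, k = 2, seed = 7,
                                      mask = mask))
  expect_identical(res$dominant_fst, 3L)
  expect_error(classify_image(sc$image, k = 2, mask = mask & FALSE),
               "excludes every pixel")
  # without a mask the dark background grabs a cluster and warns
  expect_warning(classify_image(sc$image, k = 3, seed = 7), "dark cluster")
})

test_that("segmentation maps are internally consistent", {
  sc <- two_region_scene(width = 80, height = 60, noise_sigma = 1,
                         seed = 29)
  seg <- segment_image(sc$image, k = 3, seed = 7, max_dim = 128)
  # legend is the single source of truth for the rasters
  expect_identical(seg$fst_raster,
                   matrix(seg$legend$fst[seg$label_raster],
                          nrow(seg$label_raster), ncol(seg$label_raster)))
  expect_equal(seg$legend$fraction,
               cluster_fractions(as.vector(seg$label_raster), seg$k))
  expect_error(segment_image(sc$image, k = 1), "k >= 2")
})

test_that("a flat image segments to a single constant FST class", {
  flat <- array(0, dim = c(40, 40, 3))
  flat[, , 1] <- 61
  flat[, , 2] <- 11
  flat[, , 3] <- 19
  class(flat) <- "lab_image"
  seg <- segment_image(flat, k = 2, seed = 3)
  expect_true(all(seg$fst_raster == 3L))
  sw <- sweep_cluster_counts(flat, ks = 2:4, seed = 3)
  expect_true(all(sw$fraction[sw$fst == 3] == 1))
})

test_that("region boundaries are located within two pixels", {
  sc <- two_region_scene(width = 120, height = 60, noise_sigma = 1,
                         seed = 31)
  seg <- segment_image(sc$image, k = 2, seed = 7, max_dim = 512)
  true_boundary <- max(which(sc$truth[1, ] == 3L))
  per_row_ok <- vapply(seq_len(nrow(seg$fst_raster)), function(r) {
    row <- seg$fst_raster[r, ]
    cross <- which(diff(row) != 0)
    length(cross) == 1 && abs(cross - true_boundary) <= 2
  }, logical(1))
  expect_gte(mean(per_row_ok), 0.95)
})

test_that("fraction aggregation by class preserves the dominant tone", {
  sc <- two_region_scene(seed = 37)
  sw <- sweep_cluster_counts(sc$image, ks = 2:4, seed = 7)
  expect_setequal(unique(sw$k), 2:4)
  for (kk in 2:4) {
    sub <- sw[sw$k == kk, ]
    expect_equal(sum(sub$fraction), 1, tolerance = 1e-9)
    expect_identical(sub$fst[which.max(sub$fraction)], 3L)
    dom_frac <- sub$fraction[sub$fst == 3]
    expect_lt(abs(dom_frac - 0.75), 0.05)
    # aggregated dominant class equals the per-segmentation dominant
    seg <- attr(sw, "segmentations")[[paste0("k", kk)]]
    expect_identical(seg$dominant_fst, 3L)
  }
})
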