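test_that("the model registry is closed", {
  expect_length(cluster_models(), 12)
  expect_error(fit_clusters(matrix(1:30, ncol = 3), model = "kmedoids"),
               "unknown clustering model")
  expect_error(fit_clusters(matrix(runif(9), 3, 3), k = 5), "exceeds")
})

test_that("two duplicated far colours are recovered exactly", {
  x <- rbind(matrix(rep(c(70, 10, 15), 3), ncol = 3, byrow = TRUE),
             matrix(rep(c(30, 20, 25), 3), ncol = 3, byrow = TRUE))
  fit <- fit_clusters(x, "kmeans", k = 2, seed = 1)
  expect_equal(sort(fit$centers[, 1]), c(30, 70))
  expect_true(same_partition(fit$labels, rep(1:2, each = 3)))
  expect_equal(fit$extras$inertia, 0)
})

test_that("every model family returns a total partition on blob data", {
  # two well-separated blobs sized so density models keep their defaults
  blobs <- make_blobs(n_per = 80, sigma = 0.8, seed = 17)
  for (m in cluster_models()) {
    fit <- fit_clusters(blobs$x, model = m, k = 2, seed = 42)
    expect_length(fit$labels, nrow(blobs$x))
    expect_true(all(fit$labels >= 1L & fit$labels <= fit$k),
                label = paste(m, "labels in range"))
    expect_true(all(tabulate(fit$labels, fit$k) > 0),
                label = paste(m, "no empty cluster"))
    expect_true(all(is.finite(fit$centers)),
                label = paste(m, "finite centres"))
    # every cluster is pure with respect to the generating blobs
    purity <- tapply(blobs$truth, fit$labels,
                     function(t) max(table(t)) / length(t))
    expect_true(all(purity == 1), label = paste(m, "blob-pure clusters"))
  }
})

test_that("centroid-style models match nearest-true-centre assignment", {
  blobs <- make_blobs(n_per = 50, sigma = 1, seed = 6)
  oracle <- oracle_assign(blobs$x, blobs$centers)
  for (m in c("kmeans", "kmeans_minibatch", "kmeans_pca", "gmm",
              "fuzzy_cmeans", "ahc", "spectral")) {
    fit <- fit_clusters(blobs$x, model = m, k = 2, seed = 11)
    expect_true(same_partition(fit$labels, oracle),
                label = paste(m, "recovers the generating partition"))
  }
})

test_that("density models infer two clusters and flag reassigned noise", {
  blobs <- make_blobs(n_per = 80, sigma = 0.8, seed = 23)
  for (m in c("dbscan", "hdbscan", "optics_dbscan", "mean_shift")) {
    fit <- fit_clusters(blobs$x, model = m, seed = 2)
    expect_equal(fit$k, 2, label = paste(m, "finds k = 2"))
    expect_gte(fit$extras$noise_reassigned, 0)
  }
})

test_that("fuzzy c-means exposes its membership matrix", {
  blobs <- make_blobs(seed = 3)
  fit <- fit_clusters(blobs$x, "fuzzy_cmeans", k = 2, seed = 5)
  mem <- fit$extras$membership
  expect_equal(dim(mem), c(nrow(blobs$x), 2))
  expect_equal(rowSums(mem), rep(1, nrow(blobs$x)), tolerance = 1e-6)
  # hardened labels are the membership argmax
  expect_equal(fit$labels, unname(max.col(mem)))
})

test_that("noise pixels go to their nearest centre", {
  set.seed(9)
  centers <- matrix(runif(9, 0, 100), 3, 3)
  x <- matrix(runif(120, 0, 100), ncol = 3)
  labels <- sample(c(-1L, 0L, 1L, 2L, 3L), nrow(x), replace = TRUE)
  out <- assign_noise_pixels(labels, x, centers)
  keep <- labels >= 1L
  expect_identical(out[keep], labels[keep])
  noise <- which(!keep)
  bf <- apply(x[noise, ], 1, function(p) {
    which.min(colSums((t(centers) - p)^2))
  })
  expect_identical(out[noise], as.integer(bf))
  # a noise point on a centre gets that centre's label
  expect_identical(assign_noise_pixels(c(1L, -1L),
                                       rbind(centers[1, ], centers[2, ]),
                                       centers)[2], 2L)
  expect_error(assign_noise_pixels(c(-1L, -1L), x[1:2, ],
                                   centers[0, , drop = FALSE]),
               "clustering failure")
})

test_that("PCA projection preserves geometry and variance structure", {
  set.seed(14)
  x <- matrix(rnorm(300), ncol = 3) %*%
    matrix(c(3, 1, 0, 0, 2, 1, 0, 0, 0.5), 3, 3)
  # full-rank projection is a rigid rotation
  p3 <- pca_project(x, 3)
  expect_equal(as.matrix(dist(p3)), as.matrix(dist(x)), tolerance = 1e-9)
  # points on a line are perfectly captured by one component
  line <- outer(seq(0, 1, length.out = 40), c(2, -1, 3))
  p1 <- pca_project(line, 1)
  recon <- p1 %*% t(attr(p1, "rotation"))
  recon <- sweep(recon, 2, attr(p1, "center"), "+")
  expect_equal(recon, line, tolerance = 1e-9, ignore_attr = TRUE)
  # component variances are the covariance eigenvalues
  expect_equal(attr(p3, "sdev")^2, sort(eigen(cov(x))$values,
                                        decreasing = TRUE),
               tolerance = 1e-9)
})
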