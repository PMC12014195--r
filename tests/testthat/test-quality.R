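test_that("silhouette closed forms hold on constructed partitions", {
  # two duplicated points per cluster, far apart: a = 0, b > 0 -> 1
  x <- rbind(c(0, 0, 0), c(0, 0, 0), c(50, 0, 0), c(50, 0, 0))
  expect_equal(silhouette_score(x, c(1, 1, 2, 2)), 1)
  # 4-point instance evaluated per point by the brute-force oracle
  x4 <- rbind(c(0, 0, 0), c(0, 1, 0), c(10, 10, 0), c(10, 11, 0))
  lab4 <- c(1, 1, 2, 2)
  expect_close(silhouette_score(x4, lab4), bf_silhouette(x4, lab4))
  expect_error(silhouette_score(x4, rep(1, 4)), "single cluster")
})

test_that("all three indices match from-scratch oracles on seeded instances", {
  for (i in 1:6) {
    set.seed(400 + i)
    n <- sample(40:150, 1)
    k <- sample(2:4, 1)
    x <- matrix(runif(n * 3, 0, 100), ncol = 3)
    labels <- sample(seq_len(k), n, replace = TRUE)
    labels[seq_len(k)] <- seq_len(k) # every cluster non-empty
    expect_close(silhouette_score(x, labels), bf_silhouette(x, labels))
    expect_close(calinski_harabasz(x, labels),
                 bf_calinski_harabasz(x, labels))
    expect_close(davies_bouldin(x, labels), bf_davies_bouldin(x, labels))
  }
})

test_that("silhouette agrees with the cluster package implementation", {
  set.seed(77)
  x <- matrix(runif(240, 0, 100), ncol = 3)
  labels <- sample(1:3, 80, replace = TRUE)
  sil <- cluster::silhouette(labels, dist(x))
  expect_close(silhouette_score(x, labels), mean(sil[, "sil_width"]))
})

test_that("silhouette subsampling is seeded and exact at full size", {
  blobs <- make_blobs(n_per = 100, sigma = 2, seed = 31)
  full <- silhouette_score(blobs$x, blobs$truth, sample_size = NULL)
  expect_equal(silhouette_score(blobs$x, blobs$truth,
                                sample_size = nrow(blobs$x)), full)
  s1 <- silhouette_score(blobs$x, blobs$truth, sample_size = 50, seed = 3)
  s2 <- silhouette_score(blobs$x, blobs$truth, sample_size = 50, seed = 3)
  expect_identical(s1, s2)
})

test_that("Calinski-Harabasz has the documented limits and monotonicity", {
  x <- rbind(c(0, 0, 0), c(0, 0, 0), c(9, 9, 9), c(9, 9, 9))
  expect_identical(calinski_harabasz(x, c(1, 1, 2, 2)), Inf)
  tight <- make_blobs(n_per = 60, sigma = 1, seed = 40)
  noisy <- make_blobs(n_per = 60, sigma = 3, seed = 40)
  expect_gt(calinski_harabasz(tight$x, tight$truth),
            calinski_harabasz(noisy$x, noisy$truth))
  expect_error(calinski_harabasz(x[1:2, ], 1:2), "k >= N")
})

test_that("Davies-Bouldin limits, linearity in spread, and error cases", {
  x <- rbind(c(0, 0, 0), c(0, 0, 0), c(9, 9, 9), c(9, 9, 9))
  expect_equal(davies_bouldin(x, c(1, 1, 2, 2)), 0)
  # doubling every point's offset from its centroid doubles the index
  base <- make_blobs(n_per = 40, sigma = 1, seed = 50)
  centred <- base$x
  for (j in 1:2) {
    rows <- base$truth == j
    mu <- colMeans(base$x[rows, ])
    centred[rows, ] <- sweep(base$x[rows, , drop = FALSE], 2, mu, "-")
  }
  spread2 <- centred * 2
  for (j in 1:2) {
    rows <- base$truth == j
    mu <- colMeans(base$x[rows, ])
    spread2[rows, ] <- sweep(spread2[rows, , drop = FALSE], 2, mu, "+")
  }
  expect_equal(davies_bouldin(spread2, base$truth),
               2 * davies_bouldin(base$x, base$truth), tolerance = 1e-9)
  dup <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_error(davies_bouldin(dup, c(1, 1, 2, 2)), "coincident")
})

test_that("separation-sensitive indices degrade together under noise", {
  sils <- chs <- dbs <- numeric(3)
  for (i in 1:3) {
    b <- make_blobs(n_per = 60, sigma = c(0.5, 1.5, 3)[i], seed = 60)
    sils[i] <- silhouette_score(b$x, b$truth)
    chs[i] <- calinski_harabasz(b$x, b$truth)
    dbs[i] <- davies_bouldin(b$x, b$truth)
  }
  expect_true(all(diff(sils) < 0))
  expect_true(all(diff(chs) < 0))
  expect_true(all(diff(dbs) > 0))
})

test_that("the benchmark harness isolates failures and is deterministic", {
  blobs <- make_blobs(n_per = 90, sigma = 1, seed = 70)
  one <- benchmark_models(blobs$x, models = "kmeans", k = 2, seed = 1)
  expect_equal(nrow(one), 1)
  expect_gt(one$silhouette, 0.9) # fixture separation >> spread
  mixed <- benchmark_models(blobs$x, models = c("kmeans", "kmedoids", "gmm"),
                            k = 2, seed = 1)
  expect_equal(mixed$status[c(1, 3)], c("ok", "ok"))
  expect_match(mixed$status[2], "error")
  expect_true(all(is.na(mixed$silhouette[2])))
  again <- benchmark_models(blobs$x, models = c("kmeans", "kmedoids", "gmm"),
                            k = 2, seed = 1)
  drop_time <- function(d) d[, setdiff(names(d), "fit_seconds")]
  expect_equal(drop_time(mixed), drop_time(again))
  expect_error(benchmark_models(blobs$x, models = character(0)), "no models")
})

test_that("degenerate single-cluster fits are reported, not raised", {
  x <- matrix(rnorm(150, 50, 0.5), ncol = 3)
  fit <- fit_clusters(x, "dbscan", seed = 1)
  expect_equal(fit$k, 1)
  rep <- quality_report(x, fit)
  expect_identical(rep$status, "degenerate")
  expect_true(is.na(rep$silhouette))
})
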