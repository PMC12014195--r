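# Internal clustering validity indices and the model benchmark harness.
# All three indices use Euclidean distance in CIELAB, the clustering space,
# so "distance" below always means Delta-E (CIE76).

#' Mean silhouette score of a labelled pixel cloud
#'
#' For each point `i`, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)`
#' is the mean distance to the other members of its own cluster and `b(i)`
#' the smallest mean distance to the members of any other cluster; singleton
#' clusters contribute `s(i) = 0`. The score is the mean of `s(i)` over
#' (sampled) points and lies in `[-1, 1]`; higher is better.
#'
#' For large pixel clouds the score is computed on a seeded subsample of
#' `sample_size` points (clusters that survive in the subsample are scored
#' within it); set `sample_size = NULL` to force the full computation, which
#' is exact but quadratic in N.
#'
#' @param pixels `N x 3` LAB matrix.
#' @param labels Integer cluster labels in `1..k`, length N.
#' @param sample_size Subsample cap (default 10000), or `NULL` for full.
#' @param seed Seed for the subsample draw.
#' @return A single number in `[-1, 1]`.
#' @export
silhouette_score <- function(pixels, labels, sample_size = 10000L,
                             seed = 42L) {
  x <- as.matrix(pixels)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  check_two_clusters(labels)
  n <- nrow(x)
  if (!is.null(sample_size) && n > sample_size) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    idx <- sort(sample.int(n, sample_size))
    x <- x[idx, , drop = FALSE]
    labels <- labels[idx]
    check_two_clusters(labels)
  }
  ids <- sort(unique(labels))
  k <- length(ids)
  lab_idx <- match(labels, ids)
  counts <- tabulate(lab_idx, nbins = k)
  n <- nrow(x)
  # mean distance from every point to each cluster, block-wise
  mean_d <- matrix(0, n, k)
  member <- matrix(0, n, k)
  member[cbind(seq_len(n), lab_idx)] <- 1
  for (rows in block_rows(n)) {
    d <- sqrt(dist2_to_centers(x[rows, , drop = FALSE], x))
    mean_d[rows, ] <- (d %*% member) %*% diag(1 / counts, k)
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab_idx[i]
    if (counts[ci] == 1L) next # singleton: s = 0
    a <- mean_d[i, ci] * counts[ci] / (counts[ci] - 1L) # exclude self
    b <- min(mean_d[i, -ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index (variance ratio criterion)
#'
#' `[tr(B)/(k-1)] / [tr(W)/(N-k)]`, where `B` and `W` are the between- and
#' within-cluster scatter matrices about the cluster means and the global
#' mean. Higher is better. If every cluster has zero within-scatter the
#' index is `Inf` (documented sentinel for the zero-variance limit).
#'
#' @inheritParams silhouette_score
#' @return A non-negative number (possibly `Inf`).
#' @export
calinski_harabasz <- function(pixels, labels) {
  x <- as.matrix(pixels)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  check_two_clusters(labels)
  n <- nrow(x)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k >= n) {
    stop("Calinski-Harabasz is undefined for k >= N", call. = FALSE)
  }
  g <- colMeans(x)
  tr_b <- 0
  tr_w <- 0
  for (j in ids) {
    m <- x[labels == j, , drop = FALSE]
    cj <- colMeans(m)
    tr_b <- tr_b + nrow(m) * sum((cj - g)^2)
    tr_w <- tr_w + sum(sweep(m, 2, cj, "-")^2)
  }
  if (tr_w == 0) return(Inf)
  (tr_b / (k - 1)) / (tr_w / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters `i` of `max_{j != i} (S_i + S_j) / M_ij`, where `S` is
#' the mean distance of members to their centroid and `M` the distance
#' between centroids. Lower is better; two zero-variance clusters give 0.
#' Coincident centroids of distinct clusters make the ratio undefined and
#' raise an error naming the offending pair.
#'
#' @inheritParams silhouette_score
#' @return A non-negative number.
#' @export
davies_bouldin <- function(pixels, labels) {
  x <- as.matrix(pixels)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  check_two_clusters(labels)
  ids <- sort(unique(labels))
  k <- length(ids)
  centroids <- cluster_means(x, labels, ids)
  s <- vapply(seq_len(k), function(j) {
    m <- x[labels == ids[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, centroids[j, ], "-")^2)))
  }, numeric(1))
  m_d <- as.matrix(stats::dist(centroids))
  bad <- which(m_d == 0 & upper.tri(m_d), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("Davies-Bouldin undefined: clusters ", ids[bad[1, 1]], " and ",
         ids[bad[1, 2]], " have coincident centroids", call. = FALSE)
  }
  r <- outer(s, s, "+") / m_d
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

check_two_clusters <- function(labels) {
  if (length(unique(labels)) < 2L) {
    stop("validity indices are undefined for a single cluster",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Score a clustering fit with all three validity indices
#'
#' @param pixels `N x 3` LAB matrix.
#' @param fit A `skin_clustering` object for those pixels.
#' @param sample_size,seed Passed to [silhouette_score()].
#' @return A one-row tibble: `model`, `k_found`, `silhouette`,
#'   `calinski_harabasz`, `davies_bouldin`, `fit_seconds`, `status`.
#'   Undefined indices (single cluster) are reported as `NA` with
#'   `status = "degenerate"` rather than raising, so sweep tables stay
#'   complete.
#' @export
quality_report <- function(pixels, fit, sample_size = 10000L, seed = 42L) {
  stopifnot(inherits(fit, "skin_clustering"))
  idx <- function(f) tryCatch(f, error = function(e) NA_real_)
  sil <- idx(silhouette_score(pixels, fit$labels, sample_size, seed))
  ch <- idx(calinski_harabasz(pixels, fit$labels))
  db <- idx(davies_bouldin(pixels, fit$labels))
  status <- if (fit$k < 2L || anyNA(c(sil, ch, db))) "degenerate" else "ok"
  tibble::tibble(model = fit$model, k_found = fit$k,
                 silhouette = sil, calinski_harabasz = ch,
                 davies_bouldin = db, fit_seconds = fit$fit_seconds,
                 status = status)
}

#' Benchmark clustering models on one pixel cloud
#'
#' Fits each requested model on the same LAB pixels and scores it with the
#' three validity indices plus wall-clock fit time. A model that errors is
#' recorded as a row with `status` carrying the message, so one failure
#' never aborts the sweep. Fit times are hardware-dependent and are reported
#' for orientation only.
#'
#' @param pixels `N x 3` LAB matrix or a `lab_image` array.
#' @param models Character vector of model names, or `"all"` for the full
#'   registry of [cluster_models()].
#' @param k Cluster count passed to models that take one.
#' @param seed Seed shared by every fit (and the silhouette subsample).
#' @param params Named list of per-model parameter lists, e.g.
#'   `list(dbscan = list(eps = 3))`.
#' @param sample_size Silhouette subsample cap.
#' @return A tibble with one row per requested model, sortable by any index.
#' @export
benchmark_models <- function(pixels, models = "all", k = 4L, seed = 42L,
                             params = list(), sample_size = 10000L) {
  if (identical(models, "all")) models <- cluster_models()
  if (length(models) == 0L) stop("no models requested", call. = FALSE)
  if (inherits(pixels, "lab_image") || length(dim(pixels)) == 3L) {
    pixels <- image_to_pixels(pixels)
  }
  rows <- purrr::map(models, function(m) {
    tryCatch({
      fit <- fit_clusters(pixels, model = m, k = k, seed = seed,
                          params = params[[m]] %||% list())
      quality_report(pixels, fit, sample_size = sample_size, seed = seed)
    }, error = function(e) {
      tibble::tibble(model = m, k_found = NA_integer_,
                     silhouette = NA_real_, calinski_harabasz = NA_real_,
                     davies_bouldin = NA_real_, fit_seconds = NA_real_,
                     status = paste("error:", conditionMessage(e)))
    })
  })
  dplyr::bind_rows(rows)
}
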