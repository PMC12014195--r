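#' Names of the supported clustering model families
#'
#' Twelve families behind one interface: centroid models (`kmeans`,
#' `kmeans_minibatch`, `kmeans_pca`), density models (`dbscan`, `hdbscan`,
#' `optics_dbscan`), hierarchical (`ahc`), probabilistic (`gmm`), fuzzy
#' (`fuzzy_cmeans`), and exemplar/graph models (`affinity_propagation`,
#' `mean_shift`, `spectral`). Density and exemplar models infer the number
#' of clusters; the others take `k`.
#'
#' @return Character vector of model names accepted by [fit_clusters()].
#' @export
cluster_models <- function() {
  c("kmeans", "kmeans_minibatch", "kmeans_pca",
    "dbscan", "hdbscan", "optics_dbscan",
    "ahc", "gmm", "fuzzy_cmeans",
    "affinity_propagation", "mean_shift", "spectral")
}

#' Cluster a LAB pixel cloud with a named model
#'
#' Dispatches to one of the twelve supported clustering families and returns
#' a uniform result: integer labels in `1..k` for every pixel (density-model
#' noise points are reassigned to the nearest cluster centre so the partition
#' is total) and one LAB centre per cluster. Models without native centroids
#' (density models, AHC, spectral, affinity propagation) report per-cluster
#' LAB means as centres, which is what Delta-E palette matching needs.
#' Quadratic-cost models operate on a seeded pixel subsample and extend
#' labels to the full cloud by nearest-centre assignment (see `params`
#' defaults in Details).
#'
#' @details Per-model tunables (override via `params`):
#' * `kmeans`, `kmeans_minibatch`, `kmeans_pca`: `n_init` (10), `max_iter`
#'   (300), `tol` (1e-4); mini-batch adds `batch_size` (1024), `n_iter`
#'   (100); `kmeans_pca` adds `n_components` (2).
#' * `dbscan`: `eps` (1.2 Delta-E), `min_samples` (12), `max_points` (5000).
#' * `hdbscan`: `min_cluster_size` (2% of N, at least 25), `min_samples`
#'   (10), `max_points` (4096).
#' * `optics_dbscan`: `eps` (1.2), `min_samples` (12), `max_points` (4096).
#' * `ahc`: `linkage` ("ward.D2"), `max_points` (4000).
#' * `gmm`: `model_names` (c("VVV","VEV","VII")), `max_points` (6000).
#' * `fuzzy_cmeans`: `m` (2), `max_iter` (300).
#' * `affinity_propagation`: `damping` (0.9), `max_iter` (200),
#'   `preference` (median similarity), `max_points` (1000).
#' * `mean_shift`: `bandwidth` (estimated), `quantile` (0.25),
#'   `max_seeds` (500).
#' * `spectral`: `max_points` (2000).
#'
#' @param pixels An `N x 3` LAB matrix (or a `lab_image` array, flattened).
#' @param model One of [cluster_models()].
#' @param k Number of clusters for models that take one; ignored (with the
#'   found number reported) by density/exemplar models.
#' @param seed Integer seed; fits are deterministic given it.
#' @param params Named list of model hyperparameters overriding the defaults.
#' @return A `skin_clustering` object with fields `labels` (length N,
#'   values `1..k`), `centers` (`k x 3` LAB), `k`, `model`, `fit_seconds`,
#'   `converged` and `extras` (model-specific: fuzzy membership matrix,
#'   inertia trace, noise count before reassignment, ...).
#' @export
fit_clusters <- function(pixels, model = "kmeans", k = 4L, seed = 42L,
                         params = list()) {
  if (length(model) != 1L || !model %in% cluster_models()) {
    stop("unknown clustering model '", paste(model, collapse = ","),
         "'; see cluster_models()", call. = FALSE)
  }
  if (inherits(pixels, "lab_image") || length(dim(pixels)) == 3L) {
    pixels <- image_to_pixels(pixels)
  }
  x <- as.matrix(pixels)
  n <- nrow(x)
  needs_k <- model %in% c("kmeans", "kmeans_minibatch", "kmeans_pca",
                          "ahc", "gmm", "fuzzy_cmeans", "spectral")
  if (needs_k) {
    stopifnot(k >= 1)
    if (k > n) stop("n_clusters (", k, ") exceeds the number of pixels (",
                    n, ")", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  fit <- switch(model,
    kmeans = {
      p <- merge_params(list(n_init = 10L, max_iter = 300L, tol = 1e-4),
                        params)
      km <- kmeans_reference(x, k, seed = seed, n_init = p$n_init,
                             max_iter = p$max_iter, tol = p$tol)
      list(labels = km$labels, centers = km$centers,
           converged = km$converged, extras = km$extras)
    },
    kmeans_minibatch = fit_minibatch(x, k, params),
    kmeans_pca = fit_kmeans_pca(x, k, seed, params),
    dbscan = fit_dbscan(x, params),
    hdbscan = fit_hdbscan(x, params),
    optics_dbscan = fit_optics(x, params),
    ahc = fit_ahc(x, k, params),
    gmm = fit_gmm(x, k, params),
    fuzzy_cmeans = fit_fcm(x, k, params),
    affinity_propagation = fit_affinity(x, params),
    mean_shift = fit_meanshift(x, params),
    spectral = fit_spectral(x, k, params)
  )
  elapsed <- proc.time()[["elapsed"]] - t0

  labels <- as.integer(fit$labels)
  noise <- sum(labels < 1L, na.rm = TRUE) + sum(is.na(labels))
  if (noise > 0L) {
    labels[is.na(labels)] <- 0L
    present <- sort(unique(labels[labels >= 1L]))
    if (length(present) == 0L) {
      stop("clustering failure: model '", model,
           "' marked every pixel as noise", call. = FALSE)
    }
    centers <- cluster_means(x, labels, present)
    labels <- assign_noise_pixels(labels, x, centers)
  }
  # compact relabelling 1..k over non-empty clusters
  present <- sort(unique(labels))
  labels <- match(labels, present)
  centers <- if (!is.null(fit$centers) && noise == 0L &&
                 nrow(as.matrix(fit$centers)) == length(present)) {
    as.matrix(fit$centers)[present, , drop = FALSE]
  } else {
    cluster_means(x, labels, seq_along(present))
  }
  extras <- fit$extras %||% list()
  extras$noise_reassigned <- noise
  extras$seed <- seed
  new_skin_clustering(labels, centers, model, elapsed,
                      converged = fit$converged %||% TRUE, extras = extras)
}

merge_params <- function(defaults, params) {
  utils::modifyList(defaults, params %||% list())
}

cluster_means <- function(x, labels, ids) {
  t(vapply(ids, function(j) colMeans(x[labels == j, , drop = FALSE]),
           numeric(ncol(x))))
}

#' Reassign noise-labelled pixels to their nearest cluster centre
#'
#' Density-based models leave some pixels unlabelled ("noise"); downstream
#' pixel fractions require a total partition, so each noise pixel is given
#' the label of the nearest centre under CIE76 distance. Labels `<= 0` or
#' `NA` are treated as noise; all other labels pass through unchanged.
#'
#' @param labels Integer vector; noise encoded as `-1`, `0` or `NA`.
#' @param pixels `N x 3` LAB matrix matching `labels`.
#' @param centers `k x 3` matrix of LAB cluster centres (row j is the centre
#'   of label j).
#' @return Integer label vector with every entry in `1..k`.
#' @export
assign_noise_pixels <- function(labels, pixels, centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0L) {
    stop("clustering failure: no cluster centres to absorb noise points",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  noise <- which(is.na(labels) | labels < 1L)
  if (length(noise) == 0L) return(labels)
  d2 <- dist2_to_centers(as.matrix(pixels)[noise, , drop = FALSE], centers)
  labels[noise] <- max.col(-d2, ties.method = "first")
  labels
}

#' Project pixels onto their top principal components
#'
#' Mean-centred projection onto the leading `n_components` directions of the
#' sample covariance (no scaling). Used inside the `kmeans_pca` model, which
#' clusters in the reduced space and then re-expresses centres as per-cluster
#' LAB means in the original space.
#'
#' @param pixels `N x 3` numeric matrix.
#' @param n_components Integer in 1..3.
#' @return `N x n_components` score matrix with attributes `"rotation"`,
#'   `"center"` and `"sdev"`.
#' @export
pca_project <- function(pixels, n_components = 2L) {
  stopifnot(n_components >= 1L, n_components <= ncol(pixels))
  pc <- stats::prcomp(as.matrix(pixels), center = TRUE, scale. = FALSE)
  out <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(out, "rotation") <- pc$rotation[, seq_len(n_components), drop = FALSE]
  attr(out, "center") <- pc$center
  attr(out, "sdev") <- pc$sdev
  out
}

# -- centroid-family fitters --------------------------------------------------

fit_kmeans_pca <- function(x, k, seed, params) {
  p <- merge_params(list(n_components = 2L, n_init = 10L, max_iter = 300L,
                         tol = 1e-4), params)
  proj <- pca_project(x, p$n_components)
  km <- kmeans_reference(proj, k, seed = seed, n_init = p$n_init,
                         max_iter = p$max_iter, tol = p$tol)
  list(labels = km$labels, centers = NULL, converged = km$converged,
       extras = list(n_components = p$n_components,
                     explained_var = attr(proj, "sdev")^2))
}

fit_minibatch <- function(x, k, params) {
  p <- merge_params(list(batch_size = 1024L, n_iter = 100L), params)
  n <- nrow(x)
  bs <- min(p$batch_size, n)
  centers <- kmeanspp_init(x[sample.int(n, min(n, 4L * bs)), , drop = FALSE],
                           k)
  counts <- rep(0, k)
  for (it in seq_len(p$n_iter)) {
    batch <- x[sample.int(n, bs), , drop = FALSE]
    lab <- max.col(-dist2_to_centers(batch, centers), ties.method = "first")
    for (j in unique(lab)) {
      members <- batch[lab == j, , drop = FALSE]
      counts[j] <- counts[j] + nrow(members)
      eta <- nrow(members) / counts[j]
      centers[j, ] <- (1 - eta) * centers[j, ] + eta * colMeans(members)
    }
  }
  d2 <- dist2_to_centers(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  list(labels = labels, centers = centers, converged = TRUE,
       extras = list(inertia = sum(d2[cbind(seq_len(n), labels)])))
}

# -- library-backed fitters ---------------------------------------------------

fit_ahc <- function(x, k, params) {
  p <- merge_params(list(linkage = "ward.D2", max_points = 4000L), params)
  sub <- subsample_idx(nrow(x), p$max_points)
  hc <- stats::hclust(stats::dist(x[sub, , drop = FALSE]), method = p$linkage)
  sub_labels <- stats::cutree(hc, k = min(k, length(sub)))
  extend_from_subsample(x, sub, sub_labels)
}

fit_gmm <- function(x, k, params) {
  p <- merge_params(list(model_names = c("VVV", "VEV", "VII"),
                         max_points = 6000L), params)
  sub <- subsample_idx(nrow(x), p$max_points)
  xs <- x[sub, , drop = FALSE]
  fit <- NULL
  for (mn in p$model_names) {
    fit <- tryCatch(
      mclust::Mclust(xs, G = k, modelNames = mn, verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("GMM fit failed for every covariance model",
                         call. = FALSE)
  out <- extend_from_subsample(x, sub, as.integer(fit$classification))
  out$extras <- list(covariance_model = fit$modelName,
                     loglik = fit$loglik, bic = fit$bic)
  out
}

fit_fcm <- function(x, k, params) {
  p <- merge_params(list(m = 2, max_iter = 300L), params)
  fit <- e1071::cmeans(x, centers = k, m = p$m, iter.max = p$max_iter)
  list(labels = as.integer(fit$cluster), centers = fit$centers,
       converged = TRUE,
       extras = list(membership = fit$membership, fuzzifier = p$m))
}

fit_spectral <- function(x, k, params) {
  p <- merge_params(list(max_points = 2000L), params)
  sub <- subsample_idx(nrow(x), p$max_points)
  xs <- x[sub, , drop = FALSE]
  # specc needs some spread; jitter exactly duplicated points minutely
  sc <- kernlab::specc(xs, centers = k)
  extend_from_subsample(x, sub, as.integer(sc@.Data))
}

# -- helpers ------------------------------------------------------------------

subsample_idx <- function(n, cap) {
  if (n <= cap) seq_len(n) else sort(sample.int(n, cap))
}

# labels on a subsample -> centres as LAB means -> full labels by nearest
extend_from_subsample <- function(x, sub, sub_labels) {
  ids <- sort(unique(sub_labels))
  centers <- cluster_means(x[sub, , drop = FALSE], sub_labels, ids)
  if (length(sub) == nrow(x)) {
    labels <- match(sub_labels, ids)
  } else {
    labels <- max.col(-dist2_to_centers(x, centers), ties.method = "first")
  }
  list(labels = labels, centers = NULL, converged = TRUE,
       extras = list(subsample_size = length(sub)))
}
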