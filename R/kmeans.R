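#' Reference k-means (Lloyd's algorithm with k-means++ seeding)
#'
#' The package's native k-means: k-means++ initialisation, Lloyd iterations
#' (assign to nearest centre, recompute means), best of `n_init` restarts by
#' within-cluster sum of squares. Deterministic given `seed`. Argmin ties are
#' broken toward the lowest cluster index; a cluster emptied during
#' iteration is reseeded with the point farthest from its centre.
#'
#' @param pixels An `N x d` numeric matrix (rows are LAB pixels).
#' @param k Number of clusters, `1 <= k <= N`.
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence tolerance on the maximum squared centre shift.
#' @return A `skin_clustering` object; see [fit_clusters()].
#' @export
kmeans_reference <- function(pixels, k, seed = 42L, n_init = 10L,
                             max_iter = 300L, tol = 1e-4) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (k > n) stop("k (", k, ") exceeds the number of pixels (", n, ")",
                  call. = FALSE)
  stopifnot(k >= 1, n_init >= 1, max_iter >= 1)
  t0 <- proc.time()[["elapsed"]]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (run in seq_len(n_init)) {
    init <- kmeanspp_init(pixels, k)
    fit <- lloyd_iterate(pixels, init, max_iter, tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  new_skin_clustering(
    labels = best$labels,
    centers = best$centers,
    model = "kmeans",
    fit_seconds = proc.time()[["elapsed"]] - t0,
    converged = best$converged,
    extras = list(inertia = best$inertia, inertia_trace = best$trace,
                  iterations = best$iterations, seed = seed)
  )
}

# k-means++: first centre uniform, then proportional to squared distance
# to the nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L) # all points coincide with a centre
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
  }
  centers
}

# Squared Euclidean distances from each row of x to each row of centers.
dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

lloyd_iterate <- function(x, centers, max_iter, tol) {
  k <- nrow(centers)
  labels <- rep(0L, nrow(x))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(x)), new_labels)])
    trace <- c(trace, inertia)
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- which(new_labels == j)
      if (length(members) == 0L) {
        # reseed an empty cluster with the worst-fit point
        far <- which.max(d2[cbind(seq_len(nrow(x)), new_labels)])
        new_centers[j, ] <- x[far, ]
      } else {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    shift <- max(rowSums((new_centers - centers)^2))
    same <- all(new_labels == labels)
    centers <- new_centers
    labels <- new_labels
    if (shift < tol || same) {
      converged <- TRUE
      break
    }
  }
  d2 <- dist2_to_centers(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centers = centers, inertia = inertia,
       converged = converged, iterations = iter, trace = trace)
}

# -- clustering result container ---------------------------------------------

new_skin_clustering <- function(labels, centers, model, fit_seconds,
                                converged = TRUE, extras = list()) {
  centers <- as.matrix(centers)
  colnames(centers) <- c("L", "a", "b")[seq_len(ncol(centers))]
  structure(
    list(labels = as.integer(labels),
         centers = centers,
         k = nrow(centers),
         model = model,
         fit_seconds = as.numeric(fit_seconds),
         converged = isTRUE(converged),
         extras = extras),
    class = "skin_clustering"
  )
}

#' @export
print.skin_clustering <- function(x, ...) {
  cat("<skin_clustering> model:", x$model, " k:", x$k,
      " n:", length(x$labels),
      sprintf(" fit: %.3fs", x$fit_seconds),
      if (!x$converged) " (not converged)" else "", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cluster summary of a clustering fit
#'
#' @param x A `skin_clustering` object.
#' @param ... Unused.
#' @return A tibble with one row per cluster: `cluster`, centre coordinates
#'   `L`, `a`, `b`, member count `size` and `fraction` of pixels.
#' @method tidy skin_clustering
#' @export
tidy.skin_clustering <- function(x, ...) {
  counts <- tabulate(x$labels, nbins = x$k)
  tibble::tibble(cluster = seq_len(x$k),
                 L = x$centers[, 1], a = x$centers[, 2], b = x$centers[, 3],
                 size = counts,
                 fraction = counts / length(x$labels))
}

#' One-row fit summary of a clustering fit
#'
#' @param x A `skin_clustering` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `k`, `n`, `fit_seconds`, `converged`
#'   and `inertia` (NA for models that do not minimise it).
#' @method glance skin_clustering
#' @export
glance.skin_clustering <- function(x, ...) {
  tibble::tibble(model = x$model, k = x$k, n = length(x$labels),
                 fit_seconds = x$fit_seconds, converged = x$converged,
                 inertia = x$extras$inertia %||% NA_real_)
}
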