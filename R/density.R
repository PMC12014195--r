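# Density-based and exemplar-based clustering models, implemented in-package.
# All operate on an N x 3 LAB pixel matrix; quadratic-cost steps run on a
# seeded subsample (see `max_points`) and labels are extended to the full
# cloud by nearest-centre assignment in fit_clusters().
#
# Noise is encoded as label 0 here; fit_clusters() reassigns it.

# Euclidean distances from a block of rows to all points, computed in blocks
# so no full N x N matrix is ever held for DBSCAN.
block_rows <- function(n, block = 1024L) {
  split(seq_len(n), ceiling(seq_len(n) / block))
}

fit_dbscan <- function(x, params) {
  p <- merge_params(list(eps = 1.2, min_samples = 12L, max_points = 5000L),
                    params)
  sub <- subsample_idx(nrow(x), p$max_points)
  xs <- x[sub, , drop = FALSE]
  n <- nrow(xs)
  eps2 <- p$eps^2
  nb <- vector("list", n)
  for (rows in block_rows(n)) {
    d2 <- dist2_to_centers(xs[rows, , drop = FALSE], xs)
    for (i in seq_along(rows)) nb[[rows[i]]] <- which(d2[i, ] <= eps2)
  }
  core <- lengths(nb) >= p$min_samples # neighbourhood includes the point
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0L) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      fresh <- nb[[q]][labels[nb[[q]]] == 0L]
      labels[fresh] <- cl
      queue <- c(queue, fresh[core[fresh]])
    }
  }
  sub_to_full(x, sub, labels,
              extras = list(eps = p$eps, min_samples = p$min_samples,
                            n_core = sum(core)))
}

# k-th nearest-neighbour distance (neighbourhood includes the point itself),
# computed block-wise.
core_distances <- function(x, k) {
  n <- nrow(x)
  out <- numeric(n)
  for (rows in block_rows(n)) {
    d2 <- dist2_to_centers(x[rows, , drop = FALSE], x)
    for (i in seq_along(rows)) {
      out[rows[i]] <- sqrt(sort(d2[i, ], partial = k)[k])
    }
  }
  out
}

fit_hdbscan <- function(x, params) {
  p <- merge_params(list(min_cluster_size = NULL, min_samples = 10L,
                         max_points = 4096L), params)
  sub <- subsample_idx(nrow(x), p$max_points)
  xs <- x[sub, , drop = FALSE]
  n <- nrow(xs)
  mcs <- p$min_cluster_size %||% max(25L, round(0.02 * n))
  core <- core_distances(xs, min(p$min_samples, n))
  d <- as.matrix(stats::dist(xs))
  mreach <- pmax(d, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  labels <- hdbscan_extract(hc, n, mcs)
  if (all(labels == 0L)) {
    stop("clustering failure: HDBSCAN found no cluster of at least ",
         mcs, " points", call. = FALSE)
  }
  sub_to_full(x, sub, labels,
              extras = list(min_cluster_size = mcs,
                            min_samples = p$min_samples))
}

# Condensed-tree cluster extraction (excess-of-mass stability) over a
# single-linkage dendrogram on mutual-reachability distances.
hdbscan_extract <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  # subtree sizes and leaf lists per merge row
  size <- integer(nrow(merge))
  for (r in seq_len(nrow(merge))) {
    size[r] <- sum(ifelse(merge[r, ] < 0, 1L, size[pmax(merge[r, ], 1L)]))
  }
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    out <- integer(0)
    stack <- node
    while (length(stack) > 0L) {
      r <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (child in merge[r, ]) {
        if (child < 0) out <- c(out, -child) else stack <- c(stack, child)
      }
    }
    out
  }
  node_size <- function(node) if (node < 0) 1L else size[node]

  # condensed tree bookkeeping, cluster 1 = root
  birth <- 0
  stability <- 0
  parent <- 0L
  pts <- list(integer(0))
  kids <- list(integer(0))
  stack <- list(list(row = nrow(merge), cl = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    r <- top$row
    c <- top$cl
    lam <- 1 / max(height[r], 1e-12)
    ch <- merge[r, ]
    sz <- c(node_size(ch[1]), node_size(ch[2]))
    big <- sz >= mcs
    if (all(big)) {
      stability[c] <- stability[c] + sum(sz) * (lam - birth[c])
      for (i in 1:2) {
        new <- length(birth) + 1L
        birth[new] <- lam
        stability[new] <- 0
        parent[new] <- c
        pts[[new]] <- integer(0)
        kids[[new]] <- integer(0)
        kids[[c]] <- c(kids[[c]], new)
        stack[[length(stack) + 1L]] <- list(row = ch[i], cl = new)
      }
    } else {
      for (i in 1:2) {
        if (big[i]) {
          stack[[length(stack) + 1L]] <- list(row = ch[i], cl = c)
        } else {
          shed <- leaves_of(ch[i])
          stability[c] <- stability[c] + length(shed) * (lam - birth[c])
          pts[[c]] <- c(pts[[c]], shed)
        }
      }
    }
  }
  n_cl <- length(birth)
  if (n_cl == 1L) return(integer(n)) # no split survived: all noise
  # bottom-up excess-of-mass selection (root is never selected)
  choice <- character(n_cl)
  eff <- stability
  for (c in rev(seq_len(n_cl))) {
    if (length(kids[[c]]) == 0L) {
      choice[c] <- "self"
    } else {
      s_kids <- sum(eff[kids[[c]]])
      if (c != 1L && stability[c] > s_kids) {
        choice[c] <- "self"
      } else {
        choice[c] <- "kids"
        eff[c] <- s_kids
      }
    }
  }
  choice[1L] <- if (length(kids[[1L]]) > 0L) "kids" else "none"
  selected <- integer(0)
  walk <- 1L
  while (length(walk) > 0L) {
    c <- walk[[1L]]
    walk <- walk[-1L]
    if (choice[c] == "self") selected <- c(selected, c)
    else walk <- c(walk, kids[[c]])
  }
  # nearest selected ancestor-or-self, top-down in creation order
  anc <- integer(n_cl)
  for (c in seq_len(n_cl)) {
    anc[c] <- if (c %in% selected) c
              else if (parent[c] > 0L) anc[parent[c]] else 0L
  }
  labels <- integer(n)
  ids <- sort(selected)
  for (c in seq_len(n_cl)) {
    if (anc[c] > 0L && length(pts[[c]]) > 0L) {
      labels[pts[[c]]] <- match(anc[c], ids)
    }
  }
  labels
}

fit_optics <- function(x, params) {
  p <- merge_params(list(eps = 1.2, min_samples = 12L, max_eps = Inf,
                         max_points = 4096L), params)
  sub <- subsample_idx(nrow(x), p$max_points)
  xs <- x[sub, , drop = FALSE]
  n <- nrow(xs)
  core <- core_distances(xs, min(p$min_samples, n))
  core[core > p$max_eps] <- Inf
  reach <- rep(Inf, n)
  processed <- logical(n)
  order_out <- integer(n)
  for (step in seq_len(n)) {
    cand <- which(!processed)
    o <- cand[which.min(reach[cand])]
    # ties / all-Inf: which.min picks the first unprocessed point
    processed[o] <- TRUE
    order_out[step] <- o
    if (is.finite(core[o])) {
      d <- sqrt(dist2_to_centers(xs[o, , drop = FALSE], xs))[1, ]
      upd <- !processed & d <= p$max_eps
      reach[upd] <- pmin(reach[upd], pmax(core[o], d[upd]))
    }
  }
  # DBSCAN-equivalent extraction at radius eps along the ordering
  labels <- integer(n)
  cl <- 0L
  reach_ord <- reach[order_out]
  core_ord <- core[order_out]
  for (i in seq_len(n)) {
    if (reach_ord[i] > p$eps) {
      if (core_ord[i] <= p$eps) {
        cl <- cl + 1L
        labels[order_out[i]] <- cl
      } # else noise
    } else {
      labels[order_out[i]] <- max(cl, 1L)
      if (cl == 0L) cl <- 1L
    }
  }
  sub_to_full(x, sub, labels,
              extras = list(eps = p$eps, min_samples = p$min_samples,
                            reachability = reach_ord))
}

fit_affinity <- function(x, params) {
  p <- merge_params(list(damping = 0.9, max_iter = 200L, conv_iter = 30L,
                         preference = NULL, max_points = 1000L), params)
  sub <- subsample_idx(nrow(x), p$max_points)
  xs <- x[sub, , drop = FALSE]
  n <- nrow(xs)
  S <- -as.matrix(stats::dist(xs))^2
  pref <- p$preference %||% stats::median(S[upper.tri(S)])
  diag(S) <- pref
  R <- A <- matrix(0, n, n)
  lam <- p$damping
  stable <- 0L
  prev_ex <- integer(0)
  converged <- FALSE
  for (it in seq_len(p$max_iter)) {
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    r_new <- S - max1
    r_new[cbind(seq_len(n), max1_idx)] <- S[cbind(seq_len(n), max1_idx)] -
      max2
    R <- lam * R + (1 - lam) * r_new
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    a_new <- matrix(pmin(0, rep(cs, each = n) - as.vector(Rp)), n, n)
    diag(a_new) <- cs - diag(R)
    A <- lam * A + (1 - lam) * a_new
    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) > 0L && identical(ex, prev_ex)) {
      stable <- stable + 1L
      if (stable >= p$conv_iter) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    prev_ex <- ex
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(R) + diag(A))
  sub_labels <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  sub_labels[ex] <- seq_along(ex)
  out <- sub_to_full(x, sub, sub_labels,
                     extras = list(n_exemplars = length(ex),
                                   preference = pref))
  out$converged <- converged
  out
}

fit_meanshift <- function(x, params) {
  p <- merge_params(list(bandwidth = NULL, quantile = 0.25, max_seeds = 500L,
                         max_iter = 200L, max_points = 20000L), params)
  sub <- subsample_idx(nrow(x), p$max_points)
  xs <- x[sub, , drop = FALSE]
  n <- nrow(xs)
  h <- p$bandwidth %||% {
    probe <- xs[subsample_idx(n, 400L), , drop = FALSE]
    pd <- stats::dist(probe)
    max(stats::quantile(pd[pd > 0], p$quantile), 1e-6)
  }
  seeds <- xs[subsample_idx(n, p$max_seeds), , drop = FALSE]
  h2 <- h^2
  for (it in seq_len(p$max_iter)) {
    d2 <- dist2_to_centers(xs, seeds) # n x S
    W <- d2 <= h2
    counts <- colSums(W)
    new_seeds <- crossprod(W, xs) / pmax(counts, 1L)
    keep <- counts == 0L
    if (any(keep)) new_seeds[keep, ] <- seeds[keep, ]
    move2 <- max(rowSums((new_seeds - seeds)^2))
    seeds <- new_seeds
    if (move2 < (1e-3 * h)^2) break
  }
  # merge modes within h/2, favouring better-supported modes
  support <- colSums(dist2_to_centers(xs, seeds) <= h2)
  ord <- order(support, decreasing = TRUE)
  modes <- NULL
  for (i in ord) {
    if (is.null(modes)) {
      modes <- seeds[i, , drop = FALSE]
    } else if (min(dist2_to_centers(seeds[i, , drop = FALSE], modes)) >
               (h / 2)^2) {
      modes <- rbind(modes, seeds[i, ])
    }
  }
  sub_labels <- max.col(-dist2_to_centers(xs, modes), ties.method = "first")
  sub_to_full(x, sub, sub_labels,
              extras = list(bandwidth = h, n_modes = nrow(modes)))
}

# Wrap subsample labels (0 = noise allowed) for fit_clusters():
# noise reassignment happens at full scale, so extend cluster labels only.
sub_to_full <- function(x, sub, sub_labels, extras = list()) {
  if (length(sub) == nrow(x)) {
    return(list(labels = sub_labels, centers = NULL, converged = TRUE,
                extras = extras))
  }
  ids <- sort(unique(sub_labels[sub_labels >= 1L]))
  if (length(ids) == 0L) {
    return(list(labels = integer(nrow(x)), centers = NULL, converged = TRUE,
                extras = extras))
  }
  centers <- cluster_means(x[sub, , drop = FALSE], sub_labels, ids)
  labels <- max.col(-dist2_to_centers(x, centers), ties.method = "first")
  extras$subsample_size <- length(sub)
  list(labels = labels, centers = NULL, converged = TRUE, extras = extras)
}
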