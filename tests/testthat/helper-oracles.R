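# Independent oracles and fixture builders. Oracles are deliberately written
# as plain loops over textbook formulas, sharing no code with the package.

# sRGB (0-255) -> CIELAB via the textbook route: inverse sRGB gamma,
# D65 2-degree XYZ matrix, cube-root CIELAB transform.
ref_srgb_to_lab <- function(rgb) {
  rgb <- matrix(as.numeric(rgb), ncol = 3)
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- t(m %*% t(lin))
  wp <- c(0.95047, 1, 1.08883)
  r <- sweep(xyz, 2, wp, "/")
  f <- ifelse(r > (6 / 29)^3, r^(1 / 3), r / (3 * (6 / 29)^2) + 4 / 29)
  cbind(116 * f[, 2] - 16, 500 * (f[, 1] - f[, 2]), 200 * (f[, 2] - f[, 3]))
}

# brute-force per-point silhouette
bf_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) next
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Calinski-Harabasz from scratch scatter matrices
bf_calinski_harabasz <- function(x, labels) {
  g <- colMeans(x)
  ids <- unique(labels)
  k <- length(ids)
  n <- nrow(x)
  tr_b <- 0
  tr_w <- 0
  for (cl in ids) {
    m <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(m)
    tr_b <- tr_b + nrow(m) * sum((mu - g)^2)
    for (r in seq_len(nrow(m))) tr_w <- tr_w + sum((m[r, ] - mu)^2)
  }
  (tr_b / (k - 1)) / (tr_w / (n - k))
}

# Davies-Bouldin by direct formula evaluation
bf_davies_bouldin <- function(x, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  cent <- t(sapply(ids, function(cl) colMeans(x[labels == cl, , drop = FALSE])))
  s <- sapply(seq_len(k), function(j) {
    m <- x[labels == ids[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, cent[j, ], "-")^2)))
  })
  r <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      mij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      best <- max(best, (s[i] + s[j]) / mij)
    }
    r[i] <- best
  }
  mean(r)
}

# classification metrics evaluated longhand from a confusion matrix
bf_metrics <- function(m) {
  acc <- sum(diag(m)) / sum(m)
  prec <- rec <- f1 <- numeric(6)
  for (cl in 1:6) {
    prec[cl] <- if (sum(m[, cl]) == 0) 0 else m[cl, cl] / sum(m[, cl])
    rec[cl] <- if (sum(m[cl, ]) == 0) 0 else m[cl, cl] / sum(m[cl, ])
    f1[cl] <- if (prec[cl] + rec[cl] == 0) 0 else
      2 * prec[cl] * rec[cl] / (prec[cl] + rec[cl])
  }
  present <- which(rowSums(m) > 0)
  list(accuracy = acc, precision = mean(prec[present]),
       recall = mean(rec[present]), f1 = mean(f1[present]))
}

# seeded Gaussian blob fixture: k far-separated blobs in LAB-like space
make_blobs <- function(n_per = 50, centers = rbind(c(60, 10, 15),
                                                   c(40, 14, 20)),
                       sigma = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(n_per * 3, sd = sigma), ncol = 3), 2,
          centers[j, ], "+")
  }))
  list(x = x, truth = rep(seq_len(k), each = n_per), centers = centers)
}

# nearest-true-centre assignment, the oracle partition for blob fixtures
oracle_assign <- function(x, centers) {
  apply(x, 1, function(p) {
    which.min(colSums((t(centers) - p)^2))
  })
}

# agreement of two labelings up to cluster renaming
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(!duplicated(unique(data.frame(a, b))$a)) &&
    nrow(unique(data.frame(a, b))) == length(unique(a))
}

# a two-region skin scene with known fractions
two_region_scene <- function(fst = c(3L, 4L), fractions = c(0.75, 0.25),
                             width = 160L, height = 120L, noise_sigma = 2,
                             seed = 11L, ...) {
  render_scene(
    scene_spec(tibble::tibble(fst = fst, fraction = fractions),
               width = width, height = height, noise_sigma = noise_sigma,
               seed = seed, ...),
    default_fst_palette())
}

# a small 6-swatch palette chart image in LAB
swatch_chart <- function(palette = default_fst_palette(), swatch = 12L,
                         noise_sigma = 0, seed = 1L) {
  set.seed(seed)
  pal <- as.matrix(palette[, c("L", "a", "b")])
  img <- array(0, dim = c(swatch, swatch * 6L, 3L))
  for (j in 1:6) {
    cols <- ((j - 1L) * swatch + 1L):(j * swatch)
    for (ch in 1:3) img[, cols, ch] <- pal[j, ch]
  }
  if (noise_sigma > 0) {
    img <- img + array(rnorm(length(img), sd = noise_sigma), dim = dim(img))
  }
  class(img) <- "lab_image"
  img
}

# closeness assertion with absolute tolerance near zero, relative otherwise
expect_close <- function(actual, expected, tol = 1e-9) {
  expect_lt(abs(actual - expected), tol * max(1, abs(expected)))
}
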