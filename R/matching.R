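# Cluster-to-palette matching, pixel fractions, dominant-tone classification
# and FST-labelled spatial maps. Matching always operates on cluster centres
# (never per-pixel Delta-E): each centre is compared against the six palette
# entries and takes the class of the nearest one.

#' Match cluster centres to FST palette entries by CIE76 distance
#'
#' Each LAB cluster centre is assigned the Fitzpatrick class of the nearest
#' palette entry (argmin over the six CIE76 distances). Exact ties are broken
#' toward the lighter (lower-numbered) class.
#'
#' @param centers `k x 3` LAB matrix of cluster centres.
#' @param palette An [fst_palette()].
#' @return A tibble with one row per centre: `cluster`, `fst`, `delta_e`.
#' @export
match_clusters <- function(centers, palette) {
  stopifnot(inherits(palette, "fst_palette"))
  centers <- to_lab_rows(centers)
  if (nrow(centers) < 1L) stop("no cluster centres to match", call. = FALSE)
  pal <- as.matrix(palette[, c("L", "a", "b")])
  d <- sqrt(dist2_to_centers(centers, pal))
  # palette rows are sorted by fst, so ties.method = "first" is the
  # lighter-class tie rule
  best <- max.col(-d, ties.method = "first")
  tibble::tibble(cluster = seq_len(nrow(centers)),
                 fst = palette$fst[best],
                 delta_e = d[cbind(seq_len(nrow(centers)), best)])
}

#' Pixel fraction of each cluster
#'
#' @param labels Integer labels in `1..k`.
#' @param k Number of clusters.
#' @return Numeric vector of length `k`; `fraction[j] = count(labels == j)/N`.
#'   Fractions sum to 1.
#' @export
cluster_fractions <- function(labels, k) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty label vector", call. = FALSE)
  if (any(labels < 1L | labels > k)) {
    stop("labels must lie in 1..k", call. = FALSE)
  }
  tabulate(labels, nbins = k) / length(labels)
}

#' Classify the dominant skin tone of a photograph
#'
#' The end-to-end pipeline: (optional skin mask) -> resize -> convert to
#' CIELAB -> cluster the pixel cloud -> match each cluster centre to the FST
#' palette by CIE76 -> pixel fractions -> dominant class. The dominant class
#' is the matched class of the largest-fraction cluster; if two clusters tie
#' on fraction the one with the smaller Delta-E wins, and a further tie goes
#' to the lighter class. Deterministic given `seed`.
#'
#' When no mask is supplied and a very dark cluster covers a substantial
#' share of the image (centre `L < 20` and fraction > 0.2), a warning
#' suggests masking: unmasked dark backgrounds can absorb a cluster.
#'
#' @param image An sRGB (`rgb_image`, 0--255) or LAB (`lab_image`) array.
#' @param palette An [fst_palette()]; default the packaged synthetic palette.
#' @param model,k,seed,params Passed to [fit_clusters()].
#' @param mask Optional logical `H x W` matrix marking skin pixels (`TRUE`)
#'   at the *input* resolution; it is resized alongside the image.
#' @param max_dim Resize bound applied before clustering.
#' @param image_id Identifier recorded in the report.
#' @return An object of class `fst_match`: per-cluster matches plus the
#'   dominant-class decision. Use [tidy()] for the per-cluster table and
#'   [glance()] for the one-row summary.
#' @export
classify_image <- function(image, palette = default_fst_palette(),
                           model = "kmeans", k = 4L, seed = 42L,
                           params = list(), mask = NULL, max_dim = 256L,
                           image_id = attr(image, "provenance") %||% "image") {
  lab <- if (inherits(image, "lab_image")) image else srgb_to_lab(image)
  lab_small <- resize_image(lab, max_dim)
  px <- image_to_pixels(lab_small)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(unclass(image))[1:2]))
    m_small <- resize_mask(mask, dim(unclass(lab_small))[1:2])
    if (!any(m_small)) {
      stop("mask excludes every pixel", call. = FALSE)
    }
    px <- px[as.vector(m_small), , drop = FALSE]
  }
  fit <- fit_clusters(px, model = model, k = k, seed = seed, params = params)
  matches <- match_clusters(fit$centers, palette)
  matches$fraction <- cluster_fractions(fit$labels, fit$k)
  dom <- dominant_class(matches)
  if (is.null(mask)) {
    dark <- matches$fraction > 0.2 & fit$centers[, 1] < 20
    if (any(dark)) {
      warning("a dark cluster (L < 20) covers ",
              round(100 * max(matches$fraction[dark])),
              "% of the image; consider supplying a skin mask to exclude ",
              "the background", call. = FALSE)
    }
  }
  structure(
    list(matches = matches, dominant_fst = dom, k = fit$k,
         model = model, seed = seed, image_id = image_id,
         centers = fit$centers, palette = palette, fit = fit),
    class = "fst_match"
  )
}

# largest fraction; ties -> smaller delta_e; further ties -> lighter class
dominant_class <- function(matches) {
  ord <- order(-matches$fraction, matches$delta_e, matches$fst)
  as.integer(matches$fst[ord[1L]])
}

#' Segment a photograph into FST-labelled regions
#'
#' Clusters the (resized) image and re-expresses every pixel's cluster label
#' as the Fitzpatrick class of its matched palette entry, yielding a spatial
#' map of skin-tone regions. The legend carries each cluster's class,
#' Delta-E and pixel fraction.
#'
#' @inheritParams classify_image
#' @param k Number of clusters, at least 2.
#' @return An object of class `fst_segmentation` with fields `label_raster`
#'   (`H x W` cluster ids), `fst_raster` (`H x W` classes 1..6), `legend`
#'   (tibble `cluster`, `fst`, `delta_e`, `fraction`), `palette` and
#'   `dominant_fst`. Rasters are at the post-resize resolution.
#' @export
segment_image <- function(image, palette = default_fst_palette(), k = 4L,
                          seed = 42L, model = "kmeans", params = list(),
                          max_dim = 256L) {
  if (k < 2L) stop("segmentation needs k >= 2", call. = FALSE)
  lab <- if (inherits(image, "lab_image")) image else srgb_to_lab(image)
  lab_small <- resize_image(lab, max_dim)
  hw <- dim(unclass(lab_small))[1:2]
  px <- image_to_pixels(lab_small)
  fit <- fit_clusters(px, model = model, k = k, seed = seed, params = params)
  legend <- match_clusters(fit$centers, palette)
  legend$fraction <- cluster_fractions(fit$labels, fit$k)
  label_raster <- matrix(fit$labels, nrow = hw[1], ncol = hw[2])
  fst_raster <- matrix(legend$fst[fit$labels], nrow = hw[1], ncol = hw[2])
  structure(
    list(label_raster = label_raster, fst_raster = fst_raster,
         legend = legend, palette = palette, k = fit$k,
         dominant_fst = dominant_class(legend), model = model, seed = seed),
    class = "fst_segmentation"
  )
}

#' Segment an image across several cluster counts
#'
#' Runs [segment_image()] for each `k` and aggregates cluster fractions by
#' matched FST class (clusters sharing a class pool their pixels), the
#' readout used to follow how the dominant tone's share evolves as the
#' segmentation is refined from coarse to fine.
#'
#' @inheritParams segment_image
#' @param ks Integer vector of cluster counts, all at least 2.
#' @return A tibble with one row per `(k, fst)` pair: `k`, `fst`,
#'   `fraction` (aggregated), `n_clusters` contributing, and `dominant`
#'   (logical, largest aggregated fraction at that `k`). The segmentation
#'   objects are attached as attribute `"segmentations"` (a named list).
#' @export
sweep_cluster_counts <- function(image, palette = default_fst_palette(),
                                 ks = c(2L, 3L, 4L), seed = 42L,
                                 model = "kmeans", params = list(),
                                 max_dim = 256L) {
  stopifnot(all(ks >= 2L))
  segs <- purrr::map(ks, function(k) {
    segment_image(image, palette, k = k, seed = seed, model = model,
                  params = params, max_dim = max_dim)
  })
  names(segs) <- paste0("k", ks)
  agg <- purrr::map2(ks, segs, function(k, seg) {
    seg$legend |>
      dplyr::group_by(.data$fst) |>
      dplyr::summarise(fraction = sum(.data$fraction),
                       n_clusters = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(k = k, .before = 1)
  })
  out <- dplyr::bind_rows(agg) |>
    dplyr::group_by(.data$k) |>
    dplyr::mutate(dominant = .data$fraction == max(.data$fraction)) |>
    dplyr::ungroup()
  attr(out, "segmentations") <- segs
  out
}

# nearest-neighbour resize for a logical mask
resize_mask <- function(mask, new_hw) {
  old <- dim(mask)
  if (all(old == new_hw)) return(mask)
  ri <- pmin(old[1], pmax(1L, round((seq_len(new_hw[1]) - 0.5) *
                                      old[1] / new_hw[1] + 0.5)))
  ci <- pmin(old[2], pmax(1L, round((seq_len(new_hw[2]) - 0.5) *
                                      old[2] / new_hw[2] + 0.5)))
  mask[ri, ci, drop = FALSE]
}

#' @export
print.fst_match <- function(x, ...) {
  cat("<fst_match> ", x$image_id, ": dominant FST ",
      as.character(as.roman(x$dominant_fst)), " (class ", x$dominant_fst, "), model ",
      x$model, ", k = ", x$k, "\n", sep = "")
  print(x$matches)
  invisible(x)
}

#' Per-cluster palette matches of a classification
#'
#' @param x An `fst_match` object.
#' @param ... Unused.
#' @return Tibble with columns `cluster`, `fst`, `delta_e`, `fraction`,
#'   `dominant`.
#' @method tidy fst_match
#' @export
tidy.fst_match <- function(x, ...) {
  dplyr::mutate(x$matches,
                dominant = seq_len(nrow(x$matches)) ==
                  order(-x$matches$fraction, x$matches$delta_e,
                        x$matches$fst)[1L])
}

#' One-row summary of a classification
#'
#' @param x An `fst_match` object.
#' @param ... Unused.
#' @return One-row tibble: `image_id`, `dominant_fst`, `k`, `model`,
#'   `seed`, `min_delta_e`, `dominant_fraction`.
#' @method glance fst_match
#' @export
glance.fst_match <- function(x, ...) {
  dom <- which(tidy(x)$dominant)
  tibble::tibble(image_id = x$image_id, dominant_fst = x$dominant_fst,
                 k = x$k, model = x$model, seed = x$seed,
                 min_delta_e = min(x$matches$delta_e),
                 dominant_fraction = x$matches$fraction[dom])
}

#' @export
print.fst_segmentation <- function(x, ...) {
  cat("<fst_segmentation> ", nrow(x$label_raster), "x",
      ncol(x$label_raster), " raster, k = ", x$k, ", dominant FST ",
      x$dominant_fst, "\n", sep = "")
  print(x$legend)
  invisible(x)
}

#' Legend of a segmentation map
#'
#' @param x An `fst_segmentation` object.
#' @param ... Unused.
#' @return The legend tibble (`cluster`, `fst`, `delta_e`, `fraction`).
#' @method tidy fst_segmentation
#' @export
tidy.fst_segmentation <- function(x, ...) x$legend

#' Render a segmentation as an sRGB overlay image
#'
#' Every pixel is painted with its matched palette colour, giving the
#' FST-class spatial map as a viewable image.
#'
#' @param x An `fst_segmentation` object.
#' @return An `H x W x 3` sRGB array in `[0, 255]`.
#' @export
segmentation_overlay <- function(x) {
  stopifnot(inherits(x, "fst_segmentation"))
  pal_lab <- as.matrix(x$palette[, c("L", "a", "b")])
  lab <- array(pal_lab[x$fst_raster, ], dim = c(dim(x$fst_raster), 3L))
  class(lab) <- "lab_image"
  lab_to_srgb(lab)
}
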