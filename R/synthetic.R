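# Seeded generator of skin-like test images with known FST structure.
# Scenes are vertical colour bands drawn from an FST palette (exact area
# fractions by construction), with an additive linear lightness gradient
# standing in for uneven illumination, iid Gaussian LAB sensor noise, and an
# optional near-black background band emulating a dark backdrop. Geometry is
# deliberately simple: the generator exists to give the pipeline inputs with
# exactly known region fractions and dominant class, not photorealism.

#' Specify a synthetic skin scene
#'
#' @param regions A data frame with columns `fst` (1..6) and `fraction`
#'   (fractions of the skin area, summing to 1); an optional `jitter` column
#'   gives a per-region random offset scale (Delta-E units) applied to the
#'   region's base colour. The first row is conventionally the dominant
#'   region.
#' @param width,height Image size in pixels.
#' @param lighting_gradient Amplitude (L units) of a linear top-to-bottom
#'   lightness ramp, from `-amplitude/2` to `+amplitude/2`.
#' @param noise_sigma Standard deviation of iid Gaussian noise added to each
#'   LAB channel.
#' @param background_fraction Fraction of image width rendered as a
#'   near-black background band on the left (0 for none).
#' @param seed Integer seed; rendering is deterministic given it.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(regions, width = 96L, height = 72L,
                       lighting_gradient = 0, noise_sigma = 2,
                       background_fraction = 0, seed = 1L) {
  regions <- tibble::as_tibble(as.data.frame(regions))
  stopifnot(all(c("fst", "fraction") %in% names(regions)))
  if (!"jitter" %in% names(regions)) regions$jitter <- 0
  if (any(regions$fst < 1 | regions$fst > 6)) {
    stop("region fst classes must lie in 1..6", call. = FALSE)
  }
  if (abs(sum(regions$fraction) - 1) > 1e-9) {
    stop("region fractions must sum to 1", call. = FALSE)
  }
  if (any(regions$fraction <= 0)) {
    stop("region fractions must be positive", call. = FALSE)
  }
  stopifnot(width >= 1, height >= 1,
            background_fraction >= 0, background_fraction < 1,
            noise_sigma >= 0)
  structure(list(regions = regions, width = as.integer(width),
                 height = as.integer(height),
                 lighting_gradient = lighting_gradient,
                 noise_sigma = noise_sigma,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a synthetic scene to an sRGB image with ground truth
#'
#' @param spec A [scene_spec()].
#' @param palette An [fst_palette()] supplying the region base colours.
#' @return A list: `image` (`rgb_image` array, 0--255), `truth` (`H x W`
#'   integer raster of FST classes, 0 = background), `truth_fractions`
#'   (named length-6 vector of skin-area fractions per class, from the
#'   rendered geometry), `dominant_fst`, and `spec`.
#' @export
render_scene <- function(spec, palette = default_fst_palette()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(palette, "fst_palette"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  h <- spec$height
  w <- spec$width
  bg_cols <- round(spec$background_fraction * w)
  skin_cols <- w - bg_cols
  if (skin_cols < nrow(spec$regions)) {
    stop("image too narrow for the requested regions", call. = FALSE)
  }
  edges <- round(cumsum(spec$regions$fraction) * skin_cols)
  widths <- diff(c(0L, edges))
  if (any(widths == 0L)) {
    stop("a region fraction rounds to zero columns at this width",
         call. = FALSE)
  }
  col_class <- c(rep(0L, bg_cols),
                 rep(spec$regions$fst, times = widths))
  pal_lab <- as.matrix(palette[, c("L", "a", "b")])
  base <- matrix(0, nrow = nrow(spec$regions), ncol = 3L)
  for (r in seq_len(nrow(spec$regions))) {
    base[r, ] <- pal_lab[spec$regions$fst[r], ] +
      stats::rnorm(3L, sd = spec$regions$jitter[r] / sqrt(3))
  }
  lab <- array(0, dim = c(h, w, 3L))
  col_region <- c(rep(0L, bg_cols), rep(seq_len(nrow(spec$regions)),
                                        times = widths))
  for (j in seq_len(w)) {
    lab[, j, ] <- matrix(
      if (col_region[j] == 0L) c(5, 0, 0) else base[col_region[j], ],
      nrow = h, ncol = 3L, byrow = TRUE)
  }
  if (spec$lighting_gradient != 0 && h > 1L) {
    ramp <- spec$lighting_gradient * ((seq_len(h) - 1) / (h - 1) - 0.5)
    lab[, , 1] <- lab[, , 1] + ramp
  }
  if (spec$noise_sigma > 0) {
    lab <- lab + array(stats::rnorm(length(lab), sd = spec$noise_sigma),
                       dim = dim(lab))
  }
  lab[, , 1] <- pmin(pmax(lab[, , 1], 0), 100)
  class(lab) <- "lab_image"
  truth <- matrix(rep(col_class, each = h), nrow = h, ncol = w)
  skin <- truth[truth > 0L]
  truth_fractions <- tabulate(skin, nbins = 6L) / length(skin)
  names(truth_fractions) <- 1:6
  list(image = lab_to_srgb(lab),
       truth = truth,
       truth_fractions = truth_fractions,
       dominant_fst = as.integer(which.max(truth_fractions)),
       spec = spec)
}

#' Generate a seeded cohort of synthetic skin images
#'
#' Produces `n` scenes whose dominant region's class is drawn from
#' `class_mix`. Half the scenes (in expectation) carry a secondary region of
#' an adjacent class covering 15--35% of the skin area, emulating natural
#' tone variation within one subject; the rest are single-region. Per-image
#' seeds are derived deterministically from the master seed, so the whole
#' cohort is reproducible.
#'
#' @param n Number of images.
#' @param class_mix Length-6 probability vector over FST I..VI (sums to 1).
#' @param noise_sigma Per-channel LAB noise level passed to every scene.
#' @param seed Master seed.
#' @param palette An [fst_palette()].
#' @param width,height Image size of every scene.
#' @param lighting_gradient Lightness ramp amplitude passed to every scene.
#' @param two_region_prob Probability that a scene has a secondary region.
#' @return A tibble with one row per image: `image_id`, `true_fst`
#'   (constructed dominant class), `scene` (list of [render_scene()]
#'   results) and `seed`.
#' @export
generate_cohort <- function(n = 48L, class_mix = rep(1 / 6, 6),
                            noise_sigma = 2, seed = 7L,
                            palette = default_fst_palette(),
                            width = 96L, height = 72L,
                            lighting_gradient = 3,
                            two_region_prob = 0.5) {
  stopifnot(n >= 1L)
  if (length(class_mix) != 6L || abs(sum(class_mix) - 1) > 1e-8 ||
      any(class_mix < 0)) {
    stop("class_mix must be 6 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  dominant <- sample.int(6L, n, replace = TRUE, prob = class_mix)
  two_region <- stats::runif(n) < two_region_prob
  dom_frac <- stats::runif(n, 0.65, 0.85)
  direction <- sample(c(-1L, 1L), n, replace = TRUE)
  image_seeds <- sample.int(.Machine$integer.max, n)
  scenes <- purrr::map(seq_len(n), function(i) {
    if (two_region[i]) {
      second <- dominant[i] + direction[i]
      if (second < 1L || second > 6L) second <- dominant[i] - direction[i]
      regions <- tibble::tibble(fst = c(dominant[i], second),
                                fraction = c(dom_frac[i], 1 - dom_frac[i]))
    } else {
      regions <- tibble::tibble(fst = dominant[i], fraction = 1)
    }
    render_scene(
      scene_spec(regions, width = width, height = height,
                 lighting_gradient = lighting_gradient,
                 noise_sigma = noise_sigma, seed = image_seeds[i]),
      palette)
  })
  tibble::tibble(
    image_id = sprintf("img%03d", seq_len(n)),
    true_fst = as.integer(dominant),
    scene = scenes,
    seed = image_seeds
  )
}
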