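#' Construct and validate an FST palette
#'
#' An FST palette is the six-colour reference table that skin cluster centres
#' are matched against: one CIELAB colour per Fitzpatrick class I (lightest)
#' through VI (darkest). Validation enforces exactly six entries, classes
#' 1..6 without duplicates, and strictly decreasing lightness `L` from class
#' I to class VI.
#'
#' @param colors A data frame with columns `fst` (integers 1..6) and `L`,
#'   `a`, `b`, or a 6 x 3 matrix of LAB rows ordered FST I..VI.
#' @param source Character tag recording where the palette came from
#'   (`"config"` or `"clustered_image"`).
#' @return A tibble of class `"fst_palette"` with columns
#'   `fst`, `L`, `a`, `b`, sorted by `fst`.
#' @export
fst_palette <- function(colors, source = "config") {
  if (is.matrix(colors)) {
    colors <- tibble::tibble(fst = seq_len(nrow(colors)),
                             L = colors[, 1], a = colors[, 2], b = colors[, 3])
  }
  colors <- tibble::as_tibble(colors)
  required <- c("fst", "L", "a", "b")
  if (!all(required %in% names(colors))) {
    stop("palette needs columns fst, L, a, b", call. = FALSE)
  }
  if (nrow(colors) != 6L) {
    stop("an FST palette must have exactly 6 entries, got ", nrow(colors),
         call. = FALSE)
  }
  if (!setequal(colors$fst, 1:6)) {
    stop("palette fst classes must be a permutation of 1..6", call. = FALSE)
  }
  colors <- dplyr::arrange(colors[required], .data$fst)
  if (any(diff(colors$L) >= 0)) {
    stop("palette L values must be strictly decreasing from FST I to VI",
         call. = FALSE)
  }
  structure(colors, class = c("fst_palette", class(colors)),
            source = source)
}

#' Load an FST palette from a JSON file
#'
#' The file holds `{"space": "lab"|"srgb", "colors": [{"fst": i, "lab": [L,a,b]}
#' x 6]}` (sRGB palettes use `"rgb": [R,G,B]` and are converted on load).
#'
#' @param path Path to the palette JSON file.
#' @return An [fst_palette()].
#' @export
load_palette <- function(path) {
  if (!file.exists(path)) stop("palette file not found: ", path, call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- tolower(spec$space %||% "lab")
  cols <- spec$colors
  key <- if (space == "srgb") "rgb" else "lab"
  if (is.null(cols) || !is.data.frame(cols) || is.null(cols[[key]])) {
    stop("palette JSON must contain colors[].fst and colors[].", key,
         call. = FALSE)
  }
  m <- do.call(rbind, cols[[key]])
  if (is.null(m) || ncol(m) != 3L) {
    stop("each palette colour must have 3 components", call. = FALSE)
  }
  if (space == "srgb") {
    m <- srgb_to_lab(m)
  } else if (space != "lab") {
    stop("palette space must be 'lab' or 'srgb'", call. = FALSE)
  }
  fst_palette(tibble::tibble(fst = as.integer(cols$fst),
                             L = m[, 1], a = m[, 2], b = m[, 3]),
              source = "config")
}

#' The packaged default FST palette
#'
#' A synthetic six-swatch reference palette shipped with the package: each
#' swatch sits at the midpoint of its class's ITA band (del Bino banding,
#' boundaries 55, 41, 28, 10, -30 degrees) with representative skin chroma.
#' It is a constructed stand-in, not a measured palette; replace it with
#' [load_palette()] or [palette_from_image()] when a measured reference is
#' available.
#'
#' @return An [fst_palette()].
#' @export
default_fst_palette <- function() {
  load_palette(system.file("extdata", "fst_palette_synthetic.json",
                           package = "skintone", mustWork = TRUE))
}

#' Derive an FST palette from a palette photograph
#'
#' Clusters the pixels of a photographed six-swatch FST reference chart with
#' k-means (k = 6) and orders the recovered centres by descending lightness
#' to obtain classes I..VI. Fails if the image does not contain six
#' distinguishable swatch colours (two centres closer than Delta-E 1).
#'
#' @param image An sRGB or LAB image array of the palette chart.
#' @param seed Integer seed for the k-means fit.
#' @param max_dim Resize bound applied before clustering.
#' @return An [fst_palette()] with `source = "clustered_image"`.
#' @export
palette_from_image <- function(image, seed = 42L, max_dim = 256L) {
  lab <- if (inherits(image, "lab_image")) image else srgb_to_lab(image)
  lab <- resize_image(lab, max_dim)
  px <- image_to_pixels(lab)
  fit <- kmeans_reference(px, k = 6L, seed = seed)
  centers <- fit$centers
  d <- as.matrix(stats::dist(centers))
  if (any(d[upper.tri(d)] < 1)) {
    stop("degenerate palette image: fewer than 6 distinct swatch colours ",
         "(two recovered centres are within Delta-E 1)", call. = FALSE)
  }
  ord <- order(centers[, 1], decreasing = TRUE)
  fst_palette(tibble::tibble(fst = 1:6,
                             L = centers[ord, 1],
                             a = centers[ord, 2],
                             b = centers[ord, 3]),
              source = "clustered_image")
}

#' Individual Typology Angle (ITA) of a CIELAB colour
#'
#' `ITA = atan2(L - 50, b) * 180 / pi`, in degrees. ITA is the standard
#' colorimetric measure of constitutive skin pigmentation: high angles are
#' light skin, low/negative angles dark skin. For skin colours (`b > 0`) the
#' result lies in (-90, 90).
#'
#' @param color A length-3 LAB vector, an `N x 3` LAB matrix, or a data frame
#'   with columns `L` and `b`.
#' @return Numeric vector of angles in degrees.
#' @examples
#' ita_degrees(c(60, 5, 10)) # 45
#' @export
ita_degrees <- function(color) {
  if (is.data.frame(color)) {
    L <- color$L
    b <- color$b
  } else {
    m <- to_lab_rows(color)
    L <- m[, 1]
    b <- m[, 3]
  }
  if (any(L == 50 & b == 0)) {
    stop("ITA is undefined at L = 50, b = 0", call. = FALSE)
  }
  atan2(L - 50, b) * 180 / pi
}

#' Default ITA class boundaries
#'
#' Five strictly decreasing angle cutoffs (degrees) partitioning the ITA axis
#' into the six FST classes, following the standard del Bino banding:
#' very light > 55, light (41, 55], intermediate (28, 41], tan (10, 28],
#' brown (-30, 10], dark <= -30.
#'
#' @return Numeric vector of 5 descending boundaries.
#' @export
ita_thresholds <- function() c(55, 41, 28, 10, -30)

#' Map ITA angles to FST classes
#'
#' A boundary value is assigned to the lighter (lower-numbered) class.
#'
#' @param ita Numeric vector of ITA angles in degrees.
#' @param thresholds Five strictly decreasing boundaries; see
#'   [ita_thresholds()].
#' @return Integer vector of FST classes in 1..6.
#' @export
ita_to_fst <- function(ita, thresholds = ita_thresholds()) {
  stopifnot(length(thresholds) == 5L, all(diff(thresholds) < 0))
  if (any(!is.finite(ita))) stop("ITA values must be finite", call. = FALSE)
  cls <- 1L + rowSums(outer(ita, thresholds, FUN = "<"))
  as.integer(cls)
}

#' @export
print.fst_palette <- function(x, ...) {
  cat("<fst_palette> source:", attr(x, "source", exact = TRUE) %||% "?", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
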