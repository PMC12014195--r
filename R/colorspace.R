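#' Convert an sRGB image or pixel matrix to CIELAB
#'
#' Pixels are interpreted as 8-bit sRGB (channel range 0--255) and converted
#' through linear RGB and XYZ (D65 white point, 2 degree standard observer)
#' to CIELAB with `L` on the 0--100 scale. This is the working colour space
#' for all clustering, palette matching and ITA computations in the package:
#' CIELAB is approximately perceptually uniform, so Euclidean distance (the
#' CIE76 colour difference) tracks visual similarity, and lightness is
#' separated from chroma, which makes the representation less sensitive to
#' illumination than raw RGB.
#'
#' @param image An `H x W x 3` numeric array with values in `[0, 255]`, or an
#'   `N x 3` matrix of sRGB rows.
#' @return An object of the same shape with columns/channels `(L, a, b)`.
#'   Arrays carry class `"lab_image"`.
#' @examples
#' srgb_to_lab(matrix(c(255, 255, 255), ncol = 3))
#' @export
srgb_to_lab <- function(image) {
  px <- as_pixel_matrix(image, n_channels = 3L)
  if (any(px < -1e-8) || any(px > 255 + 1e-8)) {
    stop("sRGB channel values must lie in [0, 255]", call. = FALSE)
  }
  lab <- farver::convert_colour(px, from = "rgb", to = "lab")
  colnames(lab) <- c("L", "a", "b")
  restore_shape(lab, image, class = "lab_image")
}

#' Convert a CIELAB image or pixel matrix to sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut colours are clipped to
#' `[0, 255]`; the round trip over in-gamut sRGB inputs is accurate to
#' within one 8-bit step per channel.
#'
#' @param image An `H x W x 3` numeric LAB array or `N x 3` LAB matrix.
#' @return sRGB values in `[0, 255]`, same shape as the input.
#' @export
lab_to_srgb <- function(image) {
  px <- as_pixel_matrix(image, n_channels = 3L)
  rgb <- farver::convert_colour(px, from = "lab", to = "rgb")
  rgb <- pmin(pmax(rgb, 0), 255)
  colnames(rgb) <- c("R", "G", "B")
  restore_shape(rgb, image, class = "rgb_image")
}

#' CIE76 colour difference
#'
#' The Euclidean distance between two CIELAB colours,
#' `sqrt((L1-L2)^2 + (a1-a2)^2 + (b1-b2)^2)`. This is the similarity measure
#' used to match skin cluster centres to the Fitzpatrick palette. Inputs are
#' recycled row-wise, so one argument may be a single colour and the other a
#' matrix of colours.
#'
#' @param c1,c2 Length-3 LAB vectors or `N x 3` LAB matrices.
#' @return A numeric vector of non-negative distances.
#' @examples
#' delta_e_cie76(c(50, 0, 0), c(53, 4, 0)) # 3-4-5 triangle: 5
#' @export
delta_e_cie76 <- function(c1, c2) {
  m1 <- to_lab_rows(c1)
  m2 <- to_lab_rows(c2)
  n <- max(nrow(m1), nrow(m2))
  if (nrow(m1) < n) m1 <- m1[rep_len(seq_len(nrow(m1)), n), , drop = FALSE]
  if (nrow(m2) < n) m2 <- m2[rep_len(seq_len(nrow(m2)), n), , drop = FALSE]
  sqrt(rowSums((m1 - m2)^2))
}

#' Downscale an image so that its largest side does not exceed `max_dim`
#'
#' Bilinear, aspect-preserving. Images whose largest side is already within
#' `max_dim` are returned unchanged. Downscaling before clustering keeps the
#' pixel cloud at desk scale without changing the colour composition: bilinear
#' interpolation locally averages colours, so region tones are preserved and
#' boundaries are not aliased.
#'
#' @param image An `H x W x 3` numeric array (LAB or sRGB).
#' @param max_dim Positive integer, the maximum allowed value of `max(H, W)`.
#' @return The (possibly) resized array, with the input's class retained.
#' @export
resize_image <- function(image, max_dim = 256L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L, max_dim >= 1)
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (max(h, w) <= max_dim) {
    return(image)
  }
  scale <- max_dim / max(h, w)
  new_h <- max(1L, round(h * scale))
  new_w <- max(1L, round(w * scale))
  out <- EBImage::resize(unclass(image), w = new_h, h = new_w,
                         filter = "bilinear")
  out <- array(as.numeric(out), dim = c(new_h, new_w, 3L))
  class(out) <- class(image)
  out
}

#' Read a PNG or JPEG photograph as an sRGB array
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An `H x W x 3` numeric array in `[0, 255]` with class `"rgb_image"`
#'   and the source file recorded in attribute `"provenance"`.
#' @export
read_skin_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (PNG and JPEG are supported)",
         call. = FALSE)
  )
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE] # drop alpha
  img <- raw * 255
  class(img) <- "rgb_image"
  attr(img, "provenance") <- path
  img
}

#' Write an sRGB array to a PNG file
#'
#' @param image An `H x W x 3` array in `[0, 255]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_skin_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  png::writePNG(pmin(pmax(unclass(image) / 255, 0), 1), target = path)
  invisible(path)
}

# -- internal shape helpers ---------------------------------------------------

# Accept H x W x C arrays, N x C matrices, or length-C vectors; return N x C.
as_pixel_matrix <- function(image, n_channels = 3L) {
  x <- unclass(image)
  if (is.null(dim(x))) {
    if (length(x) != n_channels) {
      stop("expected a length-", n_channels, " colour vector", call. = FALSE)
    }
    return(matrix(as.numeric(x), nrow = 1L))
  }
  d <- dim(x)
  if (length(d) == 2L) {
    if (d[2] != n_channels) {
      stop("expected ", n_channels, " colour channels, got ", d[2],
           call. = FALSE)
    }
    return(matrix(as.numeric(x), ncol = n_channels))
  }
  if (length(d) == 3L) {
    if (d[3] != n_channels) {
      stop("expected ", n_channels, " colour channels, got ", d[3],
           call. = FALSE)
    }
    return(matrix(as.numeric(x), ncol = n_channels))
  }
  stop("image must be a vector, matrix or 3-d array", call. = FALSE)
}

# Reshape an N x C matrix back to the shape of `template`.
restore_shape <- function(px, template, class = NULL) {
  t0 <- unclass(template)
  if (is.null(dim(t0))) {
    out <- drop(px)
  } else if (length(dim(t0)) == 2L) {
    out <- px
  } else {
    out <- array(px, dim = dim(t0))
  }
  if (!is.null(class) && !is.null(dim(t0)) && length(dim(t0)) == 3L) {
    class(out) <- class
  }
  attr(out, "provenance") <- attr(template, "provenance", exact = TRUE)
  out
}

to_lab_rows <- function(x) {
  x <- unclass(x)
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  else matrix(as.numeric(x), ncol = 3L)
}

# Flatten an image array into an N x 3 pixel matrix, remembering H/W.
image_to_pixels <- function(image) {
  px <- as_pixel_matrix(image, 3L)
  colnames(px) <- if (inherits(image, "rgb_image")) c("R", "G", "B")
                  else c("L", "a", "b")
  attr(px, "origin_shape") <- dim(unclass(image))[1:2]
  px
}
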