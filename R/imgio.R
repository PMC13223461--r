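# Image I/O, color-space conversions, and lighting augmentation.
#
# An RGB image is an integer h x w x 3 array in [0, 255] (sRGB, origin
# top-left). Conversions return double arrays of the same h x w extent.

assert_image_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an h x w x 3 array", arg), call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("`%s` has zero extent", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must have channel values in [0, 255]", arg),
         call. = FALSE)
  invisible(img)
}

#' Read an 8-bit RGB image
#'
#' Reads a PNG (or, when \pkg{EBImage} is installed, a JPEG) into an integer
#' `h x w x 3` array with values in `[0, 255]`. An alpha channel is dropped;
#' grayscale images are replicated across the three channels.
#'
#' @param path Path to the image file.
#' @return Integer `h x w x 3` array.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG input requires the EBImage package", call. = FALSE)
    x <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(x)) == 3L) x <- aperm(x, c(2, 1, 3)) else x <- t(x)
  } else {
    x <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop("not a decodable PNG: ", path, call. = FALSE))
  }
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 3L))     # grayscale
  if (dim(x)[3] >= 4L) x <- x[, , 1:3, drop = FALSE]         # drop alpha
  if (dim(x)[3] == 2L) x <- array(x[, , 1L], c(dim(x)[1:2], 3L))
  clip8(x * 255)
}

#' Write an RGB image as a lossless PNG
#'
#' `read_image(write_image(img, path))` is the identity on pixels.
#'
#' @param img Integer `h x w x 3` array in `[0, 255]`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image_rgb(img)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("directory does not exist: ", dir, call. = FALSE)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# Canonical sRGB -> XYZ (D65) -> CIELAB on an n x 3 matrix scaled [0, 255].
srgb_to_lab_mat <- function(m) {
  x <- m / 255
  lin <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- sweep(lin %*% t(M), 2, c(0.95047, 1, 1.08883), "/")
  d <- 6 / 29
  f <- ifelse(xyz > d^3, xyz^(1 / 3), xyz / (3 * d^2) + 4 / 29)
  out <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  colnames(out) <- c("L", "a", "b")
  out
}

lab_to_srgb_mat <- function(lab) {
  d <- 6 / 29
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(t) ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx) * 0.95047, finv(fy), finv(fz) * 1.08883)
  Minv <- matrix(c( 3.2404542, -1.5371385, -0.4985314,
                   -0.9692660,  1.8760108,  0.0415560,
                    0.0556434, -0.2040259,  1.0572252), 3, 3, byrow = TRUE)
  lin <- xyz %*% t(Minv)
  lin[lin < 0] <- 0; lin[lin > 1] <- 1
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055) * 255
}

#' Convert an sRGB image to CIELAB
#'
#' Per-pixel sRGB -> linear RGB -> XYZ (D65 white point) -> CIELAB with the
#' canonical IEC 61966-2-1 constants. `L*` lies in `[0, 100]`; `a*` encodes
#' green-red and `b*` blue-yellow opponency. The conjunctiva segmentation
#' clusters pixels in the (`a*`, `b*`) plane, where redness lives.
#'
#' @param img Integer `h x w x 3` RGB array in `[0, 255]`.
#' @return Double `h x w x 3` array with slices `L*`, `a*`, `b*`.
#' @export
rgb_to_lab <- function(img) {
  assert_image_rgb(img)
  dm <- dim(img)
  lab <- srgb_to_lab_mat(matrix(as.numeric(img), ncol = 3L))
  array(lab, dm, dimnames = list(NULL, NULL, c("L", "a", "b")))
}

#' Convert a CIELAB image back to 8-bit sRGB
#'
#' Inverse of [rgb_to_lab()] up to 8-bit quantization (per-channel error
#' at most 1 after a round trip).
#'
#' @param lab Double `h x w x 3` CIELAB array.
#' @return Integer `h x w x 3` RGB array in `[0, 255]`.
#' @export
lab_to_rgb <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    stop("`lab` must be an h x w x 3 array", call. = FALSE)
  dm <- dim(lab)
  rgb <- lab_to_srgb_mat(matrix(as.numeric(lab), ncol = 3L))
  array(clip8(rgb), dm)
}

# HSI transform on an n x 3 RGB matrix in [0, 255]. Gonzalez-Woods arccos
# formulation; H in degrees [0, 360), S in [0, 1], I in [0, 1]; H = 0
# whenever S = 0 (achromatic convention).
rgb_to_hsi_mat <- function(m) {
  R <- m[, 1]; G <- m[, 2]; B <- m[, 3]
  s <- R + G + B
  I <- s / (3 * 255)
  S <- ifelse(s == 0, 0, 1 - 3 * pmin(R, G, B) / s)
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  cosx <- ifelse(den == 0, 1, pmax(-1, pmin(1, num / den)))
  theta <- acos(cosx) * 180 / pi
  H <- ifelse(B > G, 360 - theta, theta)
  H <- ifelse(S == 0, 0, H)
  H[H >= 360] <- 0
  cbind(H = H, S = S, I = I)
}

#' Convert an sRGB image to HSI
#'
#' Hue/saturation/intensity with the arccos hue formulation:
#' `I = (R+G+B)/(3*255)`, `S = 1 - 3*min(R,G,B)/(R+G+B)` (0 on black), and
#' `H = theta` or `360 - theta` when `B > G`, with `H = 0` for achromatic
#' pixels. Hue is in degrees, red at 0; the high-hue ratio feature counts
#' pixels in the red-magenta band adjoining 360.
#'
#' @param img Integer `h x w x 3` RGB array in `[0, 255]`.
#' @return Double `h x w x 3` array with slices `H`, `S`, `I`.
#' @export
rgb_to_hsi <- function(img) {
  assert_image_rgb(img)
  dm <- dim(img)
  hsi <- rgb_to_hsi_mat(matrix(as.numeric(img), ncol = 3L))
  array(hsi, dm, dimnames = list(NULL, NULL, c("H", "S", "I")))
}

#' The six lighting presets
#'
#' Diagonal (von Kries) channel gains emulating capture under six lighting
#' conditions: tungsten, cloudy, daylight, flash, fluorescent and shade.
#' Daylight is the identity `(1, 1, 1)`; the others are plausible
#' correlated-color-temperature shifts and can be overridden through
#' `config` (a named list of 3-vectors, e.g. from a YAML file).
#'
#' @param config Optional named list overriding or extending the defaults.
#' @return Named list of numeric `(gR, gG, gB)` gain vectors.
#' @export
lighting_presets <- function(config = NULL) {
  presets <- list(
    tungsten    = c(1.15, 1.00, 0.80),
    cloudy      = c(0.95, 1.00, 1.08),
    daylight    = c(1.00, 1.00, 1.00),
    flash       = c(1.05, 1.00, 1.02),
    fluorescent = c(0.95, 1.05, 1.00),
    shade       = c(0.90, 1.00, 1.12)
  )
  if (!is.null(config)) {
    for (nm in names(config)) {
      g <- as.numeric(config[[nm]])
      if (length(g) != 3L || any(!is.finite(g)) || any(g <= 0))
        stop("preset gains must be 3 positive numbers: ", nm, call. = FALSE)
      presets[[nm]] <- g
    }
  }
  presets
}

#' Apply a white-balance lighting preset
#'
#' Multiplies each channel by its preset gain, rounds half-up and clips to
#' `[0, 255]`. The daylight preset is the identity.
#'
#' @param img Integer `h x w x 3` RGB array.
#' @param preset A preset name (see [lighting_presets()]) or a numeric
#'   3-vector of gains.
#' @param presets Preset table to look names up in.
#' @return Integer `h x w x 3` RGB array.
#' @export
apply_white_balance <- function(img, preset, presets = lighting_presets()) {
  assert_image_rgb(img)
  if (is.character(preset)) {
    if (!preset %in% names(presets))
      stop("unknown lighting preset: ", preset, call. = FALSE)
    gains <- presets[[preset]]
  } else {
    gains <- as.numeric(preset)
    if (length(gains) != 3L || any(!is.finite(gains)) || any(gains <= 0))
      stop("gains must be 3 positive numbers", call. = FALSE)
  }
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch] * gains[ch]
  clip8(out)
}

#' Expand a dataset manifest across lighting presets
#'
#' Produces one record per (source image, preset) pair: the augmented set
#' replaces the originals, the daylight record reproducing the source image
#' exactly. Class labels and subject metadata are inherited. With `dir`
#' set, the white-balanced images are also materialized as PNGs named
#' `<stem>_<preset>.png`.
#'
#' @param manifest Data frame with at least an `image_path` column
#'   (see [generate_dataset()] for the full schema).
#' @param presets Named list of gain vectors, as from [lighting_presets()].
#' @param dir Optional output directory for the transformed images.
#' @return Data frame with `nrow(manifest) * length(presets)` rows and a
#'   `lighting` column naming the preset of each record.
#' @export
augment_dataset <- function(manifest, presets = lighting_presets(),
                            dir = NULL) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("`manifest` must be a non-empty data frame", call. = FALSE)
  if (length(presets) == 0L)
    stop("`presets` must be non-empty", call. = FALSE)
  if (is.null(names(presets)) || any(names(presets) == ""))
    stop("`presets` must be a named list", call. = FALSE)
  out <- vector("list", length(presets))
  for (i in seq_along(presets)) {
    nm <- names(presets)[i]
    rec <- manifest
    rec$lighting <- nm
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      newpath <- character(nrow(rec))
      for (r in seq_len(nrow(rec))) {
        img <- read_image(manifest$image_path[r])
        stem <- tools::file_path_sans_ext(basename(manifest$image_path[r]))
        newpath[r] <- file.path(dir, paste0(stem, "_", nm, ".png"))
        write_image(apply_white_balance(img, presets[[i]]), newpath[r])
      }
      rec$image_path <- newpath
    }
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
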