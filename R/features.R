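# Seven statistical and color features of a segmented conjunctiva region.
#
# A "region" is the integer N x 3 RGB matrix produced by apply_mask().
# Grayscale intensity is (R + G + B) / 3, consistent with the HSI intensity
# channel. All features are invariant under pixel permutation.

as_region <- function(region) {
  region <- as.matrix(region)
  if (ncol(region) != 3L || nrow(region) < 1L)
    stop("empty region: features need at least one pixel", call. = FALSE)
  if (anyNA(region) || min(region) < 0 || max(region) > 255)
    stop("region values must lie in [0, 255]", call. = FALSE)
  region
}

region_intensity <- function(region) rowMeans(region)

#' Mean intensity of a region
#'
#' Average grayscale intensity `(R + G + B) / 3` over the region, in
#' `[0, 255]`. Pale (anemic) conjunctivae are brighter.
#'
#' @param region Integer `N x 3` RGB matrix from [apply_mask()].
#' @return Scalar in `[0, 255]`.
#' @export
mean_intensity <- function(region) {
  mean(region_intensity(as_region(region)))
}

#' Ratio of mean red to mean green channel
#'
#' `mean(R) / mean(G)`; a redness measure that is large for well-perfused
#' conjunctivae and approaches 1 for pale ones.
#'
#' @inheritParams mean_intensity
#' @param eps Guard on the mean green channel below which the ratio is
#'   considered degenerate.
#' @return Positive scalar.
#' @export
mean_rg_ratio <- function(region, eps = 1e-6) {
  region <- as_region(region)
  g <- mean(region[, 2])
  if (g <= eps)
    stop("degenerate green channel: mean(G) <= eps", call. = FALSE)
  mean(region[, 1]) / g
}

#' Difference of mean red and mean green channel
#'
#' `mean(R) - mean(G)`, in `[-255, 255]`.
#'
#' @inheritParams mean_intensity
#' @return Scalar in `[-255, 255]`.
#' @export
mean_rg_difference <- function(region) {
  region <- as_region(region)
  mean(region[, 1]) - mean(region[, 2])
}

#' Standard deviation of region intensity
#'
#' Population (divisor `N`) standard deviation of the grayscale intensity,
#' capturing brightness homogeneity of the region.
#'
#' @inheritParams mean_intensity
#' @return Scalar in `[0, 127.5]`.
#' @export
std_intensity <- function(region) {
  x <- region_intensity(as_region(region))
  sqrt(mean((x - mean(x))^2))
}

#' Shannon entropy of the intensity histogram
#'
#' Entropy `-sum p_i log2 p_i` of the 256-bin histogram of rounded
#' grayscale intensity, in bits (`0 * log 0 = 0`). Ranges over `[0, 8]`;
#' low entropy indicates a uniform, texture-poor region.
#'
#' @inheritParams mean_intensity
#' @return Scalar in `[0, 8]` (bits).
#' @export
intensity_entropy <- function(region) {
  x <- floor(region_intensity(as_region(region)) + 0.5)
  p <- tabulate(as.integer(x) + 1L, nbins = 256L)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' High-hue ratio (HHR)
#'
#' Fraction of region pixels whose HSI hue lies at or above `tau_h`
#' degrees — the red-magenta band adjoining the 360/0 red axis — among all
#' region pixels. Achromatic pixels (S = 0) have hue 0 by convention and
#' never count. A redness proxy that decreases with pallor.
#'
#' @inheritParams mean_intensity
#' @param tau_h Hue threshold in degrees defining "high" hue.
#' @return Scalar in `[0, 1]`.
#' @export
high_hue_ratio <- function(region, tau_h = 300) {
  region <- as_region(region)
  hsi <- rgb_to_hsi_mat(region)
  mean(hsi[, "S"] > 0 & hsi[, "H"] >= tau_h)
}

#' Red pixel percentage
#'
#' Fraction of region pixels classed as red: red strictly dominates both
#' other channels and exceeds the larger of them by at least `delta` 8-bit
#' levels. Reported as a fraction in `[0, 1]`.
#'
#' @inheritParams mean_intensity
#' @param delta Dominance margin on the 8-bit scale.
#' @return Scalar in `[0, 1]`.
#' @export
red_pixel_percentage <- function(region, delta = 20) {
  region <- as_region(region)
  other <- pmax(region[, 2], region[, 3])
  mean(region[, 1] > region[, 2] & region[, 1] > region[, 3] &
         (region[, 1] - other) >= delta)
}

#' Extract the seven-feature vector of a segmented conjunctiva
#'
#' Computes all seven features on the pixels of `img` selected by `mask`:
#' mean intensity, red/green ratio, red-green difference, intensity
#' standard deviation, histogram entropy (bits), high-hue ratio and red
#' pixel percentage. Deterministic; regions smaller than `min_pixels` are
#' rejected rather than silently imputed.
#'
#' @param img Integer `h x w x 3` RGB array.
#' @param mask Logical `h x w` conjunctiva mask.
#' @param tau_h Hue threshold for [high_hue_ratio()].
#' @param delta Red-dominance margin for [red_pixel_percentage()].
#' @param min_pixels Minimum region size in pixels.
#' @return Named numeric vector with elements `mean_intensity`,
#'   `rg_ratio`, `rg_diff`, `std_intensity`, `entropy_bits`,
#'   `high_hue_ratio`, `red_pixel_pct`.
#' @export
extract_feature_vector <- function(img, mask, tau_h = 300, delta = 20,
                                   min_pixels = 50L) {
  region <- apply_mask(img, mask)
  if (nrow(region) < min_pixels)
    stop(sprintf("region too small: %d < %d pixels", nrow(region),
                 min_pixels), call. = FALSE)
  c(mean_intensity = mean_intensity(region),
    rg_ratio       = mean_rg_ratio(region),
    rg_diff        = mean_rg_difference(region),
    std_intensity  = std_intensity(region),
    entropy_bits   = intensity_entropy(region),
    high_hue_ratio = high_hue_ratio(region, tau_h = tau_h),
    red_pixel_pct  = red_pixel_percentage(region, delta = delta))
}

feature_names <- function() {
  c("mean_intensity", "rg_ratio", "rg_diff", "std_intensity",
    "entropy_bits", "high_hue_ratio", "red_pixel_pct")
}

#' Run segmentation and feature extraction over a dataset manifest
#'
#' For each manifest row, reads the image, segments the conjunctiva
#' (K-means pipeline, or the ground-truth/external mask in `mask_path` when
#' `use_masks = TRUE`) and extracts the seven-feature vector.
#'
#' @param manifest Data frame with columns `image_path`, `label` and,
#'   optionally, `mask_path`.
#' @param k Clusters for [kmeans_ab()].
#' @param seed Integer seed; each image gets an independent sub-seed.
#' @param use_masks Use `mask_path` masks instead of K-means segmentation.
#' @param ... Passed to [extract_feature_vector()].
#' @return Data frame: `image_path`, `label`, the seven feature columns.
#' @export
extract_dataset_features <- function(manifest, k = 3L, seed = 1L,
                                     use_masks = FALSE, ...) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("`manifest` must be a non-empty data frame", call. = FALSE)
  seeds <- derive_seeds(seed, nrow(manifest))
  feats <- matrix(NA_real_, nrow(manifest), 7L,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(manifest$image_path[i])
    if (use_masks) {
      mask <- load_external_mask(manifest$mask_path[i], img)
    } else {
      mask <- segment_conjunctiva(img, k = k, seed = seeds[i])$mask
    }
    feats[i, ] <- extract_feature_vector(img, mask, ...)
  }
  out <- data.frame(image_path = manifest$image_path,
                    label = manifest$label, feats,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
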