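# Synthetic eye-image generator.
#
# Renders simplified everted-lower-lid photographs: skin background, pale
# sclera ellipse, and a lower conjunctival crescent colored by class, with
# per-pixel Gaussian noise and a mild vertical illumination gradient. The
# exact conjunctiva mask is returned as ground truth. Class color means
# are calibrated in CIELAB so that (a) the conjunctiva centroid is the
# reddest cluster under all six lighting presets and (b) the red-pixel
# percentage and high-hue ratio decrease strictly from normal through
# moderate to anemic, the qualitative pallor ordering.

#' Specification of the synthetic dataset
#'
#' Defaults emulate the study conditions: 132 anemic / 169 moderately
#' anemic / 310 normal images (611 total), a 24:30 male:female ratio,
#' 256 x 256 images, and hemoglobin drawn uniformly within each class's
#' gradation interval per sex (anemic floor 6.0 g/dL; normal ceilings
#' 17.5 / 15.5 g/dL for males / females).
#'
#' @param n_per_class Named counts for `anemic`, `moderate`, `normal`.
#' @param image_size `(height, width)` in pixels.
#' @param class_colors Named list of mean conjunctiva RGB per class.
#' @param skin_color,sclera_color Background region mean RGB.
#' @param noise_sd Per-pixel Gaussian channel noise (8-bit levels).
#' @param gradient Peak-to-peak relative amplitude of the vertical
#'   illumination gradient.
#' @param male_fraction Probability a synthetic subject is male.
#' @param lighting `"daylight"` (no augmentation), another preset name, or
#'   `"all"` for all six presets.
#' @param mask_area_bounds Acceptable ground-truth mask area as a fraction
#'   of the image.
#' @param images_per_subject Images sharing one subject's sex and Hb.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(anemic = 132L, moderate = 169L,
                                           normal = 310L),
                           image_size = c(256L, 256L),
                           class_colors = list(
                             normal   = c(190, 60, 70),
                             moderate = c(195, 152, 155),
                             anemic   = c(205, 172, 164)),
                           skin_color = c(198, 192, 146),
                           sclera_color = c(222, 238, 252),
                           noise_sd = 8,
                           gradient = 0.12,
                           male_fraction = 24 / 54,
                           lighting = "daylight",
                           mask_area_bounds = c(0.03, 0.15),
                           images_per_subject = 1L) {
  if (any(n_per_class < 0L))
    stop("class counts must be nonnegative", call. = FALSE)
  if (!all(hb_classes() %in% names(n_per_class)))
    stop("`n_per_class` must name anemic, moderate and normal",
         call. = FALSE)
  stopifnot(all(unlist(class_colors) >= 0), all(unlist(class_colors) <= 255),
            length(image_size) == 2L, all(image_size >= 64L))
  structure(list(
    n_per_class = n_per_class, image_size = as.integer(image_size),
    class_colors = class_colors, skin_color = skin_color,
    sclera_color = sclera_color, noise_sd = noise_sd,
    gradient = gradient, male_fraction = male_fraction,
    lighting = lighting, mask_area_bounds = mask_area_bounds,
    images_per_subject = as.integer(images_per_subject)
  ), class = "synthetic_spec")
}

#' Render one synthetic eye image with its ground-truth mask
#'
#' Deterministic given `seed`: the same seed yields a bit-identical image
#' and mask. Geometry (eye center, axes) is jittered per image; the
#' conjunctival crescent is the part of a lower ellipse below the lid
#' line. An error is raised if the jittered geometry produces a mask
#' outside the configured area bounds.
#'
#' @param class_label `"anemic"`, `"moderate"` or `"normal"`.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `image` (integer `h x w x 3`) and `mask` (logical
#'   `h x w` ground-truth conjunctiva mask).
#' @export
render_eye_image <- function(class_label, spec = synthetic_spec(),
                             seed = 1L) {
  class_label <- match.arg(class_label, hb_classes())
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(seed, {
    # jittered geometry, scaled to the image size; macro framing: the eye
    # fills most of the frame, skin is a border
    cx <- w / 2 + runif(1, -0.03, 0.03) * w
    sc_cy <- 0.38 * h + runif(1, -0.02, 0.02) * h
    sc_a <- 0.46 * w * runif(1, 0.94, 1.06)
    sc_b <- 0.26 * h * runif(1, 0.94, 1.06)
    cj_cy <- 0.68 * h + runif(1, -0.015, 0.015) * h
    cj_a <- 0.40 * w * runif(1, 0.94, 1.06)
    cj_b <- 0.10 * h * runif(1, 0.94, 1.06)
    lid <- cj_cy - 0.035 * h

    row <- matrix(seq_len(h), h, w)
    col <- matrix(seq_len(w), h, w, byrow = TRUE)
    in_sclera <- ((col - cx) / sc_a)^2 + ((row - sc_cy) / sc_b)^2 <= 1
    in_conj <- (((col - cx) / cj_a)^2 + ((row - cj_cy) / cj_b)^2 <= 1) &
      row >= lid
    region <- matrix(1L, h, w)           # 1 skin, 2 sclera, 3 conjunctiva
    region[in_sclera] <- 2L
    region[in_conj] <- 3L
    mask <- region == 3L

    area <- mean(mask)
    if (area < spec$mask_area_bounds[1] || area > spec$mask_area_bounds[2])
      stop(sprintf(
        "degenerate geometry: mask area %.3f outside [%.3f, %.3f]",
        area, spec$mask_area_bounds[1], spec$mask_area_bounds[2]),
        call. = FALSE)

    means <- rbind(spec$skin_color, spec$sclera_color,
                   spec$class_colors[[class_label]])
    shade <- 1 + spec$gradient * (row / h - 0.5)   # darker top, brighter bottom
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      base <- matrix(means[region, ch], h, w)
      img[, , ch] <- base * shade + rnorm(h * w, sd = spec$noise_sd)
    }
    list(image = clip8(img), mask = mask)
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Emits `n_per_class` images per class with hemoglobin sampled uniformly
#' within the class-and-sex gradation interval (so `label_from_hb()`
#' re-derives every label exactly), ground-truth masks, and a
#' `manifest.csv` with columns `image_path, mask_path, subject_id, sex,
#' hb_g_dl, label, lighting`. With `spec$lighting == "all"` the manifest
#' is expanded across all six presets and the white-balanced images are
#' materialized. Fully reproducible from `(spec, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param write_images Set `FALSE` to emit only the manifest (fast paths
#'   for record arithmetic; `image_path` then points at not-yet-written
#'   files).
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = tempfile("synth"),
                             seed = 1L, write_images = TRUE) {
  n_tot <- sum(spec$n_per_class[hb_classes()])
  if (n_tot < 1L) stop("empty dataset requested", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (write_images) {
    for (d in file.path(dir, c("images", "masks")))
      if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }

  labels <- rep(hb_classes(), times = spec$n_per_class[hb_classes()])
  n_subj <- ceiling(n_tot / spec$images_per_subject)
  seeds <- derive_seeds(seed, n_tot + 2L)
  intervals <- hb_intervals()

  # subjects: sex and Hb drawn once, shared across a subject's images
  subj_of <- rep(seq_len(n_subj), each = spec$images_per_subject,
                 length.out = n_tot)
  sex <- hb <- character(n_tot); hbv <- numeric(n_tot)
  with_seed(seeds[n_tot + 1L], {
    subj_sex <- ifelse(runif(n_subj) < spec$male_fraction, "male", "female")
    for (i in seq_len(n_tot)) {
      s <- subj_sex[subj_of[i]]
      first <- which(subj_of == subj_of[i] & labels == labels[i])[1]
      if (first == i || spec$images_per_subject == 1L) {
        rng <- intervals[[labels[i]]][[s]]
        # keep strictly inside open ends so the label re-derives exactly
        v <- runif(1, rng[1], rng[2])
        if (labels[i] == "anemic") v <- min(v, rng[2] - 1e-6)
        if (labels[i] == "normal") v <- max(v, rng[1] + 1e-6)
        hbv[i] <- v
      } else {
        hbv[i] <- hbv[first]
      }
      sex[i] <- s
    }
  })
  stopifnot(all(as.character(label_from_hb(sex, hbv)) == labels))

  stem <- sprintf("%04d_%s", seq_len(n_tot), labels)
  manifest <- data.frame(
    image_path = file.path(dir, "images", paste0(stem, ".png")),
    mask_path = file.path(dir, "masks", paste0(stem, ".png")),
    subject_id = sprintf("S%03d", subj_of),
    sex = sex, hb_g_dl = hbv, label = labels,
    lighting = "daylight", stringsAsFactors = FALSE
  )

  if (write_images) {
    for (i in seq_len(n_tot)) {
      r <- render_eye_image(labels[i], spec, seed = seeds[i])
      write_image(r$image, manifest$image_path[i])
      png::writePNG(r$mask * 1, target = manifest$mask_path[i])
    }
  }

  if (identical(spec$lighting, "all")) {
    manifest <- augment_dataset(
      manifest, lighting_presets(),
      dir = if (write_images) file.path(dir, "images") else NULL)
  } else if (!identical(spec$lighting, "daylight")) {
    presets <- lighting_presets()[spec$lighting]
    manifest <- augment_dataset(
      manifest, presets,
      dir = if (write_images) file.path(dir, "images") else NULL)
  }

  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
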