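# Conjunctiva localization and segmentation.
#
# Bounding boxes are 0-based, half-open [min, max) in pixel coordinates,
# x along columns and y along rows, matching the on-disk CSV convention.

assert_bbox <- function(box, width, height) {
  box <- as.integer(box[c("x_min", "y_min", "x_max", "y_max")])
  if (anyNA(box)) stop("box must have x_min, y_min, x_max, y_max",
                       call. = FALSE)
  if (box[1] < 0L || box[2] < 0L || box[1] >= box[3] || box[2] >= box[4] ||
      box[3] > width || box[4] > height)
    stop("bounding box outside image bounds", call. = FALSE)
  names(box) <- c("x_min", "y_min", "x_max", "y_max")
  box
}

#' Baseline conjunctiva ROI detector (redness prior)
#'
#' Stand-in for a learned detector: converts to CIELAB and returns the tight
#' bounding box of pixels whose `a*` (green-red axis) lies strictly above
#' the image's 80th percentile, padded by `margin` pixels and clipped to the
#' image bounds. Any external detector can replace this by supplying boxes
#' in the same 0-based half-open format.
#'
#' @param img Integer `h x w x 3` RGB array.
#' @param margin Padding in pixels added on every side before clipping.
#' @param prob Percentile of `a*` defining the redness threshold.
#' @param lab Optional precomputed CIELAB array for `img`.
#' @return Named integer vector `(x_min, y_min, x_max, y_max)`, 0-based,
#'   half-open.
#' @export
detect_roi_baseline <- function(img, margin = 6L, prob = 0.8, lab = NULL) {
  assert_image_rgb(img)
  if (is.null(lab)) lab <- rgb_to_lab(img)
  a <- lab[, , 2]
  thr <- stats::quantile(a, prob, names = FALSE)
  sel <- which(a > thr, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    stop("ROI detection failed: no pixel exceeds the redness prior",
         call. = FALSE)
  h <- dim(img)[1]; w <- dim(img)[2]
  box <- c(
    x_min = max(0L, min(sel[, 2]) - 1L - as.integer(margin)),
    y_min = max(0L, min(sel[, 1]) - 1L - as.integer(margin)),
    x_max = min(w, max(sel[, 2]) + as.integer(margin)),
    y_max = min(h, max(sel[, 1]) + as.integer(margin))
  )
  box
}

#' Crop an image to a bounding box
#'
#' @param img Integer `h x w x 3` RGB array.
#' @param box Named vector `(x_min, y_min, x_max, y_max)`, 0-based,
#'   half-open.
#' @return The `(y_max - y_min) x (x_max - x_min) x 3` sub-image.
#' @export
crop_image <- function(img, box) {
  assert_image_rgb(img)
  box <- assert_bbox(box, dim(img)[2], dim(img)[1])
  img[(box["y_min"] + 1L):box["y_max"],
      (box["x_min"] + 1L):box["x_max"], , drop = FALSE]
}

#' K-means clustering in the (a*, b*) chromaticity plane
#'
#' Lloyd's algorithm on the per-pixel `(a*, b*)` pairs of a CIELAB image,
#' with k-means++ initialization from `seed`. Lightness `L*` is excluded:
#' the chromatic plane carries the color information that separates
#' conjunctiva, sclera and skin. Iterates to an assignment fixed point (or
#' `max_iter` sweeps); an emptied cluster is re-seeded to the pixel farthest
#' from its assigned centroid. The same seed yields a bit-identical model.
#'
#' @param img_lab Double `h x w x 3` CIELAB array from [rgb_to_lab()].
#' @param k Number of clusters (the screening pipeline uses 3:
#'   conjunctiva, sclera, surrounding skin).
#' @param seed Integer seed for the k-means++ draws.
#' @param max_iter Maximum Lloyd sweeps.
#' @param nstart Number of seeded k-means++ restarts; the run with the
#'   lowest within-cluster sum of squares is returned. Restarts guard
#'   against local minima that split a dominant background cluster
#'   instead of isolating the small conjunctiva cluster.
#' @return An object of class `ab_kmeans`: list with `k`, `centers`
#'   (`k x 2`, columns `a`, `b`), `cluster` (`h x w` integer matrix of
#'   1-based assignments), `size`, `tot_withinss`, `objective` (per-sweep
#'   trace, non-increasing) and `iterations`.
#' @export
kmeans_ab <- function(img_lab, k = 3L, seed = 1L, max_iter = 300L,
                      nstart = 5L) {
  if (!is.array(img_lab) || length(dim(img_lab)) != 3L ||
      dim(img_lab)[3] != 3L)
    stop("`img_lab` must be an h x w x 3 CIELAB array", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  dm <- dim(img_lab)
  X <- cbind(as.numeric(img_lab[, , 2]), as.numeric(img_lab[, , 3]))
  n <- nrow(X)
  if (k > n) stop("`k` exceeds the number of pixels", call. = FALSE)

  seeds <- derive_seeds(seed, max(1L, as.integer(nstart)))
  best <- NULL
  for (s in seeds) {
    fit <- kmeans_ab_once(X, k, s, max_iter)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  structure(list(
    k = k,
    centers = best$centers,
    cluster = matrix(best$cl, dm[1], dm[2]),
    size = tabulate(best$cl, nbins = k),
    tot_withinss = best$tot_withinss,
    objective = best$objective,
    iterations = best$iterations,
    seed = as.integer(seed)
  ), class = "ab_kmeans")
}

# One Lloyd run from a k-means++ start.
kmeans_ab_once <- function(X, k, seed, max_iter) {
  n <- nrow(X)
  centers <- with_seed(seed, kmeanspp_init(X, k))
  assign_step <- function(centers) {
    D <- sq_dist_to_centers(X, centers)
    cl <- max.col(-D, ties.method = "first")
    list(cl = cl, d2 = D[cbind(seq_len(n), cl)])
  }
  st <- assign_step(centers)
  objective <- sum(st$d2)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (j in seq_len(k)) {
      idx <- st$cl == j
      if (any(idx)) {
        centers[j, ] <- colMeans(X[idx, , drop = FALSE])
      } else {
        centers[j, ] <- X[which.max(st$d2), ]   # re-seed to farthest pixel
      }
    }
    new <- assign_step(centers)
    objective <- c(objective, sum(new$d2))
    if (identical(new$cl, st$cl) || iter >= max_iter) {
      st <- new
      break
    }
    st <- new
  }
  colnames(centers) <- c("a", "b")
  list(centers = centers, cl = st$cl, tot_withinss = sum(st$d2),
       objective = objective, iterations = iter)
}

# Squared Euclidean distances, n x k.
sq_dist_to_centers <- function(X, centers) {
  n <- nrow(X); k <- nrow(centers)
  D <- matrix(0, n, k)
  for (j in seq_len(k))
    D[, j] <- (X[, 1] - centers[j, 1])^2 + (X[, 2] - centers[j, 2])^2
  D
}

# k-means++ seeding (assumes the RNG is already seeded by the caller).
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- (X[, 1] - centers[1, 1])^2 + (X[, 2] - centers[1, 2])^2
    for (j in 2:k) {
      if (all(d2 == 0)) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, (X[, 1] - centers[j, 1])^2 +
                     (X[, 2] - centers[j, 2])^2)
    }
  }
  centers
}

#' @export
print.ab_kmeans <- function(x, ...) {
  cat("K-means in the CIELAB (a*, b*) plane\n")
  cat(sprintf("  k = %d clusters over %d pixels, %d Lloyd sweep(s)\n",
              x$k, sum(x$size), x$iterations))
  cat(sprintf("  total within-cluster SS: %.2f\n", x$tot_withinss))
  tab <- cbind(round(x$centers, 2), size = x$size)
  print(tab)
  invisible(x)
}

#' Select the conjunctiva cluster from a fitted color clustering
#'
#' Picks the cluster whose centroid has the maximum `a*` — the reddest
#' color, which is where the vascular conjunctiva lives — and returns its
#' pixels as a mask; all other clusters are removed. Exact `a*` ties are
#' broken by larger pixel count, then lower cluster index.
#'
#' @param model An `ab_kmeans` object from [kmeans_ab()].
#' @return Logical `h x w` mask of the selected cluster.
#' @export
select_conjunctiva_cluster <- function(model) {
  if (!inherits(model, "ab_kmeans"))
    stop("`model` must be an ab_kmeans object", call. = FALSE)
  ord <- order(-model$centers[, "a"], -model$size, seq_len(model$k))
  model$cluster == ord[1]
}

#' Load an externally produced segmentation mask
#'
#' Ingests a single-channel PNG mask (e.g. from a promptable segmentation
#' model) aligned to an image: nonzero pixels become `TRUE`.
#'
#' @param path Path to a single-channel 8-bit PNG.
#' @param img The image the mask belongs to (for dimension checking).
#' @return Logical `h x w` mask.
#' @export
load_external_mask <- function(path, img) {
  assert_image_rgb(img)
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  m <- png::readPNG(path)
  if (length(dim(m)) != 2L)
    stop("mask must be a single-channel PNG: ", path, call. = FALSE)
  if (!identical(dim(m), dim(img)[1:2]))
    stop(sprintf("mask dimensions %dx%d do not match image %dx%d",
                 dim(m)[1], dim(m)[2], dim(img)[1], dim(img)[2]),
         call. = FALSE)
  m > 0
}

#' Extract the masked pixel collection from an image
#'
#' Returns the RGB triples where the mask is true, in scan (column-major)
#' order, as the region object the feature extractors consume.
#'
#' @param img Integer `h x w x 3` RGB array.
#' @param mask Logical `h x w` mask aligned to `img`.
#' @return Integer `N x 3` matrix (columns `R`, `G`, `B`).
#' @export
apply_mask <- function(img, mask) {
  assert_image_rgb(img)
  if (!is.logical(mask) || !identical(dim(mask), dim(img)[1:2]))
    stop("`mask` must be a logical matrix aligned to `img`", call. = FALSE)
  if (!any(mask))
    stop("empty region: mask selects no pixels", call. = FALSE)
  out <- cbind(R = img[, , 1][mask], G = img[, , 2][mask],
               B = img[, , 3][mask])
  storage.mode(out) <- "integer"
  out
}

#' Segment the conjunctiva in one call
#'
#' Convenience wrapper over the full segmentation stage: ROI detection
#' ([detect_roi_baseline()]), crop, K-means in (a*, b*) ([kmeans_ab()]) and
#' reddest-cluster selection, returning the mask in full-image coordinates.
#'
#' @param img Integer `h x w x 3` RGB array.
#' @param k Number of color clusters.
#' @param seed Integer seed for the clustering initialization.
#' @param margin ROI padding in pixels.
#' @param roi If `FALSE`, cluster the whole image instead of the detected
#'   ROI.
#' @return List with `mask` (logical `h x w`, full-image coordinates),
#'   `box` and the fitted `model`.
#' @export
segment_conjunctiva <- function(img, k = 3L, seed = 1L, margin = 6L,
                                roi = TRUE) {
  assert_image_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  lab <- rgb_to_lab(img)
  if (roi) {
    box <- detect_roi_baseline(img, margin = margin, lab = lab)
    sub_lab <- lab[(box["y_min"] + 1L):box["y_max"],
                   (box["x_min"] + 1L):box["x_max"], , drop = FALSE]
  } else {
    box <- c(x_min = 0L, y_min = 0L, x_max = w, y_max = h)
    sub_lab <- lab
  }
  model <- kmeans_ab(sub_lab, k = k, seed = seed)
  sub_mask <- select_conjunctiva_cluster(model)
  mask <- matrix(FALSE, h, w)
  mask[(box["y_min"] + 1L):box["y_max"],
       (box["x_min"] + 1L):box["x_max"]] <- sub_mask
  list(mask = mask, box = box, model = model)
}
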