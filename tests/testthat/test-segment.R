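# ROI detection, cropping, a*b* K-means and mask handling.

test_that("redness-prior ROI detector finds a red rectangle exactly", {
  img <- const_image(100, 100, c(120, 120, 120))
  # red block at 0-based rows 10..20, cols 30..50 (inclusive)
  img[11:21, 31:51, 1] <- 200L
  img[11:21, 31:51, 2] <- 40L
  img[11:21, 31:51, 3] <- 40L
  box <- detect_roi_baseline(img, margin = 0)
  expect_equal(unname(box), c(30, 10, 51, 21))

  # padding clips at the image bounds
  edge <- const_image(20, 20, c(100, 100, 100))
  edge[1:5, 1:5, 1] <- 220L; edge[1:5, 1:5, 2] <- 50L
  edge[1:5, 1:5, 3] <- 50L
  b2 <- detect_roi_baseline(edge, margin = 10)
  expect_equal(unname(b2[c("x_min", "y_min")]), c(0, 0))
  expect_true(b2["x_max"] <= 20 && b2["y_max"] <= 20)

  expect_error(detect_roi_baseline(const_image(10, 10, c(90, 90, 90))),
               "no pixel")
})

test_that("crop_image slices exactly and validates bounds", {
  img <- random_image(6, 6)
  full <- c(x_min = 0, y_min = 0, x_max = 6, y_max = 6)
  expect_identical(crop_image(img, full), img)

  px <- crop_image(img, c(x_min = 0, y_min = 0, x_max = 1, y_max = 1))
  expect_equal(px[1, 1, ], img[1, 1, ])

  sub <- crop_image(img, c(x_min = 2, y_min = 1, x_max = 5, y_max = 3))
  expect_equal(dim(sub), c(2, 3, 3))
  expect_identical(sub, img[2:3, 3:5, , drop = FALSE])

  expect_error(crop_image(img, c(x_min = 2, y_min = 1, x_max = 7,
                                 y_max = 3)), "bounds")
  expect_error(crop_image(img, c(x_min = 3, y_min = 1, x_max = 3,
                                 y_max = 4)), "bounds")
})

lab_image_from_ab <- function(ab, L = 50) {
  h <- nrow(ab)
  arr <- array(0, c(h, 1, 3))
  arr[, 1, 1] <- L
  arr[, 1, 2] <- ab[, 1]
  arr[, 1, 3] <- ab[, 2]
  arr
}

test_that("kmeans_ab recovers well-separated blobs and satisfies Lloyd", {
  set.seed(41)
  blobs <- rbind(cbind(rnorm(40, 0, 0.5), rnorm(40, 0, 0.5)),
                 cbind(rnorm(40, 20, 0.5), rnorm(40, 20, 0.5)))
  m <- kmeans_ab(lab_image_from_ab(blobs), k = 2, seed = 5)
  truth <- rep(1:2, each = 40)
  agree <- max(mean(m$cluster == truth), mean(m$cluster == 3 - truth))
  expect_equal(agree, 1)
  # brute-force nearest-centroid fixed point
  expect_equal(as.vector(m$cluster), bf_nearest(blobs, m$centers))

  set.seed(42)
  centers3 <- rbind(c(-15, 0), c(10, 18), c(25, -10))
  pts <- do.call(rbind, lapply(1:3, function(j)
    cbind(rnorm(30, centers3[j, 1], 0.8), rnorm(30, centers3[j, 2], 0.8))))
  m3 <- kmeans_ab(lab_image_from_ab(pts), k = 3, seed = 2)
  for (j in 1:3) {
    members <- m3$cluster[(j - 1) * 30 + 1:30]
    expect_equal(length(unique(members)), 1)  # one blob, one label
    blob_mean <- colMeans(pts[(j - 1) * 30 + 1:30, ])
    d <- sqrt(min(colSums((t(m3$centers) - blob_mean)^2)))
    expect_lt(d, 1)
  }
})

test_that("kmeans_ab objective is non-increasing and seed-deterministic", {
  set.seed(7)
  pts <- cbind(runif(150, -30, 30), runif(150, -30, 30))
  lab <- lab_image_from_ab(pts)
  m <- kmeans_ab(lab, k = 3, seed = 9)
  expect_true(all(diff(m$objective) <= 1e-9))
  m2 <- kmeans_ab(lab, k = 3, seed = 9)
  expect_identical(m[c("centers", "cluster", "size", "tot_withinss")],
                   m2[c("centers", "cluster", "size", "tot_withinss")])

  one <- kmeans_ab(lab_image_from_ab(cbind(rep(4, 10), rep(-3, 10))),
                   k = 1, seed = 1)
  expect_equal(unname(one$centers[1, ]), c(4, -3))
  expect_true(all(one$cluster == 1))

  expect_error(kmeans_ab(lab_image_from_ab(cbind(1:3, 1:3)), k = 5,
                         seed = 1), "exceeds")
})

test_that("kmeans_ab matches stats::kmeans objective on easy data", {
  set.seed(13)
  pts <- rbind(cbind(rnorm(50, 0, 1), rnorm(50, 0, 1)),
               cbind(rnorm(50, 15, 1), rnorm(50, 15, 1)),
               cbind(rnorm(50, -15, 1), rnorm(50, 15, 1)))
  m <- kmeans_ab(lab_image_from_ab(pts), k = 3, seed = 3)
  ref <- stats::kmeans(pts, centers = 3, nstart = 20,
                       algorithm = "Lloyd", iter.max = 200)
  expect_lt(abs(m$tot_withinss - ref$tot.withinss) /
              ref$tot.withinss, 0.01)
})

test_that("reddest-centroid selection applies the documented tie-breaks", {
  model <- structure(list(
    k = 3L,
    centers = cbind(a = c(5, 30, -10), b = c(0, 0, 0)),
    cluster = matrix(c(1L, 2L, 3L, 2L), 2, 2),
    size = c(1L, 2L, 1L)), class = "ab_kmeans")
  mask <- select_conjunctiva_cluster(model)
  expect_equal(mask, model$cluster == 2L)
  expect_equal(sum(mask), model$size[2])

  tied <- structure(list(
    k = 2L,
    centers = cbind(a = c(20, 20), b = c(1, 2)),
    cluster = matrix(c(rep(1L, 100), rep(2L, 40)), 10, 14),
    size = c(100L, 40L)), class = "ab_kmeans")
  expect_equal(select_conjunctiva_cluster(tied), tied$cluster == 1L)
})

test_that("external masks load with alignment and format checking", {
  img <- random_image(8, 6)
  dir <- withr::local_tempdir()
  allon <- file.path(dir, "on.png")
  png::writePNG(matrix(1, 8, 6), allon)
  m <- load_external_mask(allon, img)
  expect_true(all(m))

  board <- matrix(rep_len(c(1, 0), 48), 8, 6)
  chk <- file.path(dir, "chk.png")
  png::writePNG(board, chk)
  expect_equal(sum(load_external_mask(chk, img)), sum(board > 0))

  small <- file.path(dir, "small.png")
  png::writePNG(matrix(1, 8, 5), small)
  expect_error(load_external_mask(small, img), "dimensions")

  rgbm <- file.path(dir, "rgb.png")
  png::writePNG(array(1, c(8, 6, 3)), rgbm)
  expect_error(load_external_mask(rgbm, img), "single-channel")
})

test_that("apply_mask returns masked RGB triples in scan order", {
  img <- random_image(5, 4)
  all_on <- matrix(TRUE, 5, 4)
  reg <- apply_mask(img, all_on)
  expect_equal(nrow(reg), 20)
  expect_equal(reg[, "R"], as.vector(img[, , 1]))

  expect_error(apply_mask(img, matrix(FALSE, 5, 4)), "empty region")

  mask <- matrix(FALSE, 5, 4)
  picks <- cbind(c(1, 3, 5, 2), c(1, 2, 4, 3))
  mask[picks] <- TRUE
  reg2 <- apply_mask(img, mask)
  expect_equal(nrow(reg2), 4)
  ord <- order(picks[, 2], picks[, 1])  # column-major scan order
  expect_equal(reg2[, "G"], img[, , 2][picks][ord])
})

test_that("segmented conjunctiva recall stays high across lighting", {
  for (cls in c("anemic", "moderate", "normal")) {
    truth <- render_eye_image(cls, seed = 300)
    for (preset in names(lighting_presets())) {
      img <- apply_white_balance(truth$image, preset)
      seg <- segment_conjunctiva(img, k = 3, seed = 17)
      recall <- sum(seg$mask & truth$mask) / sum(truth$mask)
      expect_gte(recall, 0.9)
    }
  }
})
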