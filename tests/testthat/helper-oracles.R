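# Independent brute-force oracles and small fixture builders. Everything
# here is written as plain per-pixel loops, deliberately not sharing code
# with the package internals.

const_image <- function(h, w, rgb) {
  img <- array(0L, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

random_image <- function(h, w) {
  array(sample.int(256L, h * w * 3L, replace = TRUE) - 1L, c(h, w, 3))
}

# Scalar HSI by direct evaluation of the arccos hue formula.
hsi_pixel <- function(R, G, B) {
  R <- unname(R); G <- unname(G); B <- unname(B)
  s <- R + G + B
  I <- s / (3 * 255)
  if (s == 0) return(c(H = 0, S = 0, I = 0))
  S <- 1 - 3 * min(R, G, B) / s
  if (S == 0) return(c(H = 0, S = 0, I = I))
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  th <- if (den == 0) 0 else acos(max(-1, min(1, num / den))) * 180 / pi
  H <- if (B > G) 360 - th else th
  if (H >= 360) H <- 0
  c(H = H, S = S, I = I)
}

# Brute-force versions of the seven region features (region: n x 3).
bf_features <- function(region, tau_h = 300, delta = 20) {
  n <- nrow(region)
  inten <- numeric(n); red <- logical(n); high <- logical(n)
  for (i in seq_len(n)) {
    R <- region[i, 1]; G <- region[i, 2]; B <- region[i, 3]
    inten[i] <- (R + G + B) / 3
    red[i] <- R > G && R > B && (R - max(G, B)) >= delta
    hsi <- hsi_pixel(R, G, B)
    high[i] <- hsi["S"] > 0 && hsi["H"] >= tau_h
  }
  counts <- integer(256)
  for (i in seq_len(n)) {
    b <- as.integer(floor(inten[i] + 0.5)) + 1L
    counts[b] <- counts[b] + 1L
  }
  ent <- 0
  for (b in seq_len(256)) {
    if (counts[b] > 0) {
      p <- counts[b] / n
      ent <- ent - p * log2(p)
    }
  }
  c(mean_intensity = sum(inten) / n,
    rg_ratio = (sum(region[, 1]) / n) / (sum(region[, 2]) / n),
    rg_diff = sum(region[, 1]) / n - sum(region[, 2]) / n,
    std_intensity = sqrt(sum((inten - sum(inten) / n)^2) / n),
    entropy_bits = ent,
    high_hue_ratio = sum(high) / n,
    red_pixel_pct = sum(red) / n)
}

# Exhaustive nearest-centroid assignment.
bf_nearest <- function(X, centers) {
  n <- nrow(X); k <- nrow(centers)
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- 1L; bestd <- Inf
    for (j in seq_len(k)) {
      d <- sum((X[i, ] - centers[j, ])^2)
      if (d < bestd) { bestd <- d; best <- j }
    }
    out[i] <- best
  }
  out
}

# Trapezoidal one-vs-rest AUC by an exhaustive threshold sweep over all
# distinct scores.
trapezoid_auc <- function(pos, scores) {
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- sum(pred & pos) / sum(pos)
    fpr[i] <- sum(pred & !pos) / sum(!pos)
  }
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Table-style hemoglobin grading oracle, written out case by case.
oracle_hb_label <- function(sex, hb) {
  if (hb < 10.5) return("anemic")
  if (sex == "male") {
    if (hb <= 13.5) return("moderate") else return("normal")
  }
  if (hb <= 12) "moderate" else "normal"
}

# Well-separated 3-class Gaussian feature set for classifier tests.
separable_features <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  centers <- rbind(anemic = c(0, 0, 0), moderate = c(6, 6, 0),
                   normal = c(0, 6, 6))
  rows <- lapply(rownames(centers), function(cl) {
    m <- matrix(rnorm(n_per_class * 3, sd = 0.5), ncol = 3)
    data.frame(mean_intensity = m[, 1] + centers[cl, 1],
               rg_ratio = m[, 2] + centers[cl, 2],
               rg_diff = m[, 3] + centers[cl, 3],
               label = cl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
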