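# Screening orchestration and geospatial prevalence aggregation.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Screen one image end to end
#'
#' Runs the full pipeline on a single eye image: ROI detection and crop,
#' K-means conjunctiva segmentation (or an externally supplied mask),
#' feature extraction, and MLP prediction; optionally geotags the result.
#' Errors carry a stage tag (`[read]`, `[segment]`, `[features]`,
#' `[predict]`) identifying where the pipeline failed.
#'
#' @param image Path to a PNG/JPEG, or an integer `h x w x 3` RGB array.
#' @param model A fitted [pallor_mlp()].
#' @param mask Optional path to an external single-channel PNG mask (the
#'   K-means stage is then skipped), or a logical mask matrix.
#' @param lat,lon Optional geotag in decimal degrees.
#' @param record_id Identifier for the screening record.
#' @param k,seed Segmentation parameters, as in [segment_conjunctiva()].
#' @param timestamp Record timestamp (ISO-8601 string).
#' @return List with `record` (one-row data frame: `record_id`, `label`,
#'   `probability`, `lat`, `lon`, `timestamp`), `probabilities`,
#'   `features` and `mask`.
#' @export
run_screening <- function(image, model, mask = NULL, lat = NA_real_,
                          lon = NA_real_, record_id = "R001", k = 3L,
                          seed = 1L,
                          timestamp = format(Sys.time(),
                                             "%Y-%m-%dT%H:%M:%S%z")) {
  if (!inherits(model, "pallor_mlp"))
    stop("[predict] `model` must be a pallor_mlp fit", call. = FALSE)
  if (!is.na(lat) && abs(lat) > 90) stop("invalid latitude", call. = FALSE)
  if (!is.na(lon) && abs(lon) > 180) stop("invalid longitude",
                                          call. = FALSE)
  img <- if (is.character(image)) stage("read", read_image(image))
         else stage("read", assert_image_rgb(image))
  m <- if (is.null(mask)) {
    stage("segment", segment_conjunctiva(img, k = k, seed = seed)$mask)
  } else if (is.character(mask)) {
    stage("segment", load_external_mask(mask, img))
  } else mask
  fv <- stage("features", extract_feature_vector(img, m))
  prob <- stage("predict",
                predict(model, matrix(fv, nrow = 1,
                                      dimnames = list(NULL, names(fv))),
                        type = "prob"))
  lab <- model$classes[which.max(prob)]
  record <- data.frame(record_id = record_id, label = lab,
                       probability = max(prob), lat = lat, lon = lon,
                       timestamp = timestamp, stringsAsFactors = FALSE)
  list(record = record, probabilities = drop(prob), features = fv,
       mask = m)
}

#' Aggregate screening records into a prevalence grid
#'
#' Bins geotagged screening records into an equal-degree latitude/longitude
#' grid anchored at (-90, -180) with half-open `[min, min + size)` cells
#' (the top/right world edges fold into the last cell), and flags cells
#' whose anemic fraction reaches `threshold` with at least `min_n`
#' records — the screening-cluster criterion.
#'
#' @param records Data frame with columns `label`, `lat`, `lon` (e.g.
#'   accumulated [run_screening()] records).
#' @param cell_size Grid cell size in decimal degrees.
#' @param min_n Minimum records for a cell to be flaggable.
#' @param threshold Anemic fraction at or above which a cell is flagged.
#' @param include_moderate Count `moderate` predictions as anemic.
#' @return Data frame of occupied cells: bounds, `n_total`, `n_anemic`,
#'   `anemic_fraction`, `flagged`.
#' @export
aggregate_prevalence <- function(records, cell_size = 1, min_n = 5L,
                                 threshold = 0.1,
                                 include_moderate = FALSE) {
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  if (!is.data.frame(records))
    stop("`records` must be a data frame", call. = FALSE)
  if (nrow(records) == 0L) {
    return(data.frame(lat_min = numeric(0), lat_max = numeric(0),
                      lon_min = numeric(0), lon_max = numeric(0),
                      n_total = integer(0), n_anemic = integer(0),
                      anemic_fraction = numeric(0), flagged = logical(0)))
  }
  lat <- as.numeric(records$lat); lon <- as.numeric(records$lon)
  if (anyNA(lat) || anyNA(lon) || any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("records carry invalid coordinates", call. = FALSE)
  anemic_set <- if (include_moderate) c("anemic", "moderate") else "anemic"
  iy <- pmin(floor((lat + 90) / cell_size),
             ceiling(180 / cell_size) - 1)
  ix <- pmin(floor((lon + 180) / cell_size),
             ceiling(360 / cell_size) - 1)
  key <- paste(iy, ix)
  is_anemic <- records$label %in% anemic_set
  agg <- do.call(rbind, lapply(split(seq_along(key), key), function(idx) {
    data.frame(iy = iy[idx[1]], ix = ix[idx[1]],
               n_total = length(idx),
               n_anemic = sum(is_anemic[idx]))
  }))
  agg <- agg[order(agg$iy, agg$ix), , drop = FALSE]
  out <- data.frame(
    lat_min = -90 + agg$iy * cell_size,
    lat_max = -90 + (agg$iy + 1) * cell_size,
    lon_min = -180 + agg$ix * cell_size,
    lon_max = -180 + (agg$ix + 1) * cell_size,
    n_total = as.integer(agg$n_total),
    n_anemic = as.integer(agg$n_anemic)
  )
  out$anemic_fraction <- out$n_anemic / out$n_total
  out$flagged <- out$n_total >= min_n & out$anemic_fraction >= threshold
  rownames(out) <- NULL
  out
}

#' Write a prevalence grid as GeoJSON
#'
#' Emits a `FeatureCollection` of cell polygons with `n_total`,
#' `n_anemic`, `anemic_fraction` and `flagged` properties, consumable by
#' any mapping client.
#'
#' @param cells Data frame from [aggregate_prevalence()].
#' @param path Destination `.geojson` path.
#' @return `path`, invisibly.
#' @export
prevalence_geojson <- function(cells, path) {
  features <- lapply(seq_len(nrow(cells)), function(i) {
    c0 <- cells[i, ]
    ring <- list(
      c(c0$lon_min, c0$lat_min), c(c0$lon_max, c0$lat_min),
      c(c0$lon_max, c0$lat_max), c(c0$lon_min, c0$lat_max),
      c(c0$lon_min, c0$lat_min))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(n_total = c0$n_total, n_anemic = c0$n_anemic,
                           anemic_fraction = c0$anemic_fraction,
                           flagged = c0$flagged))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a YAML configuration file
#'
#' Supported keys: `presets` (named gain triples overriding
#' [lighting_presets()]), `augmentation` (preset names to apply), and any
#' pipeline parameter consumed by the CLI.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the yaml package",
         call. = FALSE)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
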