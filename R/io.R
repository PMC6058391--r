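#' Read an azimuth observation table
#'
#' Reads a delimited text file of field azimuths. Required columns:
#' `individual`, `relocation`, `x`, `y` (observer easting/northing in
#' meters, projected CRS), `azimuth` (compass degrees in [0, 360)).
#' Additional columns (observer, date, covariates) are kept. Compass
#' azimuths are converted to internal mathematical bearings (`theta`,
#' radians counterclockwise from east) on load.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return a validated data.frame with the added `theta` column.
#' @export
read_azimuth_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data: azimuth table is empty")
  need <- c("individual", "relocation", "x", "y", "azimuth")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) {
    stop("non-finite coordinates at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(!is.finite(df$azimuth) | df$azimuth < 0 | df$azimuth >= 360)
  if (length(bad)) {
    stop("azimuth outside [0, 360) at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (any(!nzchar(as.character(df$individual))) ||
      any(!nzchar(as.character(df$relocation)))) {
    stop("empty individual/relocation id")
  }
  df$theta <- compass_to_math(df$azimuth)
  df
}

#' @rdname read_azimuth_table
#' @param table azimuth table (data.frame).
#' @export
write_azimuth_table <- function(table, path, sep = ",") {
  out <- table[, setdiff(names(table), "theta"), drop = FALSE]
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with a `seed` and module blocks (`mcmc`,
#'   `design`, `rsf`, `home_range`, `radius_r`, `output_dir`).
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

#' Write geometries as GeoJSON
#'
#' @param polygons list of closed-ring matrices (columns x, y), or a
#'   single matrix.
#' @param path output path.
#' @param properties optional data.frame of per-polygon properties.
#' @return the path, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path, properties = NULL) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  feats <- lapply(seq_along(polygons), function(i) {
    ring <- matrix(as.numeric(polygons[[i]]), ncol = 2)
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(k) ring[k, ])
    props <- if (is.null(properties)) {
      stats::setNames(list(), character())
    } else {
      as.list(properties[i, , drop = FALSE])
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records its configuration, seed, package version and
#' a configuration hash so outputs can be reproduced.
#'
#' @param config the run configuration list.
#' @param output_dir output directory.
#' @param runtime elapsed seconds.
#' @return path of the manifest file, invisibly.
#' @export
write_manifest <- function(config, output_dir, runtime = NA_real_) {
  txt <- yaml::as.yaml(config)
  tmp <- tempfile()
  writeLines(txt, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  man <- list(config = config, config_hash = h,
              package = "aztelem",
              version = as.character(utils::packageVersion("aztelem")),
              runtime_seconds = runtime,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(output_dir, "manifest.yaml")
  writeLines(yaml::as.yaml(man), path)
  invisible(path)
}
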