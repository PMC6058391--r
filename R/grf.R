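#' Gridded covariate raster
#'
#' A minimal regular-grid raster container for spatial covariates in a
#' projected planar CRS (meters): cell-center registration, rows running
#' south from the north-west corner when written to disk, but stored here
#' as matrices indexed `[col_x, row_y]` with `y` increasing.
#'
#' @param origin length-2 lower-left corner of the grid (m).
#' @param cellsize cell edge length (m, > 0).
#' @param layers named list of numeric matrices (`ncol_x` x `nrow_y`), all
#'   of identical dimension.
#' @return object of class `cov_raster`.
#' @export
cov_raster <- function(origin, cellsize, layers) {
  if (cellsize <= 0) stop("cellsize must be > 0")
  if (!length(layers)) stop("need at least one layer")
  d <- dim(layers[[1]])
  for (l in layers) if (!all(dim(l) == d)) stop("layer dimensions differ")
  structure(list(origin = as.numeric(origin), cellsize = cellsize,
                 nx = d[1], ny = d[2], layers = layers),
            class = "cov_raster")
}

#' @export
print.cov_raster <- function(x, ...) {
  cat(sprintf("cov_raster: %d x %d cells of %.0f m; layers: %s\n",
              x$nx, x$ny, x$cellsize,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @rdname cov_raster
#' @param raster a `cov_raster`.
#' @return `raster_extent`: named vector xmin/xmax/ymin/ymax.
#' @export
raster_extent <- function(raster) {
  c(xmin = raster$origin[1],
    xmax = raster$origin[1] + raster$nx * raster$cellsize,
    ymin = raster$origin[2],
    ymax = raster$origin[2] + raster$ny * raster$cellsize)
}

#' @rdname cov_raster
#' @param points n x 2 matrix of coordinates.
#' @param layer layer name or index.
#' @return `raster_values`: covariate values at the points (NA outside the
#'   grid).
#' @export
raster_values <- function(raster, points, layer = 1L) {
  pts <- matrix(as.numeric(points), ncol = 2)
  i <- floor((pts[, 1] - raster$origin[1]) / raster$cellsize) + 1L
  j <- floor((pts[, 2] - raster$origin[2]) / raster$cellsize) + 1L
  ok <- i >= 1L & i <= raster$nx & j >= 1L & j <= raster$ny
  out <- rep(NA_real_, nrow(pts))
  out[ok] <- raster$layers[[layer]][cbind(i[ok], j[ok])]
  out
}

## simulate a zero-mean unit-variance GRF with exponential covariance
## exp(-h / (range_cells * cellsize)) on an nx x ny grid by circulant
## embedding (FFT); clips small negative embedding eigenvalues.
.grf_sim <- function(nx, ny, range_cells) {
  ## generous torus padding keeps the circulant embedding near-nonnegative
  m1 <- 2L * nx + 8L * ceiling(range_cells)
  m2 <- 2L * ny + 8L * ceiling(range_cells)
  dx <- pmin(0:(m1 - 1L), m1 - (0:(m1 - 1L)))
  dy <- pmin(0:(m2 - 1L), m2 - (0:(m2 - 1L)))
  h <- sqrt(outer(dx^2, dy^2, "+"))
  C <- exp(-h / range_cells)
  lambda <- Re(fft(C))
  lambda[lambda < 0] <- 0
  z <- matrix(complex(real = rnorm(m1 * m2), imaginary = rnorm(m1 * m2)),
              m1, m2)
  f <- fft(sqrt(lambda / (m1 * m2)) * z)
  Re(f)[seq_len(nx), seq_len(ny)]
}

#' Simulate Gaussian-random-field covariate rasters
#'
#' Generates the two covariate layers used by the resource-selection
#' simulations: a continuous layer (zero-mean, unit-variance GRF with
#' exponential covariance) and an independent categorical 0/1 layer (a
#' second GRF thresholded at its median, so classes are balanced). The
#' autocorrelation level maps to the covariance range: 2, 8 or 32 cells
#' for low, moderate and high.
#'
#' @param nx,ny grid dimension in cells.
#' @param cellsize cell edge length (m), e.g. 25 or 100.
#' @param autocorrelation `"low"`, `"moderate"` or `"high"` (or a numeric
#'   range in cells).
#' @param origin lower-left corner, default `c(0, 0)`.
#' @return a [cov_raster()] with layers `cont` and `cat`.
#' @export
simulate_grf_covariates <- function(nx, ny, cellsize = 25,
                                    autocorrelation = c("moderate", "low", "high"),
                                    origin = c(0, 0)) {
  if (is.numeric(autocorrelation)) {
    range_cells <- autocorrelation
  } else {
    autocorrelation <- match.arg(autocorrelation)
    range_cells <- c(low = 2, moderate = 8, high = 32)[[autocorrelation]]
  }
  cont <- .grf_sim(nx, ny, range_cells)
  cat_f <- .grf_sim(nx, ny, range_cells)
  catl <- (cat_f > median(cat_f)) * 1
  cov_raster(origin, cellsize, layers = list(cont = cont, cat = catl))
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text single-layer raster exchange format (cell-center registered;
#' rows from the northern edge).
#'
#' @param path file path.
#' @return `read_esri_ascii`: a [cov_raster()] with one layer named
#'   `"layer"`.
#' @export
read_esri_ascii <- function(path) {
  hdr <- list()
  lines <- readLines(path, n = 6L)
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header")
  skip <- sum(vapply(lines, function(ln) {
    grepl("^[a-zA-Z]", trimws(ln))
  }, logical(1)))
  vals <- scan(path, skip = skip, quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr) stop("cell count does not match header")
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  ## file rows run north -> south; store as [x, y] with y increasing
  m <- matrix(vals, nrow = nc, ncol = nr)[, nr:1, drop = FALSE]
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  cov_raster(c(x0, y0), hdr$cellsize, layers = list(layer = m))
}

#' @rdname read_esri_ascii
#' @param raster a [cov_raster()].
#' @param layer which layer to write.
#' @export
write_esri_ascii <- function(raster, path, layer = 1L) {
  m <- raster$layers[[layer]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", raster$nx),
    paste("nrows", raster$ny),
    paste("xllcorner", raster$origin[1]),
    paste("yllcorner", raster$origin[2]),
    paste("cellsize", raster$cellsize),
    paste("NODATA_value", -9999)), con)
  m2 <- m[, raster$ny:1, drop = FALSE]
  m2[is.na(m2)] <- -9999
  for (j in seq_len(raster$ny)) {
    writeLines(paste(m2[, j], collapse = " "), con)
  }
  invisible(path)
}
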